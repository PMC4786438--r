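#' @importFrom stats lm coef rmultinom rlnorm runif setNames aggregate
#' @importFrom utils read.delim write.table packageVersion
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

#' Translate a coding DNA sequence
#'
#' Thin wrapper around [Biostrings::translate()] using the standard genetic
#' code and never interpreting the first codon as an initiator (constructs
#' here are internal segments of an open reading frame).
#'
#' @param dna Character scalar or vector of in-frame DNA sequences.
#' @return Character vector of amino-acid sequences (`*` marks stops).
#' @export
translate_dna <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE))
}

#' Reverse complement with IUPAC degenerate bases
#'
#' Complements degenerate bases symbol-wise (`N` stays `N`, `S` stays `S`),
#' so an `NNS` codon on the forward strand reads `SNN` on the reverse.
#'
#' @param x Character vector of (possibly degenerate) DNA sequences.
#' @return Character vector of reverse complements.
#' @export
degenerate_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Enumerate the NNS degenerate codon
#'
#' `N` is any base, `S` is G or C: 32 codons covering all 20 amino acids and
#' a single stop (the amber codon TAG).
#'
#' @return A data frame with columns `codon` and `aa`.
#' @export
nns_codons <- function() {
  n <- c("A", "C", "G", "T")
  s <- c("C", "G")
  codons <- as.vector(outer(outer(n, n, paste0), s, paste0))
  data.frame(codon = codons, aa = translate_dna(codons),
             stringsAsFactors = FALSE)
}

#' Define a transmembrane expression construct
#'
#' A construct is the DNA of the membrane-spanning segment plus the constant
#' flanking sequences used to locate the amplicon in sequencing reads. The
#' segment is numbered in the host protein's residue numbering so that
#' positions quoted in analyses (e.g. CLS Ala311) carry through to output.
#' Orientation is fixed N-cytoplasmic (type-II topology: the N-terminus and
#' the reporter are cytoplasmic, residue numbers increase toward the
#' periplasm).
#'
#' @param name Construct name.
#' @param dna In-frame coding DNA of the segment.
#' @param span_start,span_end First and last scanned residue positions
#'   (inclusive, in `numbering_offset`-based numbering).
#' @param numbering_offset Residue number of the first codon of `dna` minus
#'   one, so residue `i` of the translated segment is position
#'   `numbering_offset + i`.
#' @param upstream_flank,downstream_flank Constant sequences immediately 5'
#'   and 3' of `dna` in the sequenced amplicon.
#' @param protein Optional expected protein sequence; checked against the
#'   translation of `dna`.
#' @return An object of class `Construct`.
#' @export
construct <- function(name, dna, span_start, span_end,
                      numbering_offset = 0L,
                      upstream_flank, downstream_flank,
                      protein = NULL) {
  dna <- toupper(gsub("\\s", "", dna))
  stopifnot(nchar(dna) %% 3 == 0, nchar(dna) > 0)
  tr <- translate_dna(dna)
  if (!is.null(protein) && !identical(tr, toupper(protein)))
    stop("construct '", name, "': translate(dna) != protein")
  if (grepl("\\*", tr))
    stop("construct '", name, "': stop codon in coding sequence")
  numbering_offset <- as.integer(numbering_offset)
  span_start <- as.integer(span_start)
  span_end <- as.integer(span_end)
  n_res <- nchar(tr)
  if (span_start > span_end ||
      span_start <= numbering_offset ||
      span_end > numbering_offset + n_res)
    stop("construct '", name, "': span outside protein")
  if (missing(upstream_flank) || missing(downstream_flank) ||
      !nzchar(upstream_flank) || !nzchar(downstream_flank))
    stop("construct '", name, "': flanks must be non-empty")
  upstream_flank <- toupper(upstream_flank)
  downstream_flank <- toupper(downstream_flank)
  amplicon <- paste0(upstream_flank, dna, downstream_flank)
  count_occ <- function(f) {
    length(gregexpr(f, amplicon, fixed = TRUE)[[1]]) -
      (gregexpr(f, amplicon, fixed = TRUE)[[1]][1] == -1)
  }
  if (count_occ(upstream_flank) != 1L || count_occ(downstream_flank) != 1L)
    stop("construct '", name, "': flanks must occur exactly once in amplicon")
  obj <- list(name = name, dna = dna, protein = tr,
              span = c(span_start, span_end),
              numbering_offset = numbering_offset,
              upstream_flank = upstream_flank,
              downstream_flank = downstream_flank,
              orientation = "N-cytoplasmic")
  class(obj) <- "Construct"
  obj
}

#' @export
print.Construct <- function(x, ...) {
  cat("Construct", x$name, "(", x$orientation, ")\n")
  cat("  protein:", x$protein, "\n")
  cat("  span   :", x$span[1], "-", x$span[2], "(",
      x$span[2] - x$span[1] + 1, "positions )\n")
  invisible(x)
}

#' Scanned residue positions of a construct
#' @param x A `Construct`.
#' @return Integer vector of residue positions (paper numbering).
#' @export
span_positions <- function(x) seq.int(x$span[1], x$span[2])

# residue index within the translated segment (1-based) for a position
residue_index <- function(x, position) {
  idx <- as.integer(position) - x$numbering_offset
  if (any(idx < 1L | idx > nchar(x$protein)))
    stop("position outside construct protein")
  idx
}

#' Wild-type amino acid at given positions
#' @param x A `Construct`.
#' @param position Residue positions (paper numbering); defaults to the span.
#' @return Character vector of one-letter amino acids.
#' @export
wildtype_aa <- function(x, position = span_positions(x)) {
  substring(x$protein, residue_index(x, position), residue_index(x, position))
}

#' Enumerate the single-site NNS saturation library
#'
#' One variant per (scanned position, amino acid), wild-type identities
#' included, giving exactly `20 * span_length` variants. Stop codons are not
#' variants (the single NNS stop, amber, is rejected at the counting stage).
#'
#' @param x A `Construct`.
#' @return Data frame with columns `position`, `wt_aa`, `aa`, `is_wildtype`.
#' @export
enumerate_library <- function(x) {
  stopifnot(inherits(x, "Construct"))
  pos <- span_positions(x)
  wt <- wildtype_aa(x, pos)
  if (any(wt == "*")) stop("span contains a stop codon in the wild type")
  out <- data.frame(position = rep(pos, each = 20L),
                    wt_aa = rep(wt, each = 20L),
                    aa = rep(AA20, length(pos)),
                    stringsAsFactors = FALSE)
  out$is_wildtype <- out$aa == out$wt_aa
  out
}

#' Design an NNS mutagenic primer pair for one position
#'
#' The forward oligo copies the construct DNA (extending into the flanks
#' where needed) with the targeted codon replaced by `NNS`; the reverse
#' oligo is its degenerate reverse complement (`SNN` on the reverse strand).
#' Arm lengths are symmetric by default and the total oligo length is kept
#' within 40-85 nt.
#'
#' @param x A `Construct`.
#' @param position Targeted residue position (paper numbering, within span).
#' @param total_length Desired oligo length (default 48 nt, i.e. 22-23 nt
#'   arms around the codon); clamped to \[40, 85\].
#' @return A list of class `PrimerPair` with `forward`, `reverse`,
#'   `position`.
#' @export
design_primers <- function(x, position, total_length = 48L) {
  stopifnot(inherits(x, "Construct"))
  position <- as.integer(position)
  if (position < x$span[1] || position > x$span[2])
    stop("position ", position, " outside scanned span")
  total_length <- max(40L, min(85L, as.integer(total_length)))
  context <- paste0(x$upstream_flank, x$dna, x$downstream_flank)
  codon_start <- nchar(x$upstream_flank) +
    (residue_index(x, position) - 1L) * 3L + 1L
  arm <- total_length - 3L
  up_len <- arm %/% 2L
  down_len <- arm - up_len
  up_avail <- codon_start - 1L
  down_avail <- nchar(context) - (codon_start + 2L)
  # shift arms if one side is short, keeping the total
  if (up_avail < up_len) {
    down_len <- down_len + (up_len - up_avail); up_len <- up_avail
  }
  if (down_avail < down_len) {
    up_len2 <- up_len + (down_len - down_avail)
    if (up_len2 > up_avail)
      stop("position ", position,
           " too close to sequence ends for a 40-nt oligo")
    up_len <- up_len2; down_len <- down_avail
  }
  if (up_len + down_len + 3L < 40L)
    stop("position ", position,
         " too close to sequence ends for a 40-nt oligo")
  fwd <- paste0(substr(context, codon_start - up_len, codon_start - 1L),
                "NNS",
                substr(context, codon_start + 3L,
                       codon_start + 2L + down_len))
  out <- list(forward = fwd, reverse = degenerate_revcomp(fwd),
              position = position)
  class(out) <- "PrimerPair"
  out
}

#' Design primers for every scanned position
#' @inheritParams design_primers
#' @return Data frame with columns `position`, `forward`, `reverse`.
#' @export
design_all_primers <- function(x, total_length = 48L) {
  pos <- span_positions(x)
  pairs <- lapply(pos, design_primers, x = x, total_length = total_length)
  data.frame(position = pos,
             forward = vapply(pairs, `[[`, "", "forward"),
             reverse = vapply(pairs, `[[`, "", "reverse"),
             stringsAsFactors = FALSE)
}

#' Write a saturation library or primer set as FASTA
#' @param df Data frame from [enumerate_library()] or [design_all_primers()].
#' @param path Output file.
#' @param what `"library"` (one record per variant, header
#'   `position_aa`) or `"primers"` (two records per position).
#' @export
write_library_fasta <- function(df, path, what = c("library", "primers")) {
  what <- match.arg(what)
  lines <- if (what == "library") {
    as.vector(rbind(sprintf(">%d_%s%s", df$position, df$aa,
                            ifelse(df$is_wildtype, "_wt", "")),
                    df$aa))
  } else {
    as.vector(rbind(sprintf(">%d_forward", df$position), df$forward,
                    sprintf(">%d_reverse", df$position), df$reverse))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a construct definition from a flat config file
#'
#' The format is one `key: value` pair per line (keys `name`, `dna`,
#' `span_start`, `span_end`, `numbering_offset`, `upstream_flank`,
#' `downstream_flank`, optional `protein`); `#` starts a comment.
#'
#' @param path Path to the config file.
#' @return A `Construct`.
#' @export
read_construct <- function(path) {
  kv <- read_flat_config(path)
  need <- c("name", "dna", "span_start", "span_end",
            "upstream_flank", "downstream_flank")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("construct config missing keys: ", paste(miss, collapse = ", "))
  construct(name = kv$name, dna = kv$dna,
            span_start = as.integer(kv$span_start),
            span_end = as.integer(kv$span_end),
            numbering_offset = as.integer(kv$numbering_offset %||% 0L),
            upstream_flank = kv$upstream_flank,
            downstream_flank = kv$downstream_flank,
            protein = kv$protein)
}

#' Built-in example constructs
#'
#' Returns one of the constructs shipped with the package: the printed
#' C-terminal L-Selectin segment (`"cls"`), a synthetic 27-position
#' extension of it used as the default simulation world (`"cls27"`), the
#' Glycophorin A homodimer segment (`"gpa"`), and the ErbB2 segment
#' (`"erbb2"`).
#'
#' @param name One of `"cls"`, `"cls27"`, `"gpa"`, `"erbb2"`.
#' @return A `Construct`.
#' @export
example_construct <- function(name = c("cls27", "cls", "gpa", "erbb2")) {
  name <- match.arg(name)
  file <- c(cls = "cls.cfg", cls27 = "cls27_synthetic.cfg",
            gpa = "gpa.cfg", erbb2 = "erbb2.cfg")[[name]]
  read_construct(system.file("extdata", "constructs", file,
                             package = "memscan", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(m) trimws(m[3]))
  names(vals) <- vapply(kv, `[[`, "", 2)
  vals
}
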