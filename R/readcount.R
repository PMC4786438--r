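#' Merge a read pair and extract the insert sequence
#'
#' Mates are joined on their expected overlap (the amplicon layout is fixed
#' by the construct); any disagreement within the overlap rejects the pair.
#' Both constant flanks must match exactly; the in-frame insert between them
#' is returned.
#'
#' Vectorized over read pairs; `extract_span()` is the scalar convenience
#' wrapper.
#'
#' @param r1,r2 Character vectors of mate-1 and mate-2 sequences (mate 2 on
#'   the opposite strand, as sequenced).
#' @param construct The `Construct` defining the amplicon.
#' @return A list with `insert` (character, `NA` where rejected) and
#'   `reject` (character reason: `flank_mismatch`, `overlap_conflict`,
#'   `length_mismatch`, or `NA` for accepted pairs).
#' @export
extract_spans <- function(r1, r2, construct) {
  stopifnot(length(r1) == length(r2))
  amp_len <- nchar(construct$upstream_flank) + nchar(construct$dna) +
    nchar(construct$downstream_flank)
  n <- length(r1)
  reject <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  if (n == 0) return(list(insert = insert, reject = reject))
  rl <- nchar(r1[1])
  ok <- nchar(r1) == rl & nchar(r2) == rl
  if (rl > amp_len || 2L * rl < amp_len)
    stop("read length incompatible with amplicon layout")
  reject[!ok] <- "length_mismatch"
  r2f <- degenerate_revcomp(r2)           # mate 2 on forward strand
  overlap <- 2L * rl - amp_len
  # forward-strand coordinates: r1 covers [1, rl], r2f covers [amp_len-rl+1, amp_len]
  conf <- ok & substr(r1, amp_len - rl + 1L, rl) != substr(r2f, 1L, overlap)
  reject[conf] <- "overlap_conflict"
  ok <- ok & !conf
  merged <- paste0(r1, substring(r2f, overlap + 1L))
  up <- construct$upstream_flank
  down <- construct$downstream_flank
  flank_ok <- startsWith(merged, up) & endsWith(merged, down)
  reject[ok & !flank_ok] <- "flank_mismatch"
  ok <- ok & flank_ok
  insert[ok] <- substr(merged[ok], nchar(up) + 1L, amp_len - nchar(down))
  list(insert = insert, reject = reject)
}

#' @rdname extract_spans
#' @export
extract_span <- function(r1, r2, construct) {
  res <- extract_spans(r1, r2, construct)
  if (is.na(res$insert)) res$reject else res$insert
}

#' Classify an insert sequence as wild type, a single variant, or a reject
#'
#' Translates the in-frame insert and compares it with the construct
#' protein: zero amino-acid differences count as wild type (synonymous
#' codon changes collapse), exactly one difference at a scanned position is
#' that variant, and everything else is rejected (`multi_mutant`, `stop`,
#' `outside_span`, `frame`).
#'
#' @param insert Character vector of insert DNA sequences.
#' @param construct The `Construct`.
#' @return Data frame with columns `position`, `aa`, `class` (one of
#'   `wildtype`, `variant`, or a reject reason).
#' @export
classify_variants <- function(insert, construct) {
  n <- length(insert)
  out <- data.frame(position = rep(NA_integer_, n),
                    aa = rep(NA_character_, n),
                    class = rep(NA_character_, n))
  if (n == 0) return(out)
  known <- !is.na(insert)
  bad_frame <- known & nchar(insert) %% 3L != 0L
  out$class[bad_frame] <- "frame"
  idx <- which(known & !bad_frame)
  if (!length(idx)) return(out)
  # translate unique inserts once; real data are highly redundant
  uniq <- unique(insert[idx])
  prot <- translate_dna(uniq)
  wt_prot <- construct$protein
  span_idx <- residue_index(construct, span_positions(construct))
  cls <- character(length(uniq))
  pos <- rep(NA_integer_, length(uniq))
  aa <- rep(NA_character_, length(uniq))
  wt_chars <- strsplit(wt_prot, "")[[1]]
  for (k in seq_along(uniq)) {
    p <- prot[k]
    if (nchar(p) != nchar(wt_prot)) { cls[k] <- "frame"; next }
    if (grepl("*", p, fixed = TRUE)) { cls[k] <- "stop"; next }
    d <- which(strsplit(p, "")[[1]] != wt_chars)
    if (length(d) == 0L) {
      cls[k] <- "wildtype"
    } else if (length(d) > 1L) {
      cls[k] <- "multi_mutant"
    } else if (!(d %in% span_idx)) {
      cls[k] <- "outside_span"
    } else {
      cls[k] <- "variant"
      pos[k] <- construct$numbering_offset + d
      aa[k] <- substr(p, d, d)
    }
  }
  m <- match(insert[idx], uniq)
  out$class[idx] <- cls[m]
  out$position[idx] <- pos[m]
  out$aa[idx] <- aa[m]
  out
}

#' @rdname classify_variants
#' @export
classify_variant <- function(insert, construct) {
  classify_variants(insert, construct)[1, ]
}

#' Count variants in a paired-end FASTQ population
#'
#' Runs [extract_spans()] and [classify_variants()] over all read pairs and
#' aggregates a `CountTable`; rejected pairs are tallied by reason in the
#' QC record. Counting is order-independent.
#'
#' @param r1_path,r2_path FASTQ files (optionally gzipped).
#' @param construct The `Construct`.
#' @param population Population label for the table.
#' @return A `CountTable`.
#' @export
count_population <- function(r1_path, r2_path, construct,
                             population = "reference") {
  r1 <- as.character(Biostrings::readDNAStringSet(r1_path, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(r2_path, format = "fastq"))
  if (length(r1) != length(r2))
    stop("mate files have different read counts")
  n <- length(r1)
  if (n == 0) warning("empty FASTQ input; returning empty table")
  pos <- span_positions(construct)
  m <- matrix(0, length(pos), 20L,
              dimnames = list(as.character(pos), AA20))
  wt_count <- 0
  rejects <- integer()
  if (n > 0) {
    sp <- extract_spans(r1, r2, construct)
    cl <- classify_variants(ifelse(is.na(sp$reject), sp$insert, NA),
                            construct)
    cl$class[!is.na(sp$reject)] <- sp$reject[!is.na(sp$reject)]
    is_var <- cl$class %in% "variant"
    if (any(is_var)) {
      tab <- table(factor(cl$position[is_var], levels = pos),
                   factor(cl$aa[is_var], levels = AA20))
      m <- m + unclass(tab)
    }
    wt_count <- sum(cl$class %in% "wildtype")
    rej <- cl$class[!cl$class %in% c("variant", "wildtype")]
    rejects <- if (length(rej)) table(rej) else integer()
  }
  wt <- wildtype_aa(construct)
  m[cbind(seq_along(pos), match(wt, AA20))] <- NA
  count_table(construct, m, wt_count, population = population,
              n_reads_total = n,
              n_reads_passing = as.integer(sum(m, na.rm = TRUE) + wt_count),
              rejects = rejects)
}

#' Mask variants with insufficient reference counts
#'
#' Variants seen fewer than `min_count` times in the reference population
#' are eliminated from all downstream analyses (the landscape's gray
#' tiles). Wild-type identity cells are never masked. Masking is monotone
#' in `min_count`.
#'
#' @param reference The reference `CountTable`.
#' @param min_count Minimum reference count to keep a variant (default
#'   100).
#' @return Logical positions x 20 matrix, `TRUE` where the variant is
#'   eliminated (`NA`-free; wild-type cells `FALSE`), with attribute
#'   `n_surviving` = surviving grid cells out of `20 * n_positions`
#'   (wild-type cells counted as surviving when the wild-type pool itself
#'   passes the threshold).
#' @export
apply_reference_filter <- function(reference, min_count = 100) {
  m <- reference$counts
  mask <- !is.na(m) & m < min_count
  wt_cells <- is.na(m)
  n_surv <- sum(!mask & !wt_cells) +
    sum(wt_cells) * (reference$wildtype_count >= min_count)
  attr(mask, "n_surviving") <- as.integer(n_surv)
  attr(mask, "min_count") <- min_count
  mask
}

#' QC report for a counted population
#' @param x A `CountTable`.
#' @return A list with totals, pass fraction and reject breakdown.
#' @export
qc_report <- function(x) {
  list(population = x$population,
       n_reads_total = x$n_reads_total,
       n_reads_passing = x$n_reads_passing,
       pass_fraction = if (is.na(x$n_reads_total) || x$n_reads_total == 0)
         NA_real_ else x$n_reads_passing / x$n_reads_total,
       rejects = as.list(x$rejects))
}
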