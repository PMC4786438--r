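#' Per-variant read-count table for one population
#'
#' Holds read counts for every single-amino-acid variant of a scanned
#' segment as a positions x 20 matrix, plus the wild-type count. Wild-type
#' identity cells carry `NA` in the matrix: at the DNA level a wild-type
#' identity variant is indistinguishable from (and counted with) the wild
#' type, whose pooled count is `wildtype_count`.
#'
#' @param construct The `Construct` the counts refer to.
#' @param counts Numeric matrix, rows = scanned positions (rownames are
#'   residue numbers), columns = the 20 amino acids; wild-type identity
#'   cells `NA`.
#' @param wildtype_count Total reads classified as wild type (including
#'   synonymous codon changes).
#' @param population One of `"reference"`, `"insertion-selected"`,
#'   `"association-selected"`.
#' @param n_reads_total,n_reads_passing Read-pair QC accounting.
#' @param rejects Named integer vector of reject reasons (optional).
#' @return An object of class `CountTable`.
#' @export
count_table <- function(construct, counts, wildtype_count,
                        population = c("reference", "insertion-selected",
                                       "association-selected"),
                        n_reads_total = NA_integer_,
                        n_reads_passing = NA_integer_,
                        rejects = integer()) {
  population <- match.arg(population)
  pos <- span_positions(construct)
  stopifnot(is.matrix(counts), nrow(counts) == length(pos),
            ncol(counts) == 20L)
  rownames(counts) <- as.character(pos)
  colnames(counts) <- AA20
  wt <- wildtype_aa(construct)
  for (i in seq_along(pos)) {
    if (!is.na(counts[i, wt[i]]))
      stop("wild-type identity cell must be NA at position ", pos[i])
  }
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts")
  obj <- list(construct_name = construct$name,
              positions = pos, wt_aa = wt,
              counts = counts,
              wildtype_count = as.numeric(wildtype_count),
              population = population,
              n_reads_total = n_reads_total,
              n_reads_passing = n_reads_passing,
              rejects = rejects)
  class(obj) <- "CountTable"
  obj
}

#' @export
print.CountTable <- function(x, ...) {
  cat("CountTable [", x$population, "] construct", x$construct_name, "\n")
  cat("  positions:", length(x$positions),
      " variant reads:", sum(x$counts, na.rm = TRUE),
      " wild-type reads:", x$wildtype_count, "\n")
  if (!is.na(x$n_reads_total))
    cat("  QC: ", x$n_reads_passing, "/", x$n_reads_total, " pairs passed\n")
  invisible(x)
}

# total classified depth (variant + wild-type reads)
total_counts <- function(x) sum(x$counts, na.rm = TRUE) + x$wildtype_count

check_same_universe <- function(a, b) {
  if (!identical(a$positions, b$positions) ||
      !identical(a$wt_aa, b$wt_aa))
    stop("count tables cover different variant universes")
  invisible(TRUE)
}

#' Write / read a count table as TSV
#'
#' Long format with columns `population`, `position`, `wt_aa`, `mut_aa`,
#' `count`; the wild-type pool is the row with `mut_aa == wt_aa`.
#'
#' @param x A `CountTable`.
#' @param path Output (input) file.
#' @param construct For reading: the `Construct` the table refers to.
#' @return `write_counts_tsv` returns `path`; `read_counts_tsv` a
#'   `CountTable`.
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(population = x$population,
                   position = rep(x$positions, each = 20L),
                   wt_aa = rep(x$wt_aa, each = 20L),
                   mut_aa = rep(AA20, length(x$positions)),
                   count = as.vector(t(x$counts)))
  df$count[df$mut_aa == df$wt_aa] <- NA
  wtrow <- data.frame(population = x$population, position = NA,
                      wt_aa = "WT", mut_aa = "WT",
                      count = x$wildtype_count)
  df <- rbind(wtrow, df[!is.na(df$count), ])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, construct) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  wtrow <- df$mut_aa == "WT"
  wt_count <- df$count[wtrow]
  df <- df[!wtrow, ]
  pos <- span_positions(construct)
  m <- matrix(0, length(pos), 20L,
              dimnames = list(as.character(pos), AA20))
  m[cbind(match(df$position, pos), match(df$mut_aa, AA20))] <- df$count
  wt <- wildtype_aa(construct)
  m[cbind(seq_along(pos), match(wt, AA20))] <- NA
  count_table(construct, m, wt_count,
              population = unique(df$population)[1])
}
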