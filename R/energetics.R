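#' Wild-type-normalized variant frequencies
#'
#' `p[i, j] = count[i, j] / count_wildtype`; wild-type identity cells are 1
#' by definition. Frequencies are invariant to duplicating every read.
#'
#' @param x A `CountTable` with a positive wild-type count.
#' @return Positions x 20 numeric matrix.
#' @export
frequencies <- function(x) {
  if (is.na(x$wildtype_count) || x$wildtype_count <= 0)
    stop("wild-type count is zero; no landscape derivable")
  p <- x$counts / x$wildtype_count
  p[is.na(x$counts)] <- 1
  p
}

#' Selection coefficients from selected and reference populations
#'
#' `s[i, j]` is the ratio of wild-type-normalized frequencies, selected
#' over reference. Wild type has s = 1 identically. Variants with zero
#' selected reads get s = 0 and are flagged censored (their free energies
#' are lower bounds); variants masked by the reference filter carry `NA`.
#'
#' @param selected,reference `CountTable`s over the same variant universe.
#' @param mask Optional logical elimination matrix from
#'   [apply_reference_filter()].
#' @return A list of class `SelectionCoefficients` with `s`, `censored`,
#'   `mask` matrices and the population labels.
#' @export
selection_coefficients <- function(selected, reference, mask = NULL) {
  check_same_universe(selected, reference)
  if (is.null(mask))
    mask <- matrix(FALSE, nrow(reference$counts), ncol(reference$counts),
                   dimnames = dimnames(reference$counts))
  p_sel <- frequencies(selected)
  p_ref <- frequencies(reference)
  wt_cells <- is.na(reference$counts)
  if (any(p_ref == 0 & !mask & !wt_cells, na.rm = TRUE))
    stop("reference frequency 0 for an unmasked variant; ",
         "apply_reference_filter first")
  s <- p_sel / p_ref
  s[mask] <- NA
  censored <- !wt_cells & !mask & !is.na(selected$counts) &
    selected$counts == 0
  structure(list(s = s, censored = censored, mask = mask,
                 positions = reference$positions, wt_aa = reference$wt_aa,
                 selected_population = selected$population,
                 reference_population = reference$population,
                 selected_counts = selected$counts,
                 selected_wildtype_count = selected$wildtype_count,
                 p_ref = p_ref),
            class = "SelectionCoefficients")
}

#' Apparent free-energy landscape from selection coefficients
#'
#' The Gibbs relation `ddG = -RT * ln(s)` with R = 1.9872e-3 kcal/(mol K)
#' and T = 310 K by default (RT = 0.616032 kcal/mol). Censored variants
#' (zero selected reads) are assigned the value obtained by replacing the
#' zero with `pseudocount` reads, and flagged: the stored value is a lower
#' bound on the true penalty.
#'
#' @param sc A `SelectionCoefficients` object.
#' @param temperature Absolute temperature in K (default 310).
#' @param pseudocount Reads substituted for zero selected counts (default
#'   1).
#' @return An object of class `EnergyLandscape` with matrices `ddg`,
#'   `mask`, `censored`.
#' @export
to_ddg <- function(sc, temperature = 310, pseudocount = 1) {
  rt <- rt_kcal(temperature)
  s <- sc$s
  cens <- sc$censored
  if (any(cens)) {
    s_floor <- (pseudocount / sc$selected_wildtype_count) / sc$p_ref
    s[cens] <- s_floor[cens]
  }
  ddg <- -rt * log(s)
  wt_cells <- is.na(sc$selected_counts) & !sc$mask
  ddg[wt_cells] <- 0
  obj <- list(ddg = ddg, mask = sc$mask, censored = cens,
              positions = sc$positions, wt_aa = sc$wt_aa,
              temperature = temperature,
              selected_population = sc$selected_population,
              reference_population = sc$reference_population,
              relative_to = "wildtype")
  class(obj) <- "EnergyLandscape"
  obj
}

#' @export
print.EnergyLandscape <- function(x, ...) {
  cat("EnergyLandscape (", x$selected_population, "vs",
      x$reference_population, "), relative to", x$relative_to, "\n")
  cat("  positions:", length(x$positions),
      " masked:", sum(x$mask),
      " censored:", sum(x$censored), "\n")
  invisible(x)
}

#' Extract one variant's apparent free energy
#' @param x An `EnergyLandscape`.
#' @param position Residue position (paper numbering).
#' @param aa Substituting amino acid (one letter).
#' @return ddG in kcal/mol (NA if masked).
#' @export
ddg_at <- function(x, position, aa) {
  x$ddg[as.character(position), aa]
}

#' Re-reference a landscape to substitutions to Ala
#'
#' `ddg'[i, j] = ddg[i, j] - ddg[i, Ala]`; the Ala column becomes 0.
#' Positions where Ala itself is masked cannot be re-referenced and are
#' dropped (all `NA`) with a warning.
#'
#' @param x An `EnergyLandscape` relative to wild type.
#' @return An `EnergyLandscape` with `relative_to = "Ala"`.
#' @export
relative_to_ala <- function(x) {
  stopifnot(inherits(x, "EnergyLandscape"))
  ala <- x$ddg[, "A"]
  ala_bad <- is.na(ala)
  if (any(ala_bad))
    warning("Ala masked at position(s) ",
            paste(x$positions[ala_bad], collapse = ", "),
            "; dropped from Ala-relative landscape")
  out <- x
  out$ddg <- x$ddg - ala
  out$ddg[ala_bad, ] <- NA
  out$relative_to <- "Ala"
  out
}

#' Running average over neighbouring positions
#'
#' Centered moving average with a window of `window` residues (default 5,
#' two on each side). Masked values (`NA`) are excluded from the average;
#' near the series ends the window shrinks symmetrically. A fully masked
#' window yields `NA`.
#'
#' @param x Numeric vector ordered by position (`NA` = masked/excluded).
#' @param window Odd window size (default 5).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(x, window = 5L) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    v <- x[(i - h):(i + h)]
    if (all(is.na(v))) next
    out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

# smoothed Ala-relative values for one amino acid, with exclusions applied
smoothed_series <- function(landscape, aa, excluded = integer(),
                            window = 5L) {
  v <- landscape$ddg[, aa]
  v[landscape$positions %in% excluded] <- NA
  smooth_profile(v, window)
}

#' Estimate the membrane mid-plane position
#'
#' Aligns the smoothed profiles of the hydrophobic residues (Leu, Ile, Met,
#' Phe) and returns the scanned position at the trough of their mean — the
#' presumed membrane mid-plane.
#'
#' @param landscape An Ala-relative `EnergyLandscape`.
#' @param window Smoothing window (default 5).
#' @param residues Hydrophobic profile set (default L, I, M, F).
#' @return Residue position (paper numbering) of the trough.
#' @export
estimate_midplane <- function(landscape, window = 5L,
                              residues = c("L", "I", "M", "F")) {
  prof <- vapply(residues, function(a)
    smoothed_series(landscape, a, window = window),
    numeric(length(landscape$positions)))
  usable <- colSums(!is.na(prof)) >= 3L
  if (sum(usable) < 2L)
    stop("fewer than 2 usable hydrophobic profiles; cannot locate mid-plane")
  m <- rowMeans(prof[, usable, drop = FALSE], na.rm = TRUE)
  landscape$positions[which.min(m)]
}

#' Fit per-amino-acid insertion profiles over membrane depth
#'
#' Converts positions to depth `Z = (position - midplane) * rise`
#' (cytoplasm at negative Z), smooths each amino acid's Ala-relative values
#' over `window` residues, drops excluded positions, and fits a 4th-order
#' polynomial per amino acid by least squares. Amino acids with fewer than
#' 6 usable points are flagged unfit. The Ala profile is identically zero.
#'
#' @param landscape An Ala-relative `EnergyLandscape`.
#' @param midplane Mid-plane position from [estimate_midplane()].
#' @param rise Helical rise per residue in angstrom (default 1.5).
#' @param excluded Positions dropped from the fits (helix-distorting
#'   outliers; default the CLS pair 307, 308 when they lie in the span,
#'   otherwise none).
#' @param window Smoothing window (default 5).
#' @param z_fit_window Depth interval (angstrom) over which the
#'   polynomials are fitted; positions outside it (beyond the bilayer,
#'   where profiles plateau) are excluded so the quartic describes the
#'   membrane interior. Default `c(-15, 15)`.
#' @return An object of class `InsertionProfile`: coefficient matrix
#'   `coefficients` (20 x 5, `c0`..`c4` in powers of Z), smoothed `points`,
#'   `midplane`, `rise`, `zrange`, `excluded`, `unfit`.
#' @export
fit_profiles <- function(landscape, midplane, rise = 1.5,
                         excluded = NULL, window = 5L,
                         z_fit_window = c(-15, 15)) {
  stopifnot(identical(landscape$relative_to, "Ala"))
  pos <- landscape$positions
  if (is.null(excluded)) excluded <- intersect(c(307L, 308L), pos)
  z <- (pos - midplane) * rise
  in_mem <- z >= z_fit_window[1] & z <= z_fit_window[2]
  co <- matrix(NA_real_, 20L, 5L, dimnames = list(AA20, paste0("c", 0:4)))
  pts <- list()
  unfit <- character(0)
  for (aa in AA20) {
    v <- smoothed_series(landscape, aa, excluded = excluded,
                         window = window)
    keep <- !is.na(v) & !(pos %in% excluded) & in_mem
    pts[[aa]] <- data.frame(position = pos[keep], z = z[keep],
                            value = v[keep])
    if (aa == "A") { co[aa, ] <- 0; next }
    if (sum(keep) < 6L) { unfit <- c(unfit, aa); next }
    fit <- lm(v[keep] ~ poly(z[keep], 4, raw = TRUE))
    co[aa, ] <- unname(coef(fit))
  }
  obj <- list(coefficients = co, points = pts, midplane = midplane,
              rise = rise,
              zrange = range(z[!(pos %in% excluded) & in_mem]),
              excluded = excluded, unfit = unfit, window = window)
  class(obj) <- "InsertionProfile"
  obj
}

#' Evaluate an insertion profile polynomial
#' @param profile An `InsertionProfile`.
#' @param aa One-letter amino acid(s).
#' @param z Membrane depth(s) in angstrom.
#' @param warn_extrapolation Warn when `z` leaves the fitted range.
#' @return Ala-relative insertion energy in kcal/mol.
#' @export
evaluate_profile <- function(profile, aa, z, warn_extrapolation = FALSE) {
  if (warn_extrapolation &&
      any(z < profile$zrange[1] | z > profile$zrange[2]))
    warning("evaluating insertion profile outside fitted Z range")
  co <- profile$coefficients[aa, , drop = FALSE]
  as.vector(co[, 1] + co[, 2] * z + co[, 3] * z^2 + co[, 4] * z^3 +
              co[, 5] * z^4)
}

#' Boltzmann amino-acid propensities per position
#'
#' `p[i, j] = exp(-E[i, j]/RT) / sum_x exp(-E[i, x]/RT)` over the 20 amino
#' acids at each position. Censored energies enter at their stored lower
#' bounds. Rows sum to 1; propensities are invariant to per-position
#' constant shifts of the energies.
#'
#' @param landscape An `EnergyLandscape` (any reference state; the
#'   normalization removes per-position offsets). Masked cells are treated
#'   as missing and excluded from the normalization.
#' @param temperature Absolute temperature in K (default 310).
#' @return Positions x 20 probability matrix (class `PropensityTable`).
#' @export
propensities <- function(landscape, temperature = 310) {
  rt <- rt_kcal(temperature)
  e <- landscape$ddg
  w <- exp(-(e - apply(e, 1, min, na.rm = TRUE)) / rt)
  p <- w / rowSums(w, na.rm = TRUE)
  class(p) <- c("PropensityTable", class(p))
  p
}

#' Write an energy landscape as TSV
#' @param x An `EnergyLandscape`.
#' @param path Output file.
#' @export
write_landscape_tsv <- function(x, path) {
  df <- data.frame(position = rep(x$positions, each = 20L),
                   wt_aa = rep(x$wt_aa, each = 20L),
                   mut_aa = rep(AA20, length(x$positions)),
                   ddg = as.vector(t(x$ddg)),
                   masked = as.vector(t(x$mask)),
                   censored = as.vector(t(x$censored)))
  write.table(format(df, digits = 10), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read insertion-profile polynomial coefficients as JSON
#' @param profile An `InsertionProfile`.
#' @param path File path.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(list(midplane = profile$midplane,
                            rise = profile$rise,
                            zrange = profile$zrange,
                            excluded = profile$excluded,
                            unfit = profile$unfit,
                            coefficients = as.data.frame(profile$coefficients)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- as.matrix(j$coefficients)
  rownames(co) <- AA20
  obj <- list(coefficients = co, points = NULL, midplane = j$midplane,
              rise = j$rise, zrange = j$zrange,
              excluded = unlist(j$excluded),
              unfit = unlist(j$unfit), window = NA)
  class(obj) <- "InsertionProfile"
  obj
}

#' Write a propensity table in position-weight-matrix layout
#'
#' Rows are amino acids, columns are positions — the transposed-matrix text
#' layout sequence-logo tools consume.
#'
#' @param p A `PropensityTable`.
#' @param path Output file.
#' @export
write_propensity_matrix <- function(p, path) {
  m <- t(unclass(p))
  df <- data.frame(aa = rownames(m), m, check.names = FALSE)
  write.table(format(df, digits = 8), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
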