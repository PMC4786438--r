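#' Insertion-corrected self-association landscape
#'
#' A mutation's measured effect on homodimer-dependent survival contains
#' its effect on monomer insertion twice (both protomers carry it). The
#' dimerization component is recovered by subtracting twice the insertion
#' contribution at the mutation's membrane depth:
#' `ddG_dimerization = ddG_measured - 2 * ddG_insertion`, where
#' `ddG_insertion(i -> j at Z) = P_j(Z) - P_i(Z)` from the insertion-profile
#' polynomials (the Ala reference cancels in the difference).
#'
#' @param measured Wild-type-relative `EnergyLandscape` from the
#'   association selection (amp+cam over amp).
#' @param profile An `InsertionProfile` (fitted on the monomeric scan).
#' @param midplane Mid-plane position of *this* construct's span.
#' @param rise Helical rise per residue (default 1.5 angstrom).
#' @return An object of class `DimerLandscape` with matrices
#'   `ddg_measured`, `ddg_insertion_used`, `ddg_dimerization`,
#'   `extrapolated`, plus inherited `mask`/`censored`.
#' @export
correct_dimerization <- function(measured, profile, midplane, rise = 1.5) {
  stopifnot(inherits(measured, "EnergyLandscape"),
            inherits(profile, "InsertionProfile"),
            identical(measured$relative_to, "wildtype"))
  pos <- measured$positions
  z <- (pos - midplane) * rise
  ins <- matrix(NA_real_, length(pos), 20L,
                dimnames = dimnames(measured$ddg))
  # evaluate_profile pairs aa and z elementwise when both are vectors,
  # giving the wild-type profile at each position's own depth
  pw <- evaluate_profile(profile, measured$wt_aa, z)
  for (j in AA20) ins[, j] <- evaluate_profile(profile, j, z) - pw
  extrap <- matrix(z < profile$zrange[1] | z > profile$zrange[2],
                   length(pos), 20L, dimnames = dimnames(measured$ddg))
  unfit <- union(profile$unfit, character(0))
  if (length(unfit)) ins[, intersect(unfit, colnames(ins))] <- NA
  dim_ddg <- measured$ddg - 2 * ins
  obj <- list(ddg_measured = measured$ddg,
              ddg_insertion_used = ins,
              ddg_dimerization = dim_ddg,
              extrapolated = extrap,
              mask = measured$mask, censored = measured$censored,
              positions = pos, wt_aa = measured$wt_aa,
              midplane = midplane, rise = rise)
  class(obj) <- "DimerLandscape"
  obj
}

#' @export
print.DimerLandscape <- function(x, ...) {
  cat("DimerLandscape:", length(x$positions), "positions; ",
      sum(x$mask), "masked,", sum(x$censored), "censored\n")
  invisible(x)
}

#' Classify positions as likely/unlikely to mediate binding
#'
#' A position is *likely mediating binding* when at least
#' `min_substitutions` substitutions from wild type disrupt binding by at
#' least `disrupt_threshold` kcal/mol; *unlikely* when at least
#' `min_substitutions` substitutions improve or do not change binding
#' (within `neutral_tol`); positions meeting both or neither condition are
#' *indeterminate* (conservative precedence).
#'
#' @param dimer A `DimerLandscape`.
#' @param disrupt_threshold Disruption threshold in kcal/mol (default 2).
#' @param min_substitutions Minimum qualifying substitutions (default 4).
#' @param neutral_tol Tolerance for "did not change" in kcal/mol (default
#'   0.2).
#' @return Data frame with `position`, `label`, `n_disruptive`,
#'   `n_neutral_or_better`.
#' @export
classify_positions <- function(dimer, disrupt_threshold = 2,
                               min_substitutions = 4L, neutral_tol = 0.2) {
  stopifnot(inherits(dimer, "DimerLandscape"))
  d <- dimer$ddg_dimerization
  d[dimer$mask] <- NA
  n_dis <- rowSums(d >= disrupt_threshold, na.rm = TRUE)
  n_neu <- rowSums(d <= neutral_tol & !dimer$censored, na.rm = TRUE)
  likely <- n_dis >= min_substitutions
  unlikely <- n_neu >= min_substitutions
  label <- ifelse(likely & !unlikely, "likely_mediating_binding",
           ifelse(unlikely & !likely, "unlikely_mediating_binding",
                  "indeterminate"))
  data.frame(position = dimer$positions, label = label,
             n_disruptive = as.integer(n_dis),
             n_neutral_or_better = as.integer(n_neu))
}

# minimum heavy-atom distance from each labelled residue of one chain to
# any heavy atom of the partner chain
.cross_chain_min_dist <- function(atoms, chain, positions) {
  own <- atoms[atoms$chain == chain & atoms$element != "H", ]
  partner <- atoms[atoms$chain != chain & atoms$element != "H", ]
  pm <- as.matrix(partner[, c("x", "y", "z")])
  vapply(positions, function(p) {
    om <- as.matrix(own[own$resno == p, c("x", "y", "z"), drop = FALSE])
    if (!nrow(om)) return(NA_real_)
    d2 <- outer(rowSums(om^2), rowSums(pm^2), `+`) - 2 * om %*% t(pm)
    sqrt(max(0, min(d2)))
  }, 0)
}

#' Filter candidate homodimer models against mutational constraints
#'
#' A C2 homodimer model is accepted when at least `min_likely_contacts`
#' of the *likely mediating binding* positions have any heavy atom within
#' `likely_shell` of the partner protomer, and no *unlikely* position has
#' a heavy atom within `unlikely_shell` of the partner.
#'
#' @param models A list of ATOM data frames ([read_pdb()] layout) or a
#'   character vector of PDB paths.
#' @param labels Data frame from [classify_positions()] (`position`,
#'   `label`).
#' @param likely_shell Contact shell for likely positions (default 5
#'   angstrom).
#' @param unlikely_shell Exclusion shell for unlikely positions (default 4
#'   angstrom).
#' @param min_likely_contacts Minimum likely positions in contact (default
#'   2).
#' @return Data frame with one row per model: `model`, `accepted`,
#'   `n_likely_contacts`, `unlikely_violation`, `reason`.
#' @export
filter_dimer_models <- function(models, labels, likely_shell = 5,
                                unlikely_shell = 4,
                                min_likely_contacts = 2L) {
  if (is.character(models)) {
    names_ <- models
    models <- lapply(models, read_pdb)
  } else {
    names_ <- names(models) %||% paste0("model_", seq_along(models))
  }
  likely <- labels$position[labels$label == "likely_mediating_binding"]
  unlikely <- labels$position[labels$label == "unlikely_mediating_binding"]
  out <- lapply(seq_along(models), function(k) {
    atoms <- models[[k]]
    chains <- unique(atoms$chain)
    if (length(chains) != 2L)
      return(data.frame(model = names_[k], accepted = FALSE,
                        n_likely_contacts = NA_integer_,
                        unlikely_violation = NA,
                        reason = "chain_count"))
    seqs <- lapply(chains, function(ch) {
      a <- atoms[atoms$chain == ch & atoms$atom == "CA", ]
      a$resname[order(a$resno)]
    })
    if (!identical(seqs[[1]], seqs[[2]]))
      return(data.frame(model = names_[k], accepted = FALSE,
                        n_likely_contacts = NA_integer_,
                        unlikely_violation = NA,
                        reason = "sequence_mismatch"))
    # C2 symmetry: shells measured from chain A (equivalently B)
    dl <- .cross_chain_min_dist(atoms, chains[1], likely)
    du <- .cross_chain_min_dist(atoms, chains[1], unlikely)
    n_contact <- sum(dl <= likely_shell, na.rm = TRUE)
    violation <- any(du <= unlikely_shell, na.rm = TRUE)
    ok <- n_contact >= min_likely_contacts && !violation
    data.frame(model = names_[k], accepted = ok,
               n_likely_contacts = n_contact,
               unlikely_violation = violation,
               reason = if (ok) "pass"
                        else if (violation) "unlikely_in_shell"
                        else "too_few_likely_contacts")
  })
  do.call(rbind, out)
}

#' Write dimer landscape / labels as TSV
#' @param x A `DimerLandscape` or the label data frame.
#' @param path Output file.
#' @export
write_dimer_tsv <- function(x, path) {
  if (inherits(x, "DimerLandscape")) {
    df <- data.frame(position = rep(x$positions, each = 20L),
                     wt_aa = rep(x$wt_aa, each = 20L),
                     mut_aa = rep(AA20, length(x$positions)),
                     ddg_measured = as.vector(t(x$ddg_measured)),
                     ddg_insertion = as.vector(t(x$ddg_insertion_used)),
                     ddg_dimerization = as.vector(t(x$ddg_dimerization)),
                     masked = as.vector(t(x$mask)),
                     censored = as.vector(t(x$censored)),
                     extrapolated = as.vector(t(x$extrapolated)))
    write.table(format(df, digits = 10), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
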