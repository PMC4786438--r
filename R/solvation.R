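# ---- ideal-geometry helix models -------------------------------------------
#
# Residues are built atom by atom from internal coordinates (NeRF): each
# atom D is placed from three previously placed atoms A-B-C by bond length
# r(C-D), bond angle theta(B-C-D) and dihedral phi(A-B-C-D). The backbone
# uses canonical alpha-helix torsions (phi = -57, psi = -47, omega = 180)
# and standard bond geometry; side chains use fixed default rotamers
# (chi1 = -65, later chis staggered/planar), a documented approximation to
# repacked side chains.

.place_atom <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- -r * cos(theta) * bc +
    r * sin(theta) * (cos(phi) * m + sin(phi) * n)
  c + d
}

# side-chain topology: atom, element, reference atoms (A, B, C), bond,
# angle, dihedral (expression in chi1..chi4)
.sidechain_topology <- list(
  G = NULL,
  A = NULL,  # CB placed for every non-Gly residue
  S = list(c("OG", "O", "N", "CA", "CB", "1.417", "110.8", "chi1")),
  C = list(c("SG", "S", "N", "CA", "CB", "1.808", "114.4", "chi1")),
  T = list(c("OG1", "O", "N", "CA", "CB", "1.433", "109.5", "chi1"),
           c("CG2", "C", "N", "CA", "CB", "1.521", "110.5", "chi1 + 120")),
  V = list(c("CG1", "C", "N", "CA", "CB", "1.527", "110.5", "chi1"),
           c("CG2", "C", "N", "CA", "CB", "1.527", "110.5", "chi1 + 122")),
  L = list(c("CG", "C", "N", "CA", "CB", "1.530", "116.3", "chi1"),
           c("CD1", "C", "CA", "CB", "CG", "1.521", "110.7", "chi2"),
           c("CD2", "C", "CA", "CB", "CG", "1.521", "110.7", "chi2 + 122")),
  I = list(c("CG1", "C", "N", "CA", "CB", "1.530", "110.4", "chi1"),
           c("CG2", "C", "N", "CA", "CB", "1.521", "110.5", "chi1 - 122"),
           c("CD1", "C", "CA", "CB", "CG1", "1.513", "113.8", "chi2")),
  M = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("SD", "S", "CA", "CB", "CG", "1.803", "112.7", "chi2"),
           c("CE", "C", "CB", "CG", "SD", "1.791", "100.6", "chi3")),
  P = list(c("CG", "C", "N", "CA", "CB", "1.492", "104.5", "30"),
           c("CD", "C", "CA", "CB", "CG", "1.503", "105.5", "-35")),
  F = list(c("CG", "C", "N", "CA", "CB", "1.502", "113.8", "chi1"),
           c("CD1", "C", "CA", "CB", "CG", "1.384", "120.8", "chi2"),
           c("CD2", "C", "CA", "CB", "CG", "1.384", "120.8", "chi2 + 180"),
           c("CE1", "C", "CB", "CG", "CD1", "1.382", "120.8", "180"),
           c("CE2", "C", "CB", "CG", "CD2", "1.382", "120.8", "180"),
           c("CZ", "C", "CG", "CD1", "CE1", "1.382", "120.0", "0")),
  Y = list(c("CG", "C", "N", "CA", "CB", "1.512", "113.9", "chi1"),
           c("CD1", "C", "CA", "CB", "CG", "1.389", "120.8", "chi2"),
           c("CD2", "C", "CA", "CB", "CG", "1.389", "120.8", "chi2 + 180"),
           c("CE1", "C", "CB", "CG", "CD1", "1.382", "121.2", "180"),
           c("CE2", "C", "CB", "CG", "CD2", "1.382", "121.2", "180"),
           c("CZ", "C", "CG", "CD1", "CE1", "1.378", "119.6", "0"),
           c("OH", "O", "CD1", "CE1", "CZ", "1.376", "119.9", "180")),
  W = list(c("CG", "C", "N", "CA", "CB", "1.498", "113.6", "chi1"),
           c("CD1", "C", "CA", "CB", "CG", "1.365", "126.9", "chi2"),
           c("CD2", "C", "CA", "CB", "CG", "1.433", "126.6", "chi2 + 180"),
           c("NE1", "N", "CB", "CG", "CD1", "1.374", "110.1", "180"),
           c("CE2", "C", "CB", "CG", "CD2", "1.409", "107.3", "180"),
           c("CE3", "C", "CB", "CG", "CD2", "1.398", "133.9", "0"),
           c("CZ2", "C", "CG", "CD2", "CE2", "1.394", "122.3", "180"),
           c("CZ3", "C", "CG", "CD2", "CE3", "1.382", "118.7", "180"),
           c("CH2", "C", "CD2", "CE2", "CZ2", "1.368", "117.4", "0")),
  D = list(c("CG", "C", "N", "CA", "CB", "1.516", "112.6", "chi1"),
           c("OD1", "O", "CA", "CB", "CG", "1.249", "118.4", "chi2"),
           c("OD2", "O", "CA", "CB", "CG", "1.249", "118.4", "chi2 + 180")),
  N = list(c("CG", "C", "N", "CA", "CB", "1.516", "112.6", "chi1"),
           c("OD1", "O", "CA", "CB", "CG", "1.231", "120.8", "chi2"),
           c("ND2", "N", "CA", "CB", "CG", "1.328", "116.4", "chi2 + 180")),
  E = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("CD", "C", "CA", "CB", "CG", "1.516", "112.6", "chi2"),
           c("OE1", "O", "CB", "CG", "CD", "1.249", "118.4", "chi3"),
           c("OE2", "O", "CB", "CG", "CD", "1.249", "118.4", "chi3 + 180")),
  Q = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("CD", "C", "CA", "CB", "CG", "1.516", "112.6", "chi2"),
           c("OE1", "O", "CB", "CG", "CD", "1.231", "120.8", "chi3"),
           c("NE2", "N", "CB", "CG", "CD", "1.328", "116.4", "chi3 + 180")),
  K = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("CD", "C", "CA", "CB", "CG", "1.520", "111.3", "chi2"),
           c("CE", "C", "CB", "CG", "CD", "1.520", "111.3", "chi3"),
           c("NZ", "N", "CG", "CD", "CE", "1.489", "111.9", "chi4")),
  R = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("CD", "C", "CA", "CB", "CG", "1.520", "111.3", "chi2"),
           c("NE", "N", "CB", "CG", "CD", "1.461", "112.0", "chi3"),
           c("CZ", "C", "CG", "CD", "NE", "1.329", "124.2", "chi4"),
           c("NH1", "N", "CD", "NE", "CZ", "1.326", "120.0", "0"),
           c("NH2", "N", "CD", "NE", "CZ", "1.326", "120.0", "180")),
  H = list(c("CG", "C", "N", "CA", "CB", "1.497", "113.8", "chi1"),
           c("ND1", "N", "CA", "CB", "CG", "1.378", "122.7", "chi2"),
           c("CD2", "C", "CA", "CB", "CG", "1.354", "131.2", "chi2 + 180"),
           c("CE1", "C", "CB", "CG", "ND1", "1.321", "109.2", "180"),
           c("NE2", "N", "CB", "CG", "CD2", "1.374", "107.2", "180"))
)

.default_chis <- c(chi1 = -65, chi2 = 180, chi3 = 180, chi4 = 180)
.aromatic_chi2 <- c(F = 90, Y = 90, W = 95, H = 90, D = 0, N = 0)

#' Build an ideal alpha-helix model of a sequence
#'
#' Threads a sequence on a canonical alpha helix (phi = -57, psi = -47,
#' omega = 180) with standard backbone geometry and side chains in fixed
#' default rotamers. Heavy atoms only.
#'
#' @param sequence One-letter amino-acid string (standard residues only).
#' @return An object of class `HelixModel`: a list with `atoms` (data
#'   frame: `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`) and
#'   `sequence`.
#' @export
build_helix <- function(sequence) {
  seq_aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(seq_aa %in% AA20))
    stop("non-standard residue(s): ",
         paste(unique(setdiff(seq_aa, AA20)), collapse = ", "))
  n <- length(seq_aa)
  phi <- -57; psi <- -47; omega <- 180
  rows <- vector("list", 0)
  coords <- list()  # named per residue: list of atom -> xyz
  add <- function(res, atom, element, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      resno = res, resname = unname(AA3[seq_aa[res]]), atom = atom,
      element = element, x = xyz[1], y = xyz[2], z = xyz[3])
    coords[[res]][[atom]] <<- xyz
  }
  for (i in seq_len(n)) {
    coords[[i]] <- list()
    if (i == 1) {
      ca <- c(1.458, 0, 0)
      th <- 111.2 * pi / 180
      add(1, "N", "N", c(0, 0, 0))
      add(1, "CA", "C", ca)
      add(1, "C", "C", ca + 1.525 * c(-cos(th), sin(th), 0))
    } else {
      p <- coords[[i - 1]]
      nn <- .place_atom(p$N, p$CA, p$C, 1.329, 116.2, psi)
      add(i, "N", "N", nn)
      ca <- .place_atom(p$CA, p$C, nn, 1.458, 121.7, omega)
      add(i, "CA", "C", ca)
      cc <- .place_atom(p$C, nn, ca, 1.525, 111.2, phi)
      add(i, "C", "C", cc)
      # carbonyl O of the previous residue, anti to this N's CA
      add(i - 1, "O", "O",
          .place_atom(nn, p$CA, p$C, 1.231, 120.5, 180))
    }
  }
  # last residue's O from its own psi
  p <- coords[[n]]
  add(n, "O", "O", .place_atom(p$N, p$CA, p$C, 1.231, 120.5, psi + 180))
  # side chains
  for (i in seq_len(n)) {
    aa <- seq_aa[i]
    if (aa == "G") next
    p <- coords[[i]]
    add(i, "CB", "C", .place_atom(p$N, p$C, p$CA, 1.530, 110.5, 122.6))
    topo <- .sidechain_topology[[aa]]
    if (is.null(topo)) next
    chis <- .default_chis
    if (aa %in% names(.aromatic_chi2)) chis["chi2"] <- .aromatic_chi2[[aa]]
    env <- as.list(chis)
    for (t in topo) {
      refs <- coords[[i]][t[3:5]]
      dih <- eval(parse(text = t[8]), envir = env)
      add(i, t[1], t[2],
          .place_atom(refs[[1]], refs[[2]], refs[[3]],
                      as.numeric(t[6]), as.numeric(t[7]), dih))
    }
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$resno), ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, sequence = paste(seq_aa, collapse = "")),
            class = "HelixModel")
}

#' @export
print.HelixModel <- function(x, ...) {
  cat("HelixModel:", nchar(x$sequence), "residues,",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Helix geometry diagnostics
#'
#' Fits the helix axis as the first principal component of the C-alpha
#' coordinates and reports consecutive C-alpha distances, rise per residue
#' (spacing of axial projections) and the axis-fit residual (sd of the
#' C-alpha radial distances; zero for a perfect helix).
#'
#' @param model A `HelixModel`.
#' @return List with `ca_ca`, `rise`, `axis_residual`, `radius`.
#' @export
helix_geometry <- function(model) {
  ca <- as.matrix(model$atoms[model$atoms$atom == "CA",
                              c("x", "y", "z")])
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] -
                     ca[-nrow(ca), , drop = FALSE])^2))
  ctr <- colMeans(ca)
  cc <- sweep(ca, 2, ctr)
  ax <- svd(cc)$v[, 1]
  proj <- as.vector(cc %*% ax)
  rad <- sqrt(rowSums((cc - outer(proj, ax))^2))
  list(ca_ca = d, rise = mean(abs(diff(sort(proj)))),
       axis_residual = stats::sd(rad), radius = mean(rad))
}

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# deterministic unit sphere sampling (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric SASA with a deterministic Fibonacci-lattice point set; van der
#' Waals radii C 1.70, N 1.55, O 1.52, S 1.80 angstrom.
#'
#' @param model A `HelixModel` (or any data frame with `x`, `y`, `z`,
#'   `element`, `resno`).
#' @param probe Probe radius in angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @param resnos Optional residue numbers: compute SASA only for their
#'   atoms (occlusion by the whole model is still accounted for).
#' @return Numeric SASA vector (angstrom^2) for the computed atoms, with
#'   attribute `per_residue` (named by residue number).
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L, resnos = NULL) {
  atoms <- if (inherits(model, "HelixModel")) model$atoms else model
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- .vdw_radii[atoms$element]
  if (anyNA(rad)) stop("unknown element in model")
  n <- nrow(xyz)
  ext <- rad + probe
  targets <- if (is.null(resnos)) seq_len(n)
             else which(atoms$resno %in% resnos)
  sph <- .fibonacci_sphere(n_points)
  out <- numeric(length(targets))
  clash_warned <- FALSE
  for (k in seq_along(targets)) {
    i <- targets[k]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    if (!clash_warned && any(d2[-i] < 0.25)) {
      warning("clashing atoms (< 0.5 angstrom) in model")
      clash_warned <- TRUE
    }
    nb <- which(d2 < (ext[i] + ext)^2 & seq_len(n) != i)
    if (length(nb)) {
      pts <- sweep(sph * ext[i], 2, xyz[i, ], `+`)
      # points free of every neighbour sphere
      d2p <- outer(rowSums(pts^2), rowSums(xyz[nb, , drop = FALSE]^2),
                   `+`) - 2 * pts %*% t(xyz[nb, , drop = FALSE])
      free <- rowSums(sweep(d2p, 2, ext[nb]^2, `<`)) == 0
      frac <- mean(free)
    } else frac <- 1
    out[k] <- 4 * pi * ext[i]^2 * frac
  }
  attr(out, "per_residue") <- tapply(out, atoms$resno[targets], sum)
  out
}

#' Change in SASA upon a point substitution on a helix model
#'
#' Rebuilds the helix with the substitution and returns the difference in
#' surface area summed over the mutated residue's atoms,
#' `SASA_res(mutant) - SASA_res(wild)`.
#'
#' @param model A wild-type `HelixModel`.
#' @param position Residue index within the model (1-based).
#' @param from_aa,to_aa One-letter identities; `from_aa` must match the
#'   model.
#' @param probe,n_points Passed to [sasa()].
#' @return Delta SASA in angstrom^2.
#' @export
delta_sasa <- function(model, position, from_aa, to_aa,
                       probe = 1.4, n_points = 960L) {
  seq_aa <- strsplit(model$sequence, "")[[1]]
  if (seq_aa[position] != from_aa)
    stop("model residue ", position, " is ", seq_aa[position],
         ", not ", from_aa)
  if (from_aa == to_aa) return(0)
  mut_seq <- seq_aa
  mut_seq[position] <- to_aa
  mut <- build_helix(paste(mut_seq, collapse = ""))
  s_wt <- sum(sasa(model, probe, n_points, resnos = position))
  s_mu <- sum(sasa(mut, probe, n_points, resnos = position))
  s_mu - s_wt
}

#' Ordinary-least-squares fit of the atomic-solvation parameter
#'
#' Regresses apparent insertion free-energy changes (kcal/mol) on computed
#' changes in solvent-accessible surface area (angstrom^2). Burial of
#' additional apolar area stabilizes insertion, so the slope is negative;
#' its magnitude is the apparent atomic-solvation parameter.
#'
#' @param points Data frame with columns `dsasa` (angstrom^2) and `ddg`
#'   (kcal/mol); further columns are kept as labels.
#' @return An object of class `SolvationFit`: `slope` and `slope_se` in
#'   cal/mol/angstrom^2, `intercept` (kcal/mol), `r2`, `p_value`, `n`, and
#'   the input `points`.
#' @export
fit_solvation <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("dsasa", "ddg") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("dsasa", "ddg")]), ]
  if (nrow(points) < 3) stop("need at least 3 points")
  if (stats::var(points$dsasa) == 0)
    stop("degenerate fit: no variance in dsasa")
  fit <- lm(ddg ~ dsasa, data = points)
  # summary.lm warns on exact-line input; the fit itself is fine
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2]) * 1000,
                 slope_se = sm$coefficients[2, 2] * 1000,
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = nrow(points),
                 points = points),
            class = "SolvationFit")
}

#' @export
print.SolvationFit <- function(x, ...) {
  cat(sprintf(
    "SolvationFit: slope %.1f +/- %.1f cal/mol/A^2, r2 = %.2f, n = %d\n",
    x$slope, x$slope_se, x$r2, x$n))
  invisible(x)
}

.ALIPHATIC <- c("A", "V", "I", "L", "M", "F")

#' Aliphatic substitution points in the membrane core
#'
#' Selects, from an apparent insertion landscape, every substitution from
#' one aliphatic identity (Ala, Val, Ile, Leu, Met, Phe) to another at
#' positions whose wild type is aliphatic and whose depth lies in the
#' membrane-core window, and pairs each with its computed delta SASA on an
#' ideal helix model of the construct.
#'
#' @param landscape Wild-type-relative `EnergyLandscape`.
#' @param construct The scanned `Construct`.
#' @param midplane Mid-plane position (paper numbering).
#' @param rise Helical rise per residue (default 1.5 angstrom).
#' @param z_window Membrane-core window in angstrom (default
#'   `c(-9, 13)`).
#' @param helix Optional prebuilt `HelixModel` of the construct protein.
#' @param include_censored Keep censored (lower-bound) points? Default
#'   FALSE.
#' @param probe,n_points Passed to [sasa()].
#' @return Data frame with columns `position`, `from`, `to`, `z`, `dsasa`,
#'   `ddg`, `label`.
#' @export
aliphatic_core_points <- function(landscape, construct, midplane,
                                  rise = 1.5, z_window = c(-9, 13),
                                  helix = NULL, include_censored = FALSE,
                                  probe = 1.4, n_points = 960L) {
  if (is.null(helix)) helix <- build_helix(construct$protein)
  pos <- landscape$positions
  z <- (pos - midplane) * rise
  core <- which(z > z_window[1] & z < z_window[2] &
                  landscape$wt_aa %in% .ALIPHATIC)
  out <- list()
  for (i in core) {
    from <- landscape$wt_aa[i]
    for (to in setdiff(.ALIPHATIC, from)) {
      if (landscape$mask[i, to]) next
      if (!include_censored && landscape$censored[i, to]) next
      ddg <- landscape$ddg[i, to]
      if (is.na(ddg)) next
      ds <- delta_sasa(helix, residue_index(construct, pos[i]), from, to,
                       probe = probe, n_points = n_points)
      out[[length(out) + 1]] <-
        data.frame(position = pos[i], from = from, to = to, z = z[i],
                   dsasa = ds, ddg = ddg,
                   label = sprintf("%s%d%s", from, pos[i], to))
    }
  }
  do.call(rbind, out)
}

#' Mid-plane aliphatic points on a poly-Ala helix
#'
#' The inset-style estimate: each aliphatic residue contributes one point
#' pairing its fitted insertion energy at the membrane mid-plane (Z = 0,
#' relative to Ala) with the delta SASA of substituting Ala by that residue
#' at the centre of a poly-Ala helix.
#'
#' @param profile An `InsertionProfile`.
#' @param helix_length Length of the poly-Ala host helix (default 27).
#' @param probe,n_points Passed to [sasa()].
#' @return Data frame with `dsasa`, `ddg`, `label` rows for V, I, L, M, F.
#' @export
midplane_aliphatic_points <- function(profile, helix_length = 27L,
                                      probe = 1.4, n_points = 960L) {
  host <- build_helix(strrep("A", helix_length))
  centre <- (helix_length + 1L) %/% 2L
  res <- setdiff(.ALIPHATIC, "A")
  data.frame(
    dsasa = vapply(res, function(a)
      delta_sasa(host, centre, "A", a, probe, n_points), 0),
    ddg = evaluate_profile(profile, res, 0),
    label = paste0("A->", res))
}
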