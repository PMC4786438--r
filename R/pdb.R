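# Minimal fixed-width PDB ATOM I/O. No PDB reader is available among the
# package's allowed dependencies, so the subset of the format needed here
# (heavy-atom coordinates of protein chains) is parsed directly.

#' Read ATOM records from a PDB file
#'
#' @param path PDB file.
#' @return Data frame with columns `atom`, `resname`, `chain`, `resno`,
#'   `x`, `y`, `z`, `element`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (!length(lines)) stop("no ATOM records in ", path)
  f <- function(a, b) trimws(substr(lines, a, b))
  el <- f(77, 78)
  # infer element from the atom name when column 77-78 is absent
  nm <- f(13, 16)
  el[el == ""] <- substr(gsub("[0-9]", "", nm[el == ""]), 1, 1)
  data.frame(atom = nm,
             resname = f(18, 20),
             chain = f(22, 22),
             resno = as.integer(f(23, 26)),
             x = as.numeric(f(31, 38)),
             y = as.numeric(f(39, 46)),
             z = as.numeric(f(47, 54)),
             element = el,
             stringsAsFactors = FALSE)
}

#' Write ATOM records to a PDB file
#'
#' @param atoms Data frame as returned by [read_pdb()] (a `chain` column is
#'   required; `resname` defaults to `UNK`).
#' @param path Output file.
#' @export
write_pdb <- function(atoms, path) {
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(atoms$chain)) atoms$chain <- "A"
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$atom) < 4, paste0(" ", atoms$atom), atoms$atom),
    atoms$resname, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Convert a helix model to PDB atom records
#' @param model A `HelixModel`.
#' @param chain Chain identifier.
#' @param resno_offset Added to the model's 1-based residue numbers.
#' @return Data frame in [read_pdb()] layout.
#' @export
helix_to_pdb <- function(model, chain = "A", resno_offset = 0L) {
  a <- model$atoms
  data.frame(atom = a$atom, resname = a$resname, chain = chain,
             resno = a$resno + resno_offset,
             x = a$x, y = a$y, z = a$z, element = a$element,
             stringsAsFactors = FALSE)
}

# rigid-body helpers used to assemble synthetic dimers and in tests
rotate_z <- function(atoms, degrees) {
  th <- degrees * pi / 180
  x <- atoms$x * cos(th) - atoms$y * sin(th)
  y <- atoms$x * sin(th) + atoms$y * cos(th)
  atoms$x <- x; atoms$y <- y
  atoms
}

translate_xyz <- function(atoms, dx = 0, dy = 0, dz = 0) {
  atoms$x <- atoms$x + dx; atoms$y <- atoms$y + dy; atoms$z <- atoms$z + dz
  atoms
}

#' Assemble a synthetic C2 homodimer from an ideal helix
#'
#' Places two copies of the ideal helix of `sequence` side by side: the
#' second copy is rotated 180 degrees about the inter-axis normal (C2
#' symmetry) and offset by `separation`. `face_position` residues can be
#' rotated toward the partner by adjusting the helix phase. Intended for
#' constructing test fixtures and synthetic reference models; it is not a
#' docking method.
#'
#' @param sequence One-letter sequence of the protomer.
#' @param separation Axis-to-axis distance in angstrom (default 9).
#' @param phase Rotation of each protomer about its own axis, degrees.
#' @param resno_offset Residue numbering offset for both chains.
#' @return Data frame of ATOM records (chains A and B).
#' @export
make_c2_dimer <- function(sequence, separation = 9, phase = 0,
                          resno_offset = 0L) {
  m <- build_helix(sequence)
  a <- helix_to_pdb(m, chain = "A", resno_offset = resno_offset)
  # align helix axis to z through the origin
  ca <- as.matrix(a[a$atom == "CA", c("x", "y", "z")])
  ctr <- colMeans(ca)
  cc <- sweep(ca, 2, ctr)
  ax <- svd(cc)$v[, 1]
  # rotation taking ax -> (0,0,1)
  v <- c(-ax[2], ax[1], 0)
  s <- sqrt(sum(v^2)); cth <- ax[3]
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]), 2, ctr)
  if (s > 1e-12) {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    rot <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
    xyz <- xyz %*% t(rot)
  }
  a[, c("x", "y", "z")] <- xyz
  a <- rotate_z(a, phase)
  a <- translate_xyz(a, dx = -separation / 2)
  b <- a
  b$chain <- "B"
  # C2 axis along z midway between the protomers: parallel dimer
  b$x <- -b$x; b$y <- -b$y
  rbind(a, b)
}
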