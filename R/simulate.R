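#' Gas constant times temperature, in kcal/mol
#' @param temperature Absolute temperature in K (default 310).
#' @return RT in kcal/mol (0.616032 at 310 K).
#' @export
rt_kcal <- function(temperature = 310) 1.9872e-3 * temperature

# run expr with a private RNG stream, restoring the caller's state
local_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Ground-truth per-amino-acid insertion profiles
#'
#' Degree-4 polynomials in membrane depth Z (angstrom), relative to Ala,
#' emulating measured single-pass insertion profiles. Two shape families are
#' used: hydrophobic/aromatic residues get a curved trough
#' `core * (1 - (Z/h)^2)^2` (transfer energy tracks buried apolar area,
#' which falls off as soon as the side chain approaches the interface);
#' polar and charged residues get a saturating penalty
#' `core * (1 - (Z/h)^4)` (the cost of burying a polar group stays near its
#' maximum across the core). A linear term `slope * Z/h` encodes the
#' positive-inside asymmetry (cytoplasm at negative Z). Outside `|Z| > h`
#' the profile is clamped to its edge value (aqueous phase).
#'
#' Core depths (kcal/mol at Z = 0, relative to Ala) follow the measured
#' landscape: Leu/Ile/Phe -2, Met -1.7, Val -0.5, Trp -1, Tyr -0.5,
#' Gly/Pro +2, Ser/Thr +0.3, Cys +0.2, Asn/Gln/His +3.5, Asp/Glu +4.5,
#' Lys +4, Arg +1.5; Arg/Lys are 2 kcal/mol and His 1 kcal/mol more
#' favourable at the cytoplasmic than the periplasmic edge.
#'
#' @param half_width Membrane half-thickness h in angstrom (default 15).
#' @return A 20 x 5 coefficient matrix (columns `c0`..`c4`, powers of Z)
#'   with attribute `half_width`; class `TruthProfiles`.
#' @export
truth_profiles <- function(half_width = 15) {
  core <- c(A = 0, C = 0.2, D = 4.5, E = 4.5, F = -2, G = 2, H = 3.5,
            I = -2, K = 4, L = -2, M = -1.7, N = 3.5, P = 2, Q = 3.5,
            R = 1.5, S = 0.3, T = 0.3, V = -0.5, W = -1, Y = -0.5)
  # slope = half the periplasm-minus-cytoplasm edge difference (positive
  # slope disfavours the periplasmic side, i.e. positive-inside)
  slope <- c(A = 0, C = 0, D = 0, E = 0, F = 0, G = 0, H = 0.5,
             I = 0, K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0,
             R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0)
  trough <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
  h <- half_width
  m <- matrix(0, 20L, 5L, dimnames = list(AA20, paste0("c", 0:4)))
  for (aa in AA20) {
    if (aa %in% trough) {
      m[aa, ] <- c(core[aa], slope[aa] / h, -2 * core[aa] / h^2, 0,
                   core[aa] / h^4)
    } else {
      m[aa, ] <- c(core[aa], slope[aa] / h, 0, 0, -core[aa] / h^4)
    }
  }
  attr(m, "half_width") <- h
  class(m) <- c("TruthProfiles", class(m))
  m
}

# evaluate per-aa truth polynomials at depth Z, clamped to the membrane
eval_truth_profiles <- function(profiles, aa, z) {
  h <- attr(profiles, "half_width")
  z <- pmin(pmax(z, -h), h)
  co <- profiles[aa, , drop = FALSE]
  co[, 1] + co[, 2] * z + co[, 3] * z^2 + co[, 4] * z^3 + co[, 5] * z^4
}

#' Ground-truth apparent free-energy landscape for a construct
#'
#' Expands per-amino-acid depth profiles into a per-(position, amino acid)
#' table of true apparent insertion free-energy changes versus wild type:
#' `ddg[i, j] = P_j(Z_i) - P_wt(i)(Z_i)` with `Z_i = (i - midplane) * rise`.
#' Wild-type identities are exactly 0 by construction.
#'
#' @param construct A `Construct`.
#' @param midplane Residue position of the membrane mid-plane (default 311,
#'   the CLS mid-plane position).
#' @param rise Helical rise per residue in angstrom (default 1.5).
#' @param profiles A `TruthProfiles` matrix (default [truth_profiles()]).
#' @return An object of class `TruthLandscape` with the `ddg` matrix.
#' @export
truth_landscape <- function(construct, midplane = 311, rise = 1.5,
                            profiles = truth_profiles()) {
  pos <- span_positions(construct)
  wt <- wildtype_aa(construct)
  z <- (pos - midplane) * rise
  ddg <- matrix(0, length(pos), 20L,
                dimnames = list(as.character(pos), AA20))
  for (j in AA20) ddg[, j] <- eval_truth_profiles(profiles, j, z)
  ddg <- ddg - eval_truth_profiles(profiles, wt, z)  # wild-type column -> 0
  stopifnot(all(abs(ddg[cbind(seq_along(pos), match(wt, AA20))]) < 1e-12))
  obj <- list(construct_name = construct$name, positions = pos, wt_aa = wt,
              ddg = ddg, midplane = midplane, rise = rise,
              profiles = profiles)
  class(obj) <- "TruthLandscape"
  obj
}

#' Simulation configuration
#'
#' @param depth Sequencing depth (read pairs) for the reference population;
#'   default 4e6, the depth scale of the real experiment.
#' @param depth_selected Depth for the selected population (the source data
#'   do not state it separately; default equal to `depth`).
#' @param clonal_bias_sigma Log-normal sd of per-clone representation in the
#'   pooled library (default 0.5, a few-fold spread typical of pooled
#'   site-saturation libraries).
#' @param temperature Selection temperature in K (default 310).
#' @param seq_error_rate Per-base substitution error rate (default 1e-3,
#'   MiSeq scale).
#' @param rng_seed Mandatory integer seed; all randomness derives from it
#'   (reference counts use stream `seed`, selected counts `seed + 1`,
#'   FASTQ emission `seed + 2` and `seed + 3`).
#' @param read_length Read length of each mate (default 150).
#' @param wt_spike Multiplier on the wild-type clone weights (default 1).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(depth = 4e6, depth_selected = depth,
                       clonal_bias_sigma = 0.5, temperature = 310,
                       seq_error_rate = 1e-3, rng_seed,
                       read_length = 150L, wt_spike = 1) {
  if (missing(rng_seed) || is.null(rng_seed))
    stop("rng_seed is mandatory for reproducibility")
  stopifnot(depth >= 0, depth_selected >= 0,
            clonal_bias_sigma >= 0, temperature > 0,
            seq_error_rate >= 0, seq_error_rate <= 1,
            read_length > 0)
  structure(list(depth = depth, depth_selected = depth_selected,
                 clonal_bias_sigma = clonal_bias_sigma,
                 temperature = temperature,
                 seq_error_rate = seq_error_rate,
                 rng_seed = as.integer(rng_seed),
                 read_length = as.integer(read_length),
                 wt_spike = wt_spike),
            class = "SimConfig")
}

# multinomial draw collapsing wild-type identity cells into the wt pool
.cells_to_table <- function(construct, cellcounts, lib, population) {
  pos <- span_positions(construct)
  wt_cells <- lib$is_wildtype
  wildtype_count <- sum(cellcounts[wt_cells])
  m <- matrix(NA_real_, length(pos), 20L,
              dimnames = list(as.character(pos), AA20))
  keep <- !wt_cells
  m[cbind(match(lib$position[keep], pos), match(lib$aa[keep], AA20))] <-
    cellcounts[keep]
  count_table(construct, m, wildtype_count, population = population,
              n_reads_total = sum(cellcounts),
              n_reads_passing = sum(cellcounts))
}

#' Simulate reference-population counts
#'
#' Each of the `20 * span_length` library members (wild-type identities
#' included) receives a log-normal clonal weight; reads are drawn
#' multinomially at the configured depth. Wild-type identity cells collapse
#' into the pooled wild-type count, as they do in real data.
#'
#' @param construct A `Construct`.
#' @param config A `SimConfig`.
#' @param expected If `TRUE`, return noise-free expected counts
#'   (continuous) instead of a multinomial draw.
#' @return A `CountTable` with population `"reference"`.
#' @export
simulate_reference_counts <- function(construct, config, expected = FALSE) {
  lib <- enumerate_library(construct)
  n <- nrow(lib)
  local_seed(config$rng_seed, {
    w <- if (config$clonal_bias_sigma > 0)
      rlnorm(n, 0, config$clonal_bias_sigma) else rep(1, n)
    w[lib$is_wildtype] <- w[lib$is_wildtype] * config$wt_spike
    p <- w / sum(w)
    cells <- if (expected) config$depth * p
             else as.vector(rmultinom(1, config$depth, p))
    .cells_to_table(construct, cells, lib, "reference")
  })
}

#' Simulate selected-population counts under Boltzmann selection
#'
#' Selection is modelled as a single Boltzmann reweighting of the reference
#' frequencies: the expected selected frequency of variant v is proportional
#' to `f_ref(v) * exp(-ddG(v) / RT)`, with wild-type ddG = 0. Counts are
#' drawn multinomially at the configured selected depth. This inverts the
#' frequency-ratio free-energy estimator exactly in expectation.
#'
#' @param reference A reference `CountTable` (realized or expected).
#' @param truth A `TruthLandscape` covering the same variants.
#' @param config A `SimConfig`.
#' @param expected If `TRUE`, return noise-free expected counts.
#' @param population Output population label.
#' @return A `CountTable`.
#' @export
simulate_selected_counts <- function(reference, truth, config,
                                     expected = FALSE,
                                     population = "insertion-selected") {
  if (!identical(reference$positions, truth$positions) ||
      !identical(reference$wt_aa, truth$wt_aa))
    stop("reference table and truth landscape cover different variants")
  rt <- rt_kcal(config$temperature)
  f_ref <- reference$counts / total_counts(reference)
  w <- f_ref * exp(-truth$ddg / rt)
  wt_w <- reference$wildtype_count / total_counts(reference)  # ddG = 0
  tot <- sum(w, na.rm = TRUE) + wt_w
  pvec <- c(as.vector(w), wt_w) / tot
  idx <- !is.na(pvec)
  draw <- numeric(length(pvec))
  if (expected) {
    draw[idx] <- config$depth_selected * pvec[idx]
  } else {
    draw[idx] <- local_seed(config$rng_seed + 1L,
      as.vector(rmultinom(1, config$depth_selected, pvec[idx])))
  }
  m <- matrix(draw[seq_len(length(pvec) - 1L)],
              nrow = nrow(reference$counts),
              dimnames = dimnames(reference$counts))
  m[is.na(reference$counts)] <- NA
  ct <- count_table_from_parts(reference, m, draw[length(pvec)], population)
  ct
}

# rebuild a CountTable reusing another table's construct frame
count_table_from_parts <- function(template, counts, wildtype_count,
                                   population) {
  obj <- template
  obj$counts <- counts
  obj$wildtype_count <- wildtype_count
  obj$population <- population
  obj$n_reads_total <- sum(counts, na.rm = TRUE) + wildtype_count
  obj$n_reads_passing <- obj$n_reads_total
  obj$rejects <- integer()
  obj
}

#' Emit paired-end FASTQ for a count table
#'
#' One read pair per counted molecule. Each variant read carries a random
#' NNS codon encoding its amino acid at the mutated position; wild-type
#' reads carry a random synonymous NNS codon for the wild-type identity at a
#' random scanned position (emulating the site-saturation library).
#' Per-base substitution errors are applied to each mate independently at
#' `config$seq_error_rate`; quality strings encode that rate as a constant
#' Phred score.
#'
#' @param counts A `CountTable`.
#' @param construct The matching `Construct`.
#' @param config A `SimConfig`.
#' @param r1_path,r2_path Output FASTQ paths (gzipped if ending in `.gz`).
#' @param stream RNG stream offset added to `config$rng_seed` (default 2).
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
emit_fastq <- function(counts, construct, config, r1_path, r2_path,
                       stream = 2L) {
  amp <- paste0(construct$upstream_flank, construct$dna,
                construct$downstream_flank)
  amp_len <- nchar(amp)
  rl <- min(config$read_length, amp_len)
  if (2L * config$read_length < amp_len)
    stop("amplicon (", amp_len, " nt) longer than combined read coverage")
  codons <- nns_codons()
  codons <- codons[codons$aa != "*", ]
  codon_sets <- split(codons$codon, codons$aa)
  pos <- counts$positions
  up_len <- nchar(construct$upstream_flank)
  codon_start <- function(p)
    up_len + (p - construct$numbering_offset - 1L) * 3L + 1L
  sample_codons <- function(aa_vec) {
    out <- character(length(aa_vec))
    for (a in unique(aa_vec)) {
      idx <- aa_vec == a
      s <- codon_sets[[a]]
      out[idx] <- s[sample.int(length(s), sum(idx), replace = TRUE)]
    }
    out
  }

  local_seed(config$rng_seed + stream, {
    cells <- which(!is.na(counts$counts) & counts$counts > 0, arr.ind = TRUE)
    reads <- character(0)
    if (nrow(cells)) {
      n_per <- counts$counts[cells]
      p_all <- rep(pos[cells[, 1]], n_per)
      aa_all <- rep(AA20[cells[, 2]], n_per)
      cs <- codon_start(p_all)
      reads <- paste0(substr(rep(amp, length(p_all)), 1L, cs - 1L),
                      sample_codons(aa_all), substring(amp, cs + 3L))
    }
    n_wt <- round(counts$wildtype_count)
    if (n_wt > 0) {
      wp <- pos[sample.int(length(pos), n_wt, replace = TRUE)]
      wa <- wildtype_aa(construct, wp)
      cs <- codon_start(wp)
      reads <- c(reads,
                 paste0(substr(rep(amp, n_wt), 1L, cs - 1L),
                        sample_codons(wa), substring(amp, cs + 3L)))
    }
    nr <- length(reads)
    if (nr == 0) {
      r1 <- r2 <- character(0)
    } else {
      reads <- reads[sample.int(nr)]  # shuffle molecules
      r1 <- substr(reads, 1L, rl)
      r2 <- degenerate_revcomp(substring(reads, amp_len - rl + 1L))
      r1 <- .apply_seq_errors(r1, config$seq_error_rate)
      r2 <- .apply_seq_errors(r2, config$seq_error_rate)
    }
    q <- if (config$seq_error_rate > 0)
      max(2L, min(40L, round(-10 * log10(config$seq_error_rate)))) else 40L
    qual <- strrep(intToUtf8(q + 33L), rl)
    .write_fastq(r1, qual, r1_path, construct$name, 1L)
    .write_fastq(r2, qual, r2_path, construct$name, 2L)
  })
  invisible(c(r1_path, r2_path))
}

# independent per-base substitution errors on fixed-length reads
.apply_seq_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads[1])
  n_err <- rbinom(1L, length(reads) * rl, rate)
  if (n_err == 0) return(reads)
  ri <- sample.int(length(reads), n_err, replace = TRUE)
  bp <- sample.int(rl, n_err, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_err)) {
    cur <- substr(reads[ri[k]], bp[k], bp[k])
    alt <- sample(setdiff(bases, cur), 1L)
    substr(reads[ri[k]], bp[k], bp[k]) <- alt
  }
  reads
}

.write_fastq <- function(seqs, qual, path, run, mate) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seqs) == 0) { return(invisible(path)) }
  hdr <- sprintf("@SIM:%s:%d:1:1:%d:%d %d:N:0:1",
                 run, mate, seq_along(seqs), seq_along(seqs), mate)
  writeLines(as.vector(rbind(hdr, seqs, "+", qual)), con)
  invisible(path)
}

#' Write a truth landscape as JSON
#' @param truth A `TruthLandscape`.
#' @param path Output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(construct = truth$construct_name,
                            midplane = truth$midplane, rise = truth$rise,
                            positions = truth$positions,
                            wt_aa = truth$wt_aa,
                            ddg = as.data.frame(truth$ddg)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ground truth for a self-association scan
#'
#' Builds the two coupled truth landscapes of an association experiment on
#' a homodimerizing segment: the insertion landscape (as in
#' [truth_landscape()]) and the measured association landscape, defined as
#' `ddG_measured = 2 * ddG_insertion + ddG_dimerization` (the homodimer
#' carries every mutation twice). The planted dimerization component
#' follows a small-xxx-small interface: at interface positions,
#' substitutions away from small residues disrupt binding by `disrupt`
#' kcal/mol, substitutions to other small residues cost `small_penalty`;
#' all other positions contribute nothing.
#'
#' @param construct A `Construct` (e.g. the GpA segment).
#' @param interface_positions Positions forming the dimer interface
#'   (default `c(79, 83)`, the GpA GxxxG glycines).
#' @param midplane Mid-plane position (default the span's geometric
#'   centre).
#' @param rise Helical rise per residue (default 1.5 angstrom).
#' @param profiles Insertion `TruthProfiles` (default [truth_profiles()]).
#' @param disrupt Disruption magnitude in kcal/mol (default 3).
#' @param small_penalty Cost of small-to-small interface substitutions
#'   (default 0.3 kcal/mol).
#' @param small Small residues tolerated at the interface (default G, A,
#'   S).
#' @return List with `insertion` and `measured` (`TruthLandscape`s) and
#'   `dimer_effect` (positions x 20 matrix).
#' @export
dimer_truth <- function(construct, interface_positions = c(79L, 83L),
                        midplane = mean(range(span_positions(construct))),
                        rise = 1.5, profiles = truth_profiles(),
                        disrupt = 3, small_penalty = 0.3,
                        small = c("G", "A", "S")) {
  ins <- truth_landscape(construct, midplane = midplane, rise = rise,
                         profiles = profiles)
  pos <- ins$positions
  d <- matrix(0, length(pos), 20L, dimnames = dimnames(ins$ddg))
  for (i in which(pos %in% interface_positions)) {
    d[i, ] <- ifelse(AA20 %in% small, small_penalty, disrupt)
    d[i, ins$wt_aa[i]] <- 0
  }
  measured <- ins
  measured$ddg <- 2 * ins$ddg + d
  list(insertion = ins, measured = measured, dimer_effect = d)
}
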