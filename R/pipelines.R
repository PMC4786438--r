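#' Read and validate a run configuration
#'
#' Flat `key: value` text file. Recognized keys: `construct` (path to a
#' construct config), `reference_r1/_r2`, `selected_r1/_r2` (FASTQ) or
#' `reference_counts`, `selected_counts` (TSV), `insertion_profile`
#' (JSON, association runs), `min_count`, `window`, `temperature`,
#' `pseudocount`, `rise`, `midplane`, `excluded`
#' (comma-separated positions), `disrupt_threshold`, `min_substitutions`,
#' `neutral_tol`, `seed`, `outdir`.
#'
#' @param path Config file.
#' @return A validated list of class `RunConfig`.
#' @export
read_run_config <- function(path) {
  kv <- read_flat_config(path)
  if (is.null(kv$construct))
    stop("run config must name a construct file")
  if (!file.exists(kv$construct))
    stop("construct file not found: ", kv$construct)
  num <- function(key, default) as.numeric(kv[[key]] %||% default)
  cfg <- list(
    construct_path = kv$construct,
    reference_r1 = kv$reference_r1, reference_r2 = kv$reference_r2,
    selected_r1 = kv$selected_r1, selected_r2 = kv$selected_r2,
    reference_counts = kv$reference_counts,
    selected_counts = kv$selected_counts,
    insertion_profile = kv$insertion_profile,
    min_count = num("min_count", 100),
    window = as.integer(num("window", 5)),
    temperature = num("temperature", 310),
    pseudocount = num("pseudocount", 1),
    rise = num("rise", 1.5),
    midplane = if (!is.null(kv$midplane)) as.numeric(kv$midplane),
    excluded = if (!is.null(kv$excluded))
      as.integer(strsplit(kv$excluded, ",")[[1]]),
    disrupt_threshold = num("disrupt_threshold", 2),
    min_substitutions = as.integer(num("min_substitutions", 4)),
    neutral_tol = num("neutral_tol", 0.2),
    seed = as.integer(num("seed", 1)),
    outdir = kv$outdir %||% "."
  )
  has_fastq <- !is.null(cfg$reference_r1) && !is.null(cfg$reference_r2) &&
    !is.null(cfg$selected_r1) && !is.null(cfg$selected_r2)
  has_counts <- !is.null(cfg$reference_counts) &&
    !is.null(cfg$selected_counts)
  if (!has_fastq && !has_counts)
    stop("run config needs either FASTQ pairs or count tables ",
         "for both populations")
  for (key in c("reference_r1", "reference_r2", "selected_r1",
                "selected_r2", "reference_counts", "selected_counts",
                "insertion_profile")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("input file not found: ", key, " = ", cfg[[key]])
  }
  class(cfg) <- "RunConfig"
  cfg
}

# load both populations from whichever inputs the config provides
.load_populations <- function(cfg, construct, selected_label) {
  if (!is.null(cfg$reference_counts)) {
    ref <- read_counts_tsv(cfg$reference_counts, construct)
    sel <- read_counts_tsv(cfg$selected_counts, construct)
  } else {
    ref <- count_population(cfg$reference_r1, cfg$reference_r2, construct,
                            population = "reference")
    sel <- count_population(cfg$selected_r1, cfg$selected_r2, construct,
                            population = selected_label)
  }
  list(reference = ref, selected = sel)
}

.provenance <- function(cfg, extra = list()) {
  c(list(package = "memscan",
         version = as.character(packageVersion("memscan")),
         seed = cfg$seed,
         config = cfg[!vapply(cfg, is.null, TRUE)]),
    extra)
}

#' Run the insertion pipeline
#'
#' Reference and insertion-selected populations are converted to an
#' apparent free-energy landscape (reference filter, selection
#' coefficients, Gibbs transform), re-referenced to Ala, smoothed, fitted
#' as per-amino-acid depth profiles, and summarized as Boltzmann
#' propensities. Outputs (landscape TSV, profile JSON, propensity matrix,
#' QC report, provenance record) are written to `outdir`; the run is
#' deterministic given its inputs.
#'
#' @param config A `RunConfig` or path to one.
#' @return Invisibly, a list with `landscape`, `landscape_ala`, `midplane`,
#'   `profile`, `propensities`, `mask` and output paths.
#' @export
run_insertion_pipeline <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config
         else read_run_config(config)
  construct <- read_construct(cfg$construct_path)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  pops <- .load_populations(cfg, construct, "insertion-selected")
  mask <- apply_reference_filter(pops$reference, cfg$min_count)
  sc <- selection_coefficients(pops$selected, pops$reference, mask)
  land <- to_ddg(sc, temperature = cfg$temperature,
                 pseudocount = cfg$pseudocount)
  land_ala <- relative_to_ala(land)
  midplane <- cfg$midplane %||% estimate_midplane(land_ala,
                                                  window = cfg$window)
  profile <- fit_profiles(land_ala, midplane, rise = cfg$rise,
                          excluded = cfg$excluded, window = cfg$window)
  prop <- propensities(land_ala, temperature = cfg$temperature)
  paths <- list(
    landscape = file.path(cfg$outdir, "landscape.tsv"),
    landscape_ala = file.path(cfg$outdir, "landscape_ala.tsv"),
    profile = file.path(cfg$outdir, "insertion_profile.json"),
    propensities = file.path(cfg$outdir, "propensities.tsv"),
    qc = file.path(cfg$outdir, "qc.json"),
    provenance = file.path(cfg$outdir, "provenance.json"))
  write_landscape_tsv(land, paths$landscape)
  write_landscape_tsv(land_ala, paths$landscape_ala)
  write_profile_json(profile, paths$profile)
  write_propensity_matrix(prop, paths$propensities)
  jsonlite::write_json(list(reference = qc_report(pops$reference),
                            selected = qc_report(pops$selected),
                            n_surviving = attr(mask, "n_surviving"),
                            n_masked = sum(mask)),
                       paths$qc, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.provenance(cfg, list(midplane = midplane)),
                       paths$provenance, auto_unbox = TRUE, digits = NA)
  invisible(list(landscape = land, landscape_ala = land_ala,
                 midplane = midplane, profile = profile,
                 propensities = prop, mask = mask, paths = paths))
}

#' Run the association pipeline
#'
#' The ampicillin-selected population is the *reference* and the
#' ampicillin-plus-chloramphenicol population the *selected* one; the
#' measured landscape is corrected for insertion effects (twice the
#' per-monomer contribution) using a supplied insertion profile, and
#' positions are classified as likely/unlikely to mediate binding.
#'
#' @param config A `RunConfig` or path to one; must name an
#'   `insertion_profile` JSON.
#' @return Invisibly, a list with `measured`, `dimer`, `labels`, `midplane`
#'   and output paths.
#' @export
run_association_pipeline <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config
         else read_run_config(config)
  if (is.null(cfg$insertion_profile))
    stop("association runs need insertion_profile in the config")
  construct <- read_construct(cfg$construct_path)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  pops <- .load_populations(cfg, construct, "association-selected")
  mask <- apply_reference_filter(pops$reference, cfg$min_count)
  sc <- selection_coefficients(pops$selected, pops$reference, mask)
  measured <- to_ddg(sc, temperature = cfg$temperature,
                     pseudocount = cfg$pseudocount)
  profile <- read_profile_json(cfg$insertion_profile)
  # without an own insertion selection, the mid-plane frame defaults to
  # the geometric centre of the scanned span
  midplane <- cfg$midplane %||% mean(range(measured$positions))
  dimer <- correct_dimerization(measured, profile, midplane,
                                rise = cfg$rise)
  labels <- classify_positions(dimer,
                               disrupt_threshold = cfg$disrupt_threshold,
                               min_substitutions = cfg$min_substitutions,
                               neutral_tol = cfg$neutral_tol)
  paths <- list(
    measured = file.path(cfg$outdir, "landscape_measured.tsv"),
    dimer = file.path(cfg$outdir, "landscape_dimerization.tsv"),
    labels = file.path(cfg$outdir, "position_labels.tsv"),
    qc = file.path(cfg$outdir, "qc.json"),
    provenance = file.path(cfg$outdir, "provenance.json"))
  write_landscape_tsv(measured, paths$measured)
  write_dimer_tsv(dimer, paths$dimer)
  write_dimer_tsv(labels, paths$labels)
  jsonlite::write_json(list(reference = qc_report(pops$reference),
                            selected = qc_report(pops$selected),
                            n_surviving = attr(mask, "n_surviving"),
                            n_masked = sum(mask)),
                       paths$qc, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.provenance(cfg, list(midplane = midplane)),
                       paths$provenance, auto_unbox = TRUE, digits = NA)
  invisible(list(measured = measured, dimer = dimer, labels = labels,
                 midplane = midplane, paths = paths))
}

# ---- command-line interface -------------------------------------------------

.cli_args <- function(argv) {
  # parse "--key value" pairs into a named list
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    if (!startsWith(argv[i], "--"))
      stop("unexpected argument: ", argv[i])
    key <- sub("^--", "", argv[i])
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- argv[i + 1L]; i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the `memscan` subcommands (`design-primers`, `simulate`,
#' `count`, `run-insertion`, `run-association`, `classify`,
#' `filter-models`). Installed as the executable script
#' `inst/scripts/memscan`.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first).
#' @return Invisibly, the subcommand's result.
#' @export
memscan_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv))
    stop("usage: memscan <subcommand> [--key value ...]; subcommands: ",
         "design-primers simulate count run-insertion run-association ",
         "classify filter-models")
  cmd <- argv[1]
  a <- .cli_args(argv[-1])
  need <- function(key) a[[key]] %||% stop("missing --", key)
  res <- switch(
    cmd,
    "design-primers" = {
      x <- read_construct(need("construct"))
      df <- design_all_primers(x)
      out <- a$out %||% "primers.tsv"
      write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
      message("wrote ", nrow(df), " primer pairs to ", out)
      df
    },
    "simulate" = {
      x <- read_construct(need("construct"))
      cfgs <- sim_config(
        depth = as.numeric(a$depth %||% 4e6),
        seq_error_rate = as.numeric(a$error_rate %||% 1e-3),
        rng_seed = as.integer(need("seed")))
      outdir <- a$outdir %||% "."
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      truth <- truth_landscape(x,
        midplane = as.numeric(a$midplane %||% 311))
      ref <- simulate_reference_counts(x, cfgs)
      sel <- simulate_selected_counts(ref, truth, cfgs)
      write_counts_tsv(ref, file.path(outdir, "reference_counts.tsv"))
      write_counts_tsv(sel, file.path(outdir, "selected_counts.tsv"))
      write_truth_json(truth, file.path(outdir, "truth.json"))
      if (isTRUE(a$fastq == "true" || isTRUE(a$fastq))) {
        emit_fastq(ref, x, cfgs, file.path(outdir, "reference_R1.fastq.gz"),
                   file.path(outdir, "reference_R2.fastq.gz"), stream = 2L)
        emit_fastq(sel, x, cfgs, file.path(outdir, "selected_R1.fastq.gz"),
                   file.path(outdir, "selected_R2.fastq.gz"), stream = 3L)
      }
      message("simulated counts written to ", outdir)
      invisible(NULL)
    },
    "count" = {
      x <- read_construct(need("construct"))
      ct <- count_population(need("r1"), need("r2"), x,
                             population = a$population %||% "reference")
      out <- a$out %||% "counts.tsv"
      write_counts_tsv(ct, out)
      message("counted ", ct$n_reads_passing, "/", ct$n_reads_total,
              " read pairs -> ", out)
      ct
    },
    "run-insertion" = run_insertion_pipeline(need("config")),
    "run-association" = run_association_pipeline(need("config")),
    "classify" = {
      stop("classify requires a DimerLandscape produced by run-association;",
           " use run-association, which writes position_labels.tsv")
    },
    "filter-models" = {
      labels <- read.delim(need("labels"), stringsAsFactors = FALSE)
      models <- strsplit(need("models"), ",")[[1]]
      df <- filter_dimer_models(models, labels)
      out <- a$out %||% "model_filter.tsv"
      write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
      message(sum(df$accepted), "/", nrow(df), " models accepted -> ", out)
      df
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(res)
}
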