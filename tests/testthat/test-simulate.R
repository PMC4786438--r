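test_that("truth landscape has zero wild type and finite values everywhere", {
  x <- example_construct("cls27")
  tr <- truth_landscape(x, midplane = 311)
  expect_true(all(is.finite(tr$ddg)))
  wt_idx <- cbind(seq_along(tr$positions), match(tr$wt_aa, colnames(tr$ddg)))
  expect_equal(unname(tr$ddg[wt_idx]), rep(0, 27))
  # stated-world anchors from the printed landscape: charged residues
  # disruptive at the core, hydrophobics favourable, Arg mild
  expect_equal(tr$ddg["311", "L"], -2, tolerance = 1e-12)
  expect_equal(tr$ddg["311", "R"], 1.5, tolerance = 1e-12)
  expect_gt(tr$ddg["307", "K"], 3)
})

test_that("reference counts are uniform in expectation when clonal bias is off", {
  x <- example_construct("cls27")
  # chi-square goodness of fit over 540 cells, 20 seeds, alpha = 0.01:
  # expect no more rejections than a small binomial tail allows
  p_vals <- vapply(1:20, function(s) {
    cfg <- sim_config(depth = 540 * 200, clonal_bias_sigma = 0,
                      rng_seed = s)
    ref <- simulate_reference_counts(x, cfg)
    cells <- c(ref$counts[!is.na(ref$counts)], ref$wildtype_count / 27)
    # wt pool aggregates 27 equal cells; spread it back for the test
    obs <- c(ref$counts[!is.na(ref$counts)],
             rep(ref$wildtype_count / 27, 27))
    suppressWarnings(stats::chisq.test(obs)$p.value)
  }, 0)
  expect_lte(sum(p_vals < 0.01), 2L)
})

test_that("zero depth gives an all-zero table and equal seeds give equal tables", {
  x <- example_construct("gpa")
  cfg0 <- sim_config(depth = 0, rng_seed = 5)
  t0 <- simulate_reference_counts(x, cfg0)
  expect_equal(sum(t0$counts, na.rm = TRUE), 0)
  expect_equal(t0$wildtype_count, 0)
  cfg <- sim_config(depth = 1e5, rng_seed = 42)
  a <- simulate_reference_counts(x, cfg)
  b <- simulate_reference_counts(x, cfg)
  expect_identical(a$counts, b$counts)
  sel_a <- simulate_selected_counts(a, truth_landscape(x, midplane = 82.5),
                                    cfg)
  sel_b <- simulate_selected_counts(b, truth_landscape(x, midplane = 82.5),
                                    cfg)
  expect_identical(sel_a$counts, sel_b$counts)
})

test_that("selection reweighting matches its closed form", {
  x <- example_construct("gpa")
  cfg <- sim_config(depth = 1e6, clonal_bias_sigma = 0, rng_seed = 9)
  ref <- simulate_reference_counts(x, cfg, expected = TRUE)

  # all-zero truth: selected frequencies equal reference frequencies
  flat <- truth_landscape(x, midplane = 82.5)
  flat$ddg[] <- 0
  sel <- simulate_selected_counts(ref, flat, cfg, expected = TRUE)
  expect_equal(sel$counts / total_counts(sel),
               ref$counts / total_counts(ref), tolerance = 1e-12)

  # single variant at +RT: infinite-depth limit s -> exp(-1)
  one <- flat
  one$ddg["82", "L"] <- rt_kcal(cfg$temperature)
  sel1 <- simulate_selected_counts(ref, one, cfg, expected = TRUE)
  s <- (sel1$counts["82", "L"] / sel1$wildtype_count) /
    (ref$counts["82", "L"] / ref$wildtype_count)
  expect_equal(unname(s), exp(-1), tolerance = 1e-12)
})

test_that("strong penalties reach the censoring regime at moderate depth", {
  # ddG = +6 kcal/mol at depth 1e5: expected selected count is far below 1
  # (Poisson tail), so the draw is 0 with high probability
  x <- example_construct("gpa")
  cfg <- sim_config(depth = 1e5, clonal_bias_sigma = 0, rng_seed = 21)
  ref <- simulate_reference_counts(x, cfg)
  tr <- truth_landscape(x, midplane = 82.5)
  tr$ddg[] <- 0
  tr$ddg["82", "K"] <- 6
  # independent Poisson computation of the zero-count probability
  exp_sel <- simulate_selected_counts(ref, tr, cfg, expected = TRUE)
  lambda <- exp_sel$counts["82", "K"]
  expect_gt(exp(-lambda), 0.95)
  zeros <- vapply(1:10, function(s) {
    cfg_s <- sim_config(depth = 1e5, clonal_bias_sigma = 0,
                        rng_seed = 100 + s)
    refs <- simulate_reference_counts(x, cfg_s)
    sels <- simulate_selected_counts(refs, tr, cfg_s)
    sels$counts["82", "K"] == 0
  }, TRUE)
  expect_gte(sum(zeros), 9L)
})

test_that("noiseless expected frequencies invert to the exact truth", {
  # selection-model self-consistency: no sampling anywhere
  x <- example_construct("cls27")
  truth <- truth_landscape(x, midplane = 311)
  cfg <- sim_config(depth = 1e6, rng_seed = 3)
  ref <- simulate_reference_counts(x, cfg, expected = TRUE)
  sel <- simulate_selected_counts(ref, truth, cfg, expected = TRUE)
  sc <- selection_coefficients(sel, ref)
  land <- to_ddg(sc)
  expect_equal(land$ddg, truth$ddg, tolerance = 1e-9)
})

test_that("FASTQ records are well-formed", {
  x <- example_construct("gpa")
  cfg <- sim_config(depth = 500, seq_error_rate = 0.001, rng_seed = 8)
  ref <- simulate_reference_counts(x, cfg)
  fq <- emit_fastq(ref, x, cfg, tempfile(fileext = ".fastq.gz"),
                   tempfile(fileext = ".fastq.gz"))
  for (f in fq) {
    lines <- readLines(f)
    expect_equal(length(lines) %% 4L, 0L)
    expect_equal(length(lines) / 4L, 500)
    expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
    expect_true(all(lines[seq(3, length(lines), 4)] == "+"))
    expect_equal(nchar(lines[seq(2, length(lines), 4)]),
                 nchar(lines[seq(4, length(lines), 4)]))
  }
  # amplicon longer than combined coverage errors out
  cfg_short <- sim_config(depth = 10, rng_seed = 1, read_length = 40L)
  expect_error(emit_fastq(ref, x, cfg_short, tempfile(), tempfile()),
               "combined read coverage")
})

test_that("count tables round-trip through TSV", {
  x <- example_construct("gpa")
  cfg <- sim_config(depth = 2e4, rng_seed = 13)
  ref <- simulate_reference_counts(x, cfg)
  f <- tempfile(fileext = ".tsv")
  write_counts_tsv(ref, f)
  back <- read_counts_tsv(f, x)
  expect_equal(back$counts, ref$counts)
  expect_equal(back$wildtype_count, ref$wildtype_count)
})
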