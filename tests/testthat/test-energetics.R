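# hand-buildable count tables over a one-position span
.one_pos_tables <- function(ref_counts, sel_counts, wt_ref, wt_sel,
                            fill = 1000) {
  x <- construct("one", dna = "ACGGCTACGTAC", span_start = 2,
                 span_end = 2, upstream_flank = "GGGG",
                 downstream_flank = "CCCC")   # position 2 is Ala
  mk <- function(counts, wt_count, pop) {
    m <- matrix(NA_real_, 1, 20, dimnames = list("2", memscan:::AA20))
    m[1, setdiff(memscan:::AA20, "A")] <- fill
    m[1, names(counts)] <- counts
    count_table(x, m, wt_count, population = pop)
  }
  list(construct = x,
       ref = mk(ref_counts, wt_ref, "reference"),
       sel = mk(sel_counts, wt_sel, "insertion-selected"))
}

test_that("frequencies implement count ratios with wild type at 1", {
  tb <- .one_pos_tables(c(L = 500), c(L = 500), 1000, 1000)
  p <- frequencies(tb$ref)
  expect_equal(unname(p["2", "L"]), 0.5)
  expect_equal(unname(p["2", "A"]), 1)       # wild-type identity cell
  # invariant to duplicating every read
  tb2 <- .one_pos_tables(c(L = 1000), c(L = 1000), 2000, 2000,
                         fill = 2000)
  expect_equal(frequencies(tb2$ref), p)
  # zero wild-type count is a hard error
  expect_error(frequencies(.one_pos_tables(c(L = 1), c(L = 1), 0, 1)$ref),
               "wild-type")
})

test_that("selection coefficients and the Gibbs transform match closed forms", {
  rt <- 1.9872e-3 * 310                     # 0.616032 kcal/mol
  # identical populations: s = 1 everywhere, ddg exactly 0
  tb <- .one_pos_tables(c(L = 800), c(L = 800), 1000, 1000)
  sc <- selection_coefficients(tb$sel, tb$ref)
  expect_true(all(sc$s == 1))
  land0 <- to_ddg(sc)
  expect_true(all(land0$ddg == 0))

  # selected frequency half of reference -> s = 0.5
  tb2 <- .one_pos_tables(c(L = 800), c(L = 400), 1000, 1000)
  expect_equal(unname(selection_coefficients(tb2$sel, tb2$ref)$s["2", "L"]),
               0.5)

  # worked example: ref (mut 1000, wt 1000), sel (mut 100, wt 1000)
  # -> s = 0.1, ddg = -RT ln 0.1
  tb3 <- .one_pos_tables(c(L = 1000), c(L = 100), 1000, 1000)
  land <- to_ddg(selection_coefficients(tb3$sel, tb3$ref))
  expect_equal(unname(land$ddg["2", "L"]), -rt * log(0.1),
               tolerance = 1e-9 / abs(rt * log(0.1)))

  # s = exp(-1) -> ddg = +RT
  tb4 <- .one_pos_tables(c(L = 1000), c(L = round(1000 * exp(-1))),
                         1000, 1000)
  s4 <- unname(selection_coefficients(tb4$sel, tb4$ref)$s["2", "L"])
  expect_equal(-rt * log(s4), unname(to_ddg(
    selection_coefficients(tb4$sel, tb4$ref))$ddg["2", "L"]),
    tolerance = 1e-12)
  expect_equal(-rt * log(exp(-1)), rt)

  # to_ddg is strictly decreasing in s
  ss <- c(0.05, 0.2, 1, 4, 20)
  dd <- vapply(ss, function(s) {
    t <- .one_pos_tables(c(L = 1000), c(L = 1000 * s), 1000, 1000)
    unname(to_ddg(selection_coefficients(t$sel, t$ref))$ddg["2", "L"])
  }, 0)
  expect_true(all(diff(dd) < 0))
})

test_that("zero selected counts are censored with a pseudocount lower bound", {
  tb <- .one_pos_tables(c(L = 1000), c(L = 0), 1000, 1000)
  sc <- selection_coefficients(tb$sel, tb$ref)
  expect_true(sc$censored["2", "L"])
  expect_equal(unname(sc$s["2", "L"]), 0)
  land <- to_ddg(sc, pseudocount = 1)
  # bound equals the value a single read would give
  tb1 <- .one_pos_tables(c(L = 1000), c(L = 1), 1000, 1000)
  land1 <- to_ddg(selection_coefficients(tb1$sel, tb1$ref))
  expect_equal(land$ddg["2", "L"], land1$ddg["2", "L"])
  expect_true(land$censored["2", "L"])
  expect_false(land1$censored["2", "L"])
})

test_that("Ala re-referencing subtracts the Ala column and is reversible", {
  w <- cls27_world(seed = 23, depth = 4e5)
  la <- relative_to_ala(w$landscape)
  expect_true(all(la$ddg[, "A"] == 0, na.rm = TRUE))
  # subtracting then adding the Ala column restores the input
  back <- la$ddg + w$landscape$ddg[, "A"]
  expect_equal(back, w$landscape$ddg)
  # per-position constant offsets are annihilated
  shifted <- w$landscape
  shifted$ddg <- shifted$ddg + seq_along(shifted$positions)
  expect_equal(relative_to_ala(shifted)$ddg, la$ddg)
})

test_that("running average matches hand arithmetic and shrinks at ends", {
  expect_equal(smooth_profile(rep(3, 7)), rep(3, 7))
  lin <- 1:9
  expect_equal(smooth_profile(lin)[3:7], 3:7)    # interior of linear series
  expect_equal(smooth_profile(c(0, 0, 5, 0, 0))[3], 1.0)
  # masked neighbours are excluded, not imputed
  expect_equal(smooth_profile(c(1, NA, 1, 1, 1))[3], 1)
  expect_true(is.na(smooth_profile(c(NA, NA, NA))[2]))
  # edge windows shrink symmetrically: first value averages 1 neighbour side
  expect_equal(smooth_profile(c(4, 8, 12, 16, 20))[1], 4)
  expect_equal(smooth_profile(c(4, 8, 12, 16, 20))[2], 8)
})

test_that("mid-plane estimation finds planted troughs and is equivariant", {
  x <- example_construct("cls27")
  mk_land <- function(centre, positions = span_positions(x)) {
    ddg <- matrix(0, length(positions), 20,
                  dimnames = list(positions, memscan:::AA20))
    for (aa in c("L", "I", "M", "F"))
      ddg[, aa] <- 0.05 * (positions - centre)^2 - 2
    structure(list(ddg = ddg, mask = ddg * 0 > 1, censored = ddg * 0 > 1,
                   positions = positions, wt_aa = wildtype_aa(x),
                   relative_to = "Ala"),
              class = "EnergyLandscape")
  }
  expect_equal(estimate_midplane(mk_land(305)), 305)
  expect_equal(estimate_midplane(mk_land(311)), 311)
  # recovery of a randomly placed truth mid-plane across 50 simulated scans
  set.seed(99)
  centres <- sample(303:315, 50, replace = TRUE)
  err <- vapply(seq_along(centres), function(k) {
    tr <- truth_landscape(x, midplane = centres[k])
    cfg <- sim_config(depth = 4e6, rng_seed = 1000 + k)
    ref <- simulate_reference_counts(x, cfg)
    sel <- simulate_selected_counts(ref, tr, cfg)
    land <- to_ddg(selection_coefficients(sel, ref,
                                          apply_reference_filter(ref)))
    abs(estimate_midplane(relative_to_ala(land)) - centres[k])
  }, 0)
  expect_true(all(err <= 1))
})

test_that("quartic profile fits recover known coefficients and flag sparse data", {
  x <- example_construct("cls27")
  pos <- span_positions(x)
  z <- (pos - 306) * 1.5
  co_true <- c(0.5, -0.1, 0.02, 1e-3, -1e-5)
  vals <- co_true[1] + co_true[2] * z + co_true[3] * z^2 +
    co_true[4] * z^3 + co_true[5] * z^4
  # a landscape whose Leu column is exactly that quartic; smoothing is
  # bypassed by feeding a window of 1
  ddg <- matrix(0, length(pos), 20, dimnames = list(pos, memscan:::AA20))
  ddg[, "L"] <- vals
  land <- structure(list(ddg = ddg, mask = ddg > Inf, censored = ddg > Inf,
                         positions = pos, wt_aa = wildtype_aa(x),
                         relative_to = "Ala"),
                    class = "EnergyLandscape")
  prof <- fit_profiles(land, midplane = 306, window = 1L,
                       excluded = integer())
  expect_equal(unname(prof$coefficients["L", ]), co_true,
               tolerance = 1e-9)
  expect_equal(unname(prof$coefficients["A", ]), rep(0, 5))
  # fewer than 6 points -> flagged unfit
  land2 <- land
  land2$ddg[6:27, "W"] <- NA
  prof2 <- fit_profiles(land2, midplane = 306, window = 1L,
                        excluded = integer())
  expect_true("W" %in% prof2$unfit)
  # excluded positions are absent from the stored fit points
  prof3 <- fit_profiles(land, midplane = 306, window = 1L,
                        excluded = c(307L, 308L))
  expect_false(any(prof3$points[["L"]]$position %in% c(307, 308)))
})

test_that("propensities are Boltzmann weights with exact normalization", {
  x <- example_construct("gpa")
  pos <- span_positions(x)
  e <- matrix(0, length(pos), 20, dimnames = list(pos, memscan:::AA20))
  land <- structure(list(ddg = e, positions = pos, relative_to = "Ala"),
                    class = "EnergyLandscape")
  p <- propensities(land)
  expect_equal(unname(p[1, ]), rep(0.05, 20))
  # E_Leu = -2, others 0: p_Leu = e^(2/RT) / (e^(2/RT) + 19)
  rt <- 1.9872e-3 * 310
  e2 <- e; e2[, "L"] <- -2
  land2 <- structure(list(ddg = e2, positions = pos, relative_to = "Ala"),
                     class = "EnergyLandscape")
  p2 <- propensities(land2)
  expect_equal(unname(p2[1, "L"]), exp(2 / rt) / (exp(2 / rt) + 19),
               tolerance = 1e-12)
  # rows sum to 1 and constant shifts cancel
  expect_equal(unname(rowSums(p2)), rep(1, length(pos)), tolerance = 1e-12)
  land3 <- land2; land3$ddg <- land3$ddg + 7
  expect_equal(propensities(land3), p2)
  # a dominant (very negative) energy takes probability ~1
  e4 <- e; e4[, "K"] <- -50
  land4 <- structure(list(ddg = e4, positions = pos, relative_to = "Ala"),
                     class = "EnergyLandscape")
  expect_gt(min(propensities(land4)[, "K"]), 1 - 1e-10)
})

test_that("landscape, profile and propensity exports round-trip", {
  w <- cls27_world(seed = 31, depth = 4e5)
  la <- relative_to_ala(w$landscape)
  prof <- fit_profiles(la, 311)
  f <- tempfile(fileext = ".json")
  write_profile_json(prof, f)
  back <- read_profile_json(f)
  expect_equal(back$coefficients, prof$coefficients, tolerance = 1e-12)
  expect_equal(back$midplane, prof$midplane)
  ftsv <- tempfile(fileext = ".tsv")
  write_landscape_tsv(w$landscape, ftsv)
  df <- read.delim(ftsv)
  expect_equal(nrow(df), 540L)
  fpm <- tempfile(fileext = ".tsv")
  write_propensity_matrix(propensities(la), fpm)
  pm <- read.delim(fpm, check.names = FALSE)
  expect_equal(dim(pm), c(20L, 28L))   # aa column + 27 positions
})
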