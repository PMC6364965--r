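test_that("quality filter keeps strictly-greater months and is idempotent", {
  p <- data.frame(site_id = "A", year = 2000, month = 1:3,
                  nee = c(1, 2, 3), nee_quality = c(0.79, 0.80, 0.81))
  out <- qc_filter(p, 0.8)
  expect_identical(is.na(out$nee), c(TRUE, TRUE, FALSE))
  expect_equal(attr(out, "n_retained"), 1)
  expect_identical(qc_filter(out, 0.8)$nee, out$nee)

  all_good <- transform(p, nee_quality = 1)
  expect_false(anyNA(qc_filter(all_good, 0.8)$nee))

  expect_error(qc_filter(p, 0), "threshold")
  expect_error(qc_filter(p, 1.2), "threshold")

  # uniform quality: retained count within the central 99% binomial interval
  set.seed(42)
  pu <- data.frame(site_id = "A", year = rep(2000:2009, each = 12),
                   month = rep(1:12, 10), nee = rnorm(120),
                   nee_quality = runif(120))
  kept <- attr(qc_filter(pu, 0.8), "n_retained")
  expect_gte(kept, qbinom(0.005, 120, 0.2))
  expect_lte(kept, qbinom(0.995, 120, 0.2))
})

test_that("shadow-feature selection finds real predictors and flags null cases", {
  set.seed(7)
  n <- 120
  cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  # target is an exact copy of one candidate
  sel <- select_features(cand, cand$a, seed = 1, n_repeats = 10)
  expect_identical(as.character(sel), "a")
  expect_false(attr(sel, "none_significant"))

  # target independent of everything: single fallback predictor, flagged
  sel0 <- select_features(cand, rnorm(n), seed = 1, n_repeats = 10)
  expect_length(sel0, 1)
  expect_true(attr(sel0, "none_significant"))

  # duplicated informative columns: at least one survives, deterministically
  cand2 <- data.frame(a = cand$a, a2 = cand$a, b = cand$b)
  sel2 <- select_features(cand2, cand$a + rnorm(n, 0, 0.01), seed = 3,
                          n_repeats = 10)
  expect_true(any(c("a", "a2") %in% sel2))
  sel2b <- select_features(cand2, cand$a + rnorm(n, 0, 0.01), seed = 3,
                           n_repeats = 10)
  expect_identical(as.character(sel2), as.character(sel2b))

  expect_error(select_features(cand[1:30, ], rnorm(30), seed = 1),
               "insufficient")
})

make_gappy <- function(seed = 1, gap = 0.3, n_sites = 6) {
  cfg <- generator_config(n_sites = n_sites, period = c(1998L, 2007L),
                          window_period = c(2000L, 2007L),
                          window_years = c(3L, 6L),
                          gap_rate_reflectance = gap,
                          tropical_gap_factor = 1,
                          aux_start_year = 2000L, master_seed = seed)
  generate_dataset(cfg)
}

test_that("stage-1 gap-filling fills only aux-covered months and never overwrites", {
  ds <- make_gappy(2)
  before <- ds$panels
  filled <- gapfill_stage1(ds$panels, ds$aux, seed = 9)
  b <- "nir"
  obs <- !is.na(before[[b]])
  # observed cells unchanged
  expect_identical(filled[[b]][obs], before[[b]][obs])
  expect_true(all(filled[[paste0("src_", b)]][obs] == "observed"))
  # gaps before aux coverage (pre-2000) stay missing
  pre <- before$year < 2000 & !obs
  expect_true(all(is.na(filled[[b]][pre])))
  expect_true(all(filled[[paste0("src_", b)]][pre] == "missing"))
  # gaps inside coverage are filled and flagged
  post <- before$year >= 2000 & !obs
  expect_false(anyNA(filled[[b]][post]))
  expect_true(all(filled[[paste0("src_", b)]][post] == "stage1"))

  # zero gaps: values pass through untouched
  ds0 <- tiny_samples(1)$dataset
  f0 <- gapfill_stage1(ds0$panels, ds0$aux, seed = 1)
  for (b in fluxmem:::BANDS) expect_identical(f0[[b]], ds0$panels[[b]])
})

test_that("stage-2 fills every remaining gap from climate and site descriptors", {
  ds <- make_gappy(3)
  f1 <- gapfill_stage1(ds$panels, ds$aux, seed = 9)
  f2 <- gapfill_stage2(f1, ds$sites, seed = 9)
  for (b in fluxmem:::BANDS) {
    expect_false(anyNA(f2[[b]]))
    expect_true(all(f2[[paste0("src_", b)]] %in%
                      c("observed", "stage1", "stage2")))
  }
  # provenance partitions cells: stage-2 only where stage 1 could not reach
  pre <- ds$panels$year < 2000 & is.na(ds$panels$nir)
  expect_true(all(f2$src_nir[pre] == "stage2"))

  # no remaining gaps: no-op
  f2b <- gapfill_stage2(f2, ds$sites, seed = 10)
  expect_identical(f2b$nir, f2$nir)

  # a band with no observations at all cannot be trained
  broken <- f1
  broken$blue <- NA_real_
  expect_error(gapfill_stage2(broken, ds$sites, seed = 1), "blue")

  # a band that is a pure function of calendar month is recovered at about
  # the month mean (tree-ensemble tolerance)
  ds2 <- make_gappy(4)
  month_mean <- c(0.2, 0.22, 0.3, 0.4, 0.5, 0.6, 0.62, 0.6, 0.5, 0.4, 0.3, 0.22)
  ds2$panels$nir <- ifelse(is.na(ds2$panels$nir), NA,
                           month_mean[ds2$panels$month])
  f <- gapfill_stage2(src_copy <- fluxmem:::src_cols(ds2$panels), ds2$sites,
                      seed = 2)
  gap <- is.na(ds2$panels$nir)
  expect_lt(max(abs(f$nir[gap] - month_mean[ds2$panels$month[gap]])), 0.1)
})

test_that("climate down-scaling selects by skill and is order-invariant", {
  set.seed(11)
  n <- 120
  nb <- matrix(rnorm(3 * n, 10, 3), n, 3)
  # site equals neighbor 1: the linear family is perfect
  y1 <- nb[, 1]
  y1[sample(n, 20)] <- NA
  r1 <- downscale_climate(y1, nb, variable = "tair", seed = 1)
  expect_identical(r1$selection$chosen_family, "linear")
  expect_gt(r1$selection$candidate_scores[["linear"]], 0.999)
  expect_false(anyNA(r1$filled))
  expect_false(r1$selection$low_skill)

  # independent noise: still returns a choice; skill near or below zero and
  # the low-skill flag mirrors the scores
  y0 <- rnorm(n); y0[sample(n, 20)] <- NA
  r0 <- suppressWarnings(downscale_climate(y0, nb, variable = "tair", seed = 1))
  expect_true(all(r0$selection$candidate_scores < 0.3))
  expect_identical(r0$selection$low_skill,
                   max(r0$selection$candidate_scores) <= 0)
  expect_type(r0$selection$chosen_family, "character")

  # family list order never changes the choice
  r1b <- downscale_climate(y1, nb, variable = "tair",
                           families = rev(fluxmem:::DOWNSCALE_FAMILIES),
                           seed = 1)
  expect_identical(r1b$selection$chosen_family, r1$selection$chosen_family)

  # precipitation switches the selection metric to RMSE
  rp <- downscale_climate(y1, nb, variable = "precip", seed = 1)
  expect_identical(rp$selection$metric, "rmse")

  # short overlap: pass-through with a warning
  yshort <- rep(NA_real_, n); yshort[1:20] <- nb[1:20, 1]
  expect_warning(rs <- downscale_climate(yshort, nb, seed = 1), "overlap")
  expect_identical(rs$filled, yshort)
})

test_that("a blended site series prefers the linear family in most replicates", {
  set.seed(21)
  n <- 120
  wins <- 0
  for (rep in 1:40) {
    nb <- matrix(rnorm(3 * n, 15, 4), n, 3)
    y <- 0.5 * (nb[, 1] + nb[, 2]) + rnorm(n, 0, 0.2)
    y[sample(n, 24)] <- NA
    r <- downscale_climate(y, nb, variable = "tair", seed = rep)
    wins <- wins + (r$selection$chosen_family == "linear")
  }
  expect_gte(wins / 40, 0.95)
})
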