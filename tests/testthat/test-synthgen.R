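test_that("configuration validation names the offending field", {
  expect_error(generator_config(n_sites = 0), "n_sites")
  expect_error(generator_config(lambda = 0), "lambda")
  expect_no_error(generator_config(lambda = 0, allow_infinite_memory = TRUE))
  expect_error(generator_config(period = c(2000, 2002)), "period")
  expect_error(generator_config(disturbance_prob = 1.5), "disturbance_prob")
  expect_error(generator_config(qc_alpha = -1), "qc_alpha")
  expect_error(generator_config(window_period = c(1990, 2015),
                                period = c(2000, 2015)), "window_period")
})

test_that("site generation is seeded-deterministic and respects windows", {
  cfg <- tiny_config(3)
  s1 <- generate_sites(cfg)
  s2 <- generate_sites(cfg)
  expect_identical(s1, s2)
  # windows inside the configured placement period, 3-5 years long
  expect_true(all(s1$win_start_year >= 2001 & s1$win_end_year <= 2006))
  len <- (s1$win_end_year * 12 + s1$win_end_month) -
         (s1$win_start_year * 12 + s1$win_start_month) + 1
  expect_true(all(len %in% (12 * 3:5)))
  # climate class is a deterministic function of |latitude|
  expect_identical(s1$climate_class,
                   fluxmem:::climate_class_of(s1$latitude))
  # adding sites must not perturb existing ones (hierarchical seeding)
  cfg_more <- tiny_config(3); cfg_more$n_sites <- 12L
  s3 <- generate_sites(cfg_more)
  expect_identical(s1$latitude, s3$latitude[1:8])
})

test_that("disturbance count falls in the central 99% binomial interval", {
  cfg <- generator_config(n_sites = 200, disturbance_prob = 0.25,
                          master_seed = 1)
  sites <- generate_sites(cfg)
  n_dist <- sum(!is.na(sites$disturbance_year))
  lo <- qbinom(0.005, 200, 0.25)
  hi <- qbinom(0.995, 200, 0.25)
  expect_gte(n_dist, lo)
  expect_lte(n_dist, hi)
  expect_true(all(sites$disturbance_year >= cfg$period[1] &
                  sites$disturbance_year <= cfg$period[2], na.rm = TRUE))
})

test_that("climate phase flips across hemispheres, amplitude does not", {
  cfg <- tiny_config(1, noise = zero_noise())
  north <- simulate_climate(manual_site(latitude = 45), cfg)
  south <- simulate_climate(manual_site(latitude = -45), cfg)
  # warm-season peak 6 months apart
  expect_equal(which.max(north$tair[1:12]), 7)
  expect_equal(which.max(south$tair[1:12]), 1)
  expect_equal(max(north$tair) - min(north$tair),
               max(south$tair) - min(south$tair), tolerance = 1e-12)
  # noise-free series are exactly periodic with period 12
  for (v in c("tair", "precip", "rg", "vpd", "rpot"))
    expect_equal(north[[v]][1:12], north[[v]][13:24], tolerance = 1e-12,
                 ignore_attr = TRUE)
  # VPD monotone in temperature (noise-free)
  expect_true(all(diff(north$vpd[order(north$tair)]) >= 0))
  expect_true(all(north$precip >= 0))
})

test_that("top-of-atmosphere radiation has smaller annual range at the equator", {
  r0 <- fluxmem:::rpot_toa(0, 1:12)
  r45 <- fluxmem:::rpot_toa(45, 1:12)
  expect_lt(diff(range(r0)), diff(range(r45)))
  expect_true(all(r0 > 0) && all(r45 > 0))
})

test_that("vegetation is periodic without disturbance and recovers exponentially with it", {
  cfg <- tiny_config(1, noise = zero_noise())
  site <- manual_site()
  clim <- simulate_climate(site, cfg)
  veg <- simulate_vegetation(site, clim, cfg)
  expect_equal(veg$greenness[1:12], veg$greenness[13:24], tolerance = 1e-12)
  # bands are affine in greenness: perfect correlation without noise
  expect_equal(abs(cor(veg$reflectance$nir, veg$greenness)), 1,
               tolerance = 1e-10)
  expect_gt(cor(veg$reflectance$nir, veg$greenness), 0)
  expect_lt(cor(veg$reflectance$red, veg$greenness), 0)
  expect_true(all(veg$reflectance$nir >= 0 & veg$reflectance$nir <= 1))

  # disturbance: drop 0.5, tau 24 -> at +24 months 1 - e^-1 of the drop is back
  cfg2 <- tiny_config(1, noise = zero_noise(), disturbance_drop = 0.5,
                      recovery_tau = 24)
  site2 <- manual_site(disturbance_year = 2001L, disturbance_month = 3L)
  veg2 <- simulate_vegetation(site2, clim, cfg2)
  td <- which(clim$year == 2001 & clim$month == 3)
  g_ref <- veg$greenness
  deficit_frac <- 1 - veg2$greenness[td + 24] / g_ref[td + 24]
  expect_equal(deficit_frac, 0.5 * exp(-1), tolerance = 1e-10)
})

test_that("NEE memory mechanics follow the pool recursion", {
  cfg <- tiny_config(1, noise = zero_noise())
  site <- manual_site()
  clim <- simulate_climate(site, cfg)
  veg <- simulate_vegetation(site, clim, cfg)

  # epsilon = 0: no uptake, zero pool, NEE is noise only (here: exactly 0)
  cfg0 <- tiny_config(1, noise = zero_noise(), epsilon = 0, c0 = 0)
  flux0 <- simulate_nee(site, clim, veg$greenness, cfg0)
  expect_true(all(flux0$gpp == 0))
  expect_true(all(flux0$nee == 0))

  # lambda = 1, gamma = 1: pure one-month lag
  cfg1 <- tiny_config(1, noise = zero_noise(), lambda = 1, gamma = 1, c0 = 0)
  flux1 <- simulate_nee(site, clim, veg$greenness, cfg1)
  n <- nrow(clim)
  expect_equal(flux1$cpool[2:n], flux1$gpp[1:(n - 1)], tolerance = 1e-12)

  # constant GPP g, lambda = 0.2: pool converges to 5 g by t = 60
  clim_const <- clim
  clim_const$rg <- 100; clim_const$tair <- 15; clim_const$vpd <- 10
  g_const <- rep(0.5, n)
  cfg2 <- tiny_config(1, noise = zero_noise(), lambda = 0.2, gamma = 1, c0 = 0)
  flux2 <- simulate_nee(site, clim_const, g_const, cfg2)
  expect_equal(flux2$cpool[60], 5 * flux2$gpp[1], tolerance = 1e-4)

  # memory by construction: positive partial correlation of NEE_t with
  # GPP_{t-1} given GPP_t in the noise-free limit
  flux <- simulate_nee(site, clim, veg$greenness, cfg)
  t_idx <- 2:n
  r_nee <- resid(lm(flux$nee[t_idx] ~ flux$gpp[t_idx]))
  r_lag <- resid(lm(flux$gpp[t_idx - 1] ~ flux$gpp[t_idx]))
  expect_gt(cor(r_nee, r_lag), 0)

  # memoryless limit: lambda = 1, gamma = 0 -> NEE = -GPP exactly
  cfgm <- tiny_config(1, noise = zero_noise(), lambda = 1, gamma = 0, c0 = 0)
  fluxm <- simulate_nee(site, clim, veg$greenness, cfgm)
  expect_equal(fluxm$nee, -fluxm$gpp, tolerance = 1e-12)
})

test_that("observation model masks reflectance at the configured rate", {
  # gap rate 0: nothing missing
  ds0 <- tiny_samples(1)$dataset
  expect_false(anyNA(ds0$panels[, fluxmem:::BANDS]))

  # gap rate 1: everything withheld
  cfg1 <- tiny_config(1, gap_rate_reflectance = 1)
  ds1 <- generate_dataset(cfg1)
  expect_true(all(is.na(ds1$panels[, fluxmem:::BANDS])))

  # gap rate 0.3 on non-tropical sites: overall withheld fraction in the
  # central 99% binomial interval
  cfg <- generator_config(n_sites = 25, period = c(2000L, 2009L),
                          window_period = c(2001L, 2009L),
                          window_years = c(3L, 6L),
                          gap_rate_reflectance = 0.3,
                          tropical_gap_factor = 1, master_seed = 2)
  ds <- generate_dataset(cfg)
  n_cells <- nrow(ds$panels) * length(fluxmem:::BANDS)
  n_miss <- sum(is.na(ds$panels[, fluxmem:::BANDS]))
  expect_gte(n_miss, qbinom(0.005, n_cells, 0.3))
  expect_lte(n_miss, qbinom(0.995, n_cells, 0.3))

  # NEE only inside the measurement window
  s <- ds$sites[1, ]
  p <- ds$panels[ds$panels$site_id == s$site_id, ]
  ym <- p$year * 12 + p$month
  inwin <- ym >= s$win_start_year * 12 + s$win_start_month &
           ym <= s$win_end_year * 12 + s$win_end_month
  expect_true(all(is.na(p$nee[!inwin])))
  expect_true(all(!is.na(p$nee[inwin])))
  q <- p$nee_quality[inwin]
  expect_true(all(q >= 0 & q <= 1))
})

test_that("datasets serialize reproducibly and panels are gap-free in time", {
  cfg <- tiny_config(5)
  ds <- generate_dataset(cfg)
  # 7-year panel: 84 consecutive months per site, no duplicates
  for (sid in ds$sites$site_id[1:3]) {
    p <- ds$panels[ds$panels$site_id == sid, ]
    expect_equal(nrow(p), 84)
    expect_false(any(duplicated(p[, c("year", "month")])))
    expect_equal(diff(p$year * 12 + p$month), rep(1, 83))
  }
  d1 <- file.path(tempdir(), "fmds1"); d2 <- file.path(tempdir(), "fmds2")
  write_dataset(ds, d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  back <- read_dataset(d1)
  expect_equal(back$sites$latitude, ds$sites$latitude, tolerance = 1e-12)
  expect_equal(back$panels$nee, ds$panels$nee, tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("no greenness breakpoints appear when disturbances are off", {
  # oracle: seasonally adjusted CUSUM scan on the latent greenness
  scan_break <- function(g, month) {
    ga <- g - ave(g, month)
    z <- cumsum(ga - mean(ga)) / (sd(ga) * sqrt(length(ga)))
    max(abs(z))
  }
  # year-scale greenness anomalies are off in both arms so the scan
  # isolates the disturbance breakpoint against month-scale noise
  cfg_off <- tiny_config(7, disturbance_prob = 0,
                         noise = list(greenness_iav = 0))
  ds_off <- generate_dataset(cfg_off)
  stats_off <- sapply(split(ds_off$truth, ds_off$truth$site_id),
                      function(d) scan_break(d$greenness, d$month))
  # sensitivity 2.5 accommodates the month-scale AR(1) greenness noise,
  # which inflates the CUSUM relative to white noise
  expect_true(all(stats_off < 2.5))

  # positive control: a forced disturbance trips the same scan
  cfg_on <- tiny_config(7, disturbance_prob = 1, disturbance_drop = 0.6,
                        recovery_tau = 60, noise = list(greenness_iav = 0))
  ds_on <- generate_dataset(cfg_on)
  stats_on <- sapply(split(ds_on$truth, ds_on$truth$site_id),
                     function(d) scan_break(d$greenness, d$month))
  expect_gt(mean(stats_on > 2.5), 0.5)
})
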