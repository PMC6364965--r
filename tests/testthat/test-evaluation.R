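test_that("NSE follows its defining formula and edge cases", {
  obs <- c(1, 2, 3)
  expect_equal(nse(obs, obs), 1)
  expect_equal(nse(obs, rep(2, 3)), 0)
  expect_equal(nse(obs, c(1, 2, 4)), 0.5)
  expect_error(nse(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(nse(1, 1), "equal-length")
})

test_that("the metric suite separates correlation from agreement", {
  obs <- c(0.3, -1.2, 2.1, 0.7, -0.5)
  m <- metric_suite(obs, obs + 1)
  expect_equal(m$r2, 1)
  expect_equal(m$mae, 1)
  expect_lt(m$nse, 1)

  # anti-correlated predictions on zero-mean obs: R2 = 1, NSE = -3
  m2 <- metric_suite(c(-1, 1), c(1, -1))
  expect_equal(m2$r2, 1)
  expect_equal(m2$nse, -3)

  m3 <- metric_suite(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(m3$rmse, sqrt(0.5))
  expect_equal(m3$mae, 0.5)
})

test_that("NSE is affine-invariant and MAE scales linearly", {
  set.seed(3)
  obs <- rnorm(50); pred <- obs + rnorm(50, 0, 0.5)
  a <- 3.7; b <- -1.2
  expect_equal(nse(a * obs + b, a * pred + b), nse(obs, pred),
               tolerance = 1e-12)
  expect_equal(metric_suite(a * obs, a * pred)$mae,
               abs(a) * metric_suite(obs, pred)$mae, tolerance = 1e-12)
})

test_that("complete years require all twelve months", {
  yr <- rep(2001:2005, each = 12); mo <- rep(1:12, 5)
  expect_equal(complete_years(yr, mo), 2001:2005)
  mask <- rep(TRUE, 60); mask[yr == 2003 & mo == 1] <- FALSE
  expect_equal(complete_years(yr, mo, mask), c(2001, 2002, 2004, 2005))

  # uniform quality through the 0.8 filter leaves essentially no complete year
  ds <- generate_dataset(tiny_config(9, qc_alpha = 1, qc_beta = 1))
  p <- qc_filter(ds$panels)
  n_complete <- sum(sapply(split(p, p$site_id), function(d)
    length(complete_years(d$year, d$month, !is.na(d$nee)))))
  expect_equal(n_complete, 0)
})

test_that("hemisphere alignment shifts the south by six months", {
  expect_equal(hemisphere_align(1, -30), 7)
  expect_equal(hemisphere_align(7, -30), 1)
  expect_equal(hemisphere_align(1:12, 45), 1:12)
  twice <- hemisphere_align(hemisphere_align(1:12, -10), -10)
  expect_equal(twice, 1:12)
})

fake_table <- function(n_sites = 3, years = 2001:2004, site_offsets = NULL) {
  rows <- list()
  for (i in seq_len(n_sites)) {
    yr <- rep(years, each = 12); mo <- rep(1:12, length(years))
    obs <- sin(2 * pi * mo / 12) + 0.1 * (yr - mean(years)) + i + rnorm(length(yr), 0, 0.05)
    off <- if (is.null(site_offsets)) 0 else site_offsets[i]
    rows[[i]] <- data.frame(site_id = sprintf("S%02d", i), year = yr,
                            month = mo, obs = obs, pred = obs + off)
  }
  do.call(rbind, rows)
}

test_that("decomposition identities hold exactly", {
  set.seed(8)
  tab <- fake_table()
  d <- decompose(tab)
  # monthly value = calendar-month mean + seasonal anomaly, per site
  for (sid in unique(tab$site_id)) {
    sub <- tab[tab$site_id == sid, ]
    anoms <- d$seasonal_anomalies[d$seasonal_anomalies$site_id == sid, ]
    mmeans <- tapply(sub$obs, sub$month, mean)
    expect_equal(anoms$obs + mmeans[as.character(anoms$month)], sub$obs,
                 ignore_attr = TRUE, tolerance = 1e-12)
    # anomalies average to zero per site-month
    expect_equal(max(abs(tapply(anoms$obs, anoms$month, mean))), 0,
                 tolerance = 1e-12)
  }
  # interannual anomalies sum to zero per site
  ia <- d$interannual_anomalies
  expect_equal(max(abs(tapply(ia$obs, ia$site_id, sum))), 0, tolerance = 1e-12)
  expect_equal(max(abs(tapply(ia$pred, ia$site_id, sum))), 0,
               tolerance = 1e-12)
  # across-site: one row per site
  expect_equal(nrow(d$across_site), 3)

  # hand-checked interannual arithmetic: annual means 10, 12, 14
  tab2 <- data.frame(site_id = "A", year = rep(2001:2003, each = 12),
                     month = rep(1:12, 3),
                     obs = rep(c(10, 12, 14), each = 12),
                     pred = rep(c(10, 12, 14), each = 12))
  ia2 <- decompose(tab2)$interannual_anomalies
  expect_equal(ia2$obs, c(-2, 0, 2))

  # a site with identical years has all-zero anomalies
  tab3 <- tab2; tab3$obs <- rep(sin(1:12), 3); tab3$pred <- tab3$obs
  d3 <- decompose(tab3)
  expect_equal(max(abs(d3$seasonal_anomalies$obs)), 0, tolerance = 1e-12)
  expect_equal(max(abs(d3$interannual_anomalies$obs)), 0, tolerance = 1e-12)
})

test_that("sites below the complete-year threshold are excluded from anomalies", {
  set.seed(2)
  tab <- fake_table(n_sites = 2)
  # cripple site 2: only two complete years
  tab <- tab[!(tab$site_id == "S02" & tab$year %in% 2001:2002), ]
  d <- decompose(tab, min_years = 3)
  expect_false("S02" %in% d$seasonal_anomalies$site_id)
  expect_false("S02" %in% d$interannual_anomalies$site_id)
  expect_true("S02" %in% d$across_site$site_id)
  expect_identical(d$excluded, "S02")
})

test_that("site-centered residual curves cancel constant offsets", {
  set.seed(4)
  sites <- data.frame(site_id = c("S01", "S02", "S03"),
                      latitude = c(45, -30, 50),
                      pft = c("deciduous", "deciduous", "evergreen"))
  tab <- fake_table(3, site_offsets = c(2, -1, 0.5))
  # per-site constant offsets vanish under site centering
  cur <- residual_seasonal_curve(tab, sites)
  expect_equal(max(abs(cur$resid_mean)), 0, tolerance = 1e-12)

  # exact agreement: flat zero
  tab0 <- fake_table(3)
  tab0$pred <- tab0$obs
  cur0 <- residual_seasonal_curve(tab0, sites)
  expect_equal(cur0$resid_mean, rep(0, 12), tolerance = 1e-12)

  # two-site hand computation, including the southern-hemisphere shift
  tab2 <- fake_table(2)
  tab2$pred <- tab2$obs + rep(c(0.3, -0.2), each = 48) *
    sin(2 * pi * tab2$month / 12)
  oracle <- local({
    r <- numeric(12)
    for (m in 1:12) {
      vals <- c()
      for (sid in c("S01", "S02")) {
        sub <- tab2[tab2$site_id == sid, ]
        res <- (sub$obs - mean(sub$obs)) - (sub$pred - mean(sub$pred))
        lat <- sites$latitude[sites$site_id == sid]
        mal <- if (lat < 0) (sub$month + 5) %% 12 + 1 else sub$month
        vals <- c(vals, res[mal == m])
      }
      r[m] <- mean(vals)
    }
    r
  })
  cur2 <- residual_seasonal_curve(tab2, sites)
  expect_equal(cur2$resid_mean, oracle, tolerance = 1e-12)
})

test_that("stratified reports degrade to NA, never to fabricated zeros", {
  set.seed(6)
  tab <- fake_table(4, years = 2001:2004)
  sites <- data.frame(site_id = sprintf("S%02d", 1:4), latitude = 45,
                      pft = c("deciduous", "deciduous", "evergreen",
                              "evergreen"),
                      climate_class = c("temperate", "temperate", "arid",
                                        "arid"),
                      age_class = "50-100")
  # arid sites have too few complete years for anomaly statistics
  tab <- tab[!(tab$site_id %in% c("S03", "S04") & tab$year %in% 2001:2002), ]
  mp <- cbind(tab$pred, tab$pred)  # degenerate two-member ensemble
  cv <- list(predictions = tab, member_preds = mp, setup = "LSTM")
  rep_ <- stratified_report(cv, sites, by = c("pft", "climate_class"))

  arid_ia <- rep_[rep_$stratum == "arid" &
                  rep_$scale == "interannual_anomalies" &
                  rep_$metric == "nse", ]
  expect_true(is.na(arid_ia$member_mean))
  temp_sc <- rep_[rep_$stratum == "temperate" &
                  rep_$scale == "seasonal_cycle" & rep_$metric == "nse", ]
  expect_false(is.na(temp_sc$member_mean))
  # identical members: sd over members is zero
  expect_equal(temp_sc$member_sd, 0)

  # a single-stratum report equals the unstratified numbers
  one <- stratified_report(cv, sites[sites$pft == "deciduous", ], by = "pft")
  all_row <- one[one$stratum_type == "all" & one$metric == "nse" &
                 one$scale == "seasonal_cycle", ]
  pft_row <- one[one$stratum_type == "pft" & one$metric == "nse" &
                 one$scale == "seasonal_cycle", ]
  expect_equal(all_row$member_mean, pft_row$member_mean, tolerance = 1e-12)
})
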