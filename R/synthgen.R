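#' @section Sign convention:
#' Throughout the package NEE follows the micrometeorological convention:
#' negative values are net CO2 uptake by the ecosystem, positive values net
#' release.
#' @name fluxmem-conventions
#' @rdname fluxmem-conventions
#' @keywords internal
NULL

BANDS <- c("blue", "green", "red", "nir", "swir1", "swir2", "tir")
CLIMVARS <- c("tair", "precip", "rg", "vpd")
PREDICTORS <- c(BANDS, CLIMVARS)

climate_class_of <- function(latitude) {
  a <- abs(latitude)
  ifelse(a < 23.5, "tropical", ifelse(a < 35, "arid",
         ifelse(a < 55, "temperate", "boreal")))
}

age_class_of <- function(age) {
  cut(age, breaks = c(-0.5, 10, 20, 50, 100, 150, Inf),
      labels = c("0-10", "10-20", "20-50", "50-100", "100-150", "150+"))
}

#' Generate site records
#'
#' Samples static site metadata: latitude (climate class follows
#' deterministically from the |latitude| band), plant functional type, stand
#' age, an optional disturbance event, and a 3--12 year NEE measurement
#' window placed inside `config$window_period`. All draws come from
#' per-site seed streams, so adding sites leaves existing ones unchanged.
#'
#' @param config an [generator_config()] object.
#' @return a data.frame with one row per site.
#' @export
generate_sites <- function(config) {
  validate_config(config)
  n <- config$n_sites
  cw <- config$climate_weights / sum(config$climate_weights)
  pw <- config$pft_weights / sum(config$pft_weights)
  bands_lat <- list(tropical = c(0, 23.5), arid = c(23.5, 35),
                    temperate = c(35, 55), boreal = c(55, 68))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- with_seed(derive_seed(config$master_seed, i, "site"), {
      cls <- sample(names(cw), 1, prob = cw)
      b <- bands_lat[[cls]]
      alat <- runif(1, b[1] + 1e-3, b[2] - 1e-3)
      lat <- alat * ifelse(runif(1) < config$hemisphere_north_prob, 1, -1)
      pft <- sample(names(pw), 1, prob = pw)
      age0 <- round(min(pmax(rlnorm(1, log(50), 0.9), 1), 300))
      has_dist <- runif(1) < config$disturbance_prob
      dist_year <- if (has_dist)
        sample(seq(config$period[1], config$period[2]), 1) else NA_integer_
      dist_month <- if (has_dist) sample(1:12, 1) else NA_integer_
      wy <- sample(seq(config$window_years[1], config$window_years[2]), 1)
      span_months <- (config$window_period[2] - config$window_period[1] + 1) * 12
      len <- wy * 12
      start_off <- sample(0:(span_months - len), 1)
      sy <- config$window_period[1] + start_off %/% 12
      sm <- start_off %% 12 + 1
      end_off <- start_off + len - 1
      ey <- config$window_period[1] + end_off %/% 12
      em <- end_off %% 12 + 1
      # stand age at window start; a disturbance inside the record resets it
      age_ws <- age0 + (sy - 1982)
      if (has_dist && dist_year < sy) age_ws <- sy - dist_year
      data.frame(site_id = sprintf("S%03d", i), site_index = i,
                 latitude = lat, pft = pft,
                 climate_class = climate_class_of(lat),
                 age_1982 = age0,
                 age_class = as.character(age_class_of(age_ws)),
                 disturbance_year = dist_year, disturbance_month = dist_month,
                 win_start_year = sy, win_start_month = sm,
                 win_end_year = ey, win_end_month = em,
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}

# daily-mean top-of-atmosphere radiation (W m-2) from latitude and month,
# evaluated at the mid-month day of year; standard solar-geometry closed form
rpot_toa <- function(latitude, month) {
  doy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)[month]
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  phi <- latitude * pi / 180
  e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
  x <- pmin(pmax(-tan(phi) * tan(decl), -1), 1)
  ws <- acos(x)
  pmax(1367 / pi * e0 *
         (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws)), 0)
}

# stationary AR(1) noise with sd `scale` and lag-1 coefficient `phi`
ar1_noise <- function(n, scale, phi = 0.5) {
  if (scale == 0) return(numeric(n))
  e <- rnorm(n, 0, scale * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

month_grid <- function(period) {
  years <- seq(period[1], period[2])
  data.frame(year = rep(years, each = 12), month = rep(1:12, length(years)))
}

# seasonal carrier: +1 at the warm-season peak (July in the north, January
# in the south), -1 half a year away
season_cos <- function(month, latitude) {
  peak <- ifelse(latitude >= 0, 7, 1)
  cos(2 * pi * (month - peak) / 12)
}

#' Simulate the climate block for one site
#'
#' Air temperature and global radiation follow sinusoidal seasonal cycles
#' with latitude-dependent mean and amplitude plus stationary AR(1) noise;
#' the seasonal phase south of the equator is offset by six months. VPD is a
#' monotone increasing function of air temperature plus noise; precipitation
#' is lognormal around a seasonal mean (hence positive); `rpot` is the
#' noise-free closed-form top-of-atmosphere radiation.
#'
#' @param site one row of [generate_sites()].
#' @param config the generator configuration.
#' @return data.frame `year, month, tair, precip, rg, vpd, rpot`.
#' @export
simulate_climate <- function(site, config) {
  g <- month_grid(config$period)
  n <- nrow(g)
  lat <- site$latitude
  alat <- abs(lat)
  s <- season_cos(g$month, lat)
  ns <- config$noise
  with_seed(derive_seed(config$master_seed, site$site_index, "climate"), {
    tmean <- 27 - 0.4 * alat
    tamp <- pmin(2 + 0.33 * alat, 22)
    tair <- tmean + tamp * s + ar1_noise(n, ns$tair)
    rgm <- 240 - 2.6 * alat
    rga <- pmin(2.4 * alat, 115)
    rg <- pmax(rgm + rga * s + ar1_noise(n, ns$rg), 1)
    vpd <- pmax(2.2 * exp(0.06 * tair) + ar1_noise(n, ns$vpd), 0)
    pm <- 80 * (1 + 0.3 * s)
    precip <- if (ns$precip_sdlog == 0) pm else
      pm * rlnorm(n, -ns$precip_sdlog^2 / 2, ns$precip_sdlog)
    data.frame(year = g$year, month = g$month, tair = tair, precip = precip,
               rg = rg, vpd = vpd, rpot = rpot_toa(lat, g$month))
  })
}

pft_green_pars <- function(pft) {
  switch(pft,
         deciduous = c(mean = 0.50, amp = 0.45),
         evergreen = c(mean = 0.62, amp = 0.12),
         mixed     = c(mean = 0.55, amp = 0.30),
         savanna   = c(mean = 0.40, amp = 0.33),
         stop("unknown pft: ", pft))
}

# affine band models: intercept + slope * greenness; NIR increases with
# greenness, red/SWIR decrease, blue weakly decreases, green weakly increases
BAND_AFFINE <- list(blue  = c(0.08, -0.05), green = c(0.08, 0.05),
                    red   = c(0.12, -0.08), nir   = c(0.15, 0.35),
                    swir1 = c(0.30, -0.18), swir2 = c(0.25, -0.16))

#' Simulate latent greenness and the reflectance block
#'
#' Greenness has a PFT-dependent seasonal amplitude (deciduous > mixed >
#' evergreen) plus a year-scale anomaly term (`noise$greenness_iav`)
#' emulating drought and high-productivity years. A disturbance removes
#' `disturbance_drop` of greenness in the event month and relaxes back
#' exponentially with time constant `recovery_tau` months. The six optical bands are affine in greenness plus
#' noise, clipped to [0, 1]; the thermal band tracks air temperature.
#'
#' @param site one site row; `climate` its simulated climate block.
#' @param climate data.frame from [simulate_climate()].
#' @param config generator configuration.
#' @return list with `greenness` (numeric) and `reflectance` (data.frame of
#'   the seven bands).
#' @export
simulate_vegetation <- function(site, climate, config) {
  n <- nrow(climate)
  ns <- config$noise
  pp <- pft_green_pars(site$pft)
  s <- season_cos(climate$month, site$latitude)
  with_seed(derive_seed(config$master_seed, site$site_index, "veg"), {
    g0 <- pp["mean"] + pp["amp"] * s + ar1_noise(n, ns$greenness)
    # year-scale anomalies (drought years / good years), mildly persistent
    yrs <- sort(unique(climate$year))
    iav <- ar1_noise(length(yrs), ns$greenness_iav, phi = 0.3)
    g0 <- g0 + iav[match(climate$year, yrs)]
    if (!is.na(site$disturbance_year)) {
      td <- which(climate$year == site$disturbance_year &
                  climate$month == site$disturbance_month)
      if (length(td) == 1) {
        dt <- seq_len(n) - td
        deficit <- ifelse(dt >= 0,
                          config$disturbance_drop * exp(-dt / config$recovery_tau), 0)
        g0 <- g0 * (1 - deficit)
      }
    }
    g <- pmin(pmax(g0, 0.02), 0.98)
    refl <- lapply(names(BAND_AFFINE), function(b) {
      ab <- BAND_AFFINE[[b]]
      pmin(pmax(ab[1] + ab[2] * g + rnorm(n, 0, ns$reflectance), 0), 1)
    })
    names(refl) <- names(BAND_AFFINE)
    refl$tir <- climate$tair + 273.15 + rnorm(n, 0, ns$tir)
    list(greenness = g, reflectance = as.data.frame(refl))
  })
}

#' Simulate NEE through a lagged carbon pool
#'
#' GPP is light-use-efficiency times radiation times greenness, modulated by
#' smooth temperature and dryness scalars in [0, 1]. A single carbon pool
#' `C_t = (1 - lambda) C_{t-1} + gamma GPP_{t-1}` feeds respiration
#' `Reco_t = resp_base exp(resp_temp_sens T_t) C_t`, so respiration carries
#' a memory of past productivity with half-life
#' `log(2) / -log(1 - lambda)` months. `NEE = Reco - GPP + noise`; negative
#' NEE is net uptake.
#'
#' @inheritParams simulate_vegetation
#' @param greenness latent greenness from [simulate_vegetation()].
#' @return data.frame `gpp, cpool, reco, nee`.
#' @export
simulate_nee <- function(site, climate, greenness, config) {
  if (config$lambda == 0 && !config$allow_infinite_memory)
    stop_config("lambda", "0 implies an infinite-memory pool")
  n <- nrow(climate)
  f_t <- plogis((climate$tair - 8) / 6)
  f_w <- plogis(-(climate$vpd - 18) / 6)
  gpp <- config$epsilon * climate$rg * greenness * f_t * f_w
  cpool <- numeric(n)
  cprev <- config$c0
  for (t in seq_len(n)) {
    gprev <- if (t == 1) 0 else gpp[t - 1]
    cpool[t] <- (1 - config$lambda) * cprev + config$gamma * gprev
    cprev <- cpool[t]
  }
  reco <- config$resp_base * exp(config$resp_temp_sens * climate$tair) * cpool
  eps <- with_seed(derive_seed(config$master_seed, site$site_index, "nee"),
                   rnorm(n, 0, config$noise$nee))
  data.frame(gpp = gpp, cpool = cpool, reco = reco, nee = reco - gpp + eps)
}

#' Apply the observation model
#'
#' Draws a monthly NEE quality fraction from Beta(`qc_alpha`, `qc_beta`),
#' restricts NEE to the site's measurement window, and knocks out
#' reflectance observations at random (per band, per month) at the
#' configured cloud-gap rate, inflated by `tropical_gap_factor` for tropical
#' sites. Withheld reflectance values remain available in the ground truth.
#'
#' @param panel complete latent panel (climate + reflectance + nee columns).
#' @param site the site row; `config` the generator configuration.
#' @param config generator configuration.
#' @return the observed panel: masked values are `NA`, with logical
#'   `obs_<band>` columns and `nee_quality`.
#' @export
apply_observation_model <- function(panel, site, config) {
  n <- nrow(panel)
  rate <- config$gap_rate_reflectance *
    ifelse(site$climate_class == "tropical", config$tropical_gap_factor, 1)
  rate <- min(rate, 1)
  with_seed(derive_seed(config$master_seed, site$site_index, "obs"), {
    q <- rbeta(n, config$qc_alpha, config$qc_beta)
    ym <- panel$year * 12 + panel$month
    w0 <- site$win_start_year * 12 + site$win_start_month
    w1 <- site$win_end_year * 12 + site$win_end_month
    inwin <- ym >= w0 & ym <= w1
    panel$nee[!inwin] <- NA_real_
    panel$nee_quality <- ifelse(inwin, q, NA_real_)
    for (b in BANDS) {
      miss <- runif(n) < rate
      panel[[paste0("obs_", b)]] <- !miss
      panel[[b]][miss] <- NA_real_
    }
    panel
  })
}

#' Generate a complete multi-site dataset
#'
#' Composes site generation, climate, vegetation, NEE and the observation
#' model; fully reproducible from `config$master_seed`.
#'
#' @param config an [generator_config()] object.
#' @return a list of class `fm_dataset` with elements `sites`, `panels`
#'   (one long data.frame over all sites), `truth` (latent greenness,
#'   GPP/Reco/C-pool and pre-withholding band values), `aux` (auxiliary
#'   reflectance table covering `aux_start_year` onward, for stage-1
#'   gap-filling), and `config`.
#' @export
generate_dataset <- function(config) {
  sites <- generate_sites(config)
  panels <- vector("list", nrow(sites)); truths <- panels; auxs <- panels
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    clim <- simulate_climate(site, config)
    veg <- simulate_vegetation(site, clim, config)
    flux <- simulate_nee(site, clim, veg$greenness, config)
    latent <- cbind(site_id = site$site_id, clim, veg$reflectance,
                    nee = flux$nee)
    truths[[i]] <- data.frame(site_id = site$site_id, year = clim$year,
                              month = clim$month, greenness = veg$greenness,
                              gpp = flux$gpp, reco = flux$reco,
                              cpool = flux$cpool,
                              setNames(veg$reflectance,
                                       paste0(names(veg$reflectance), "_true")))
    panels[[i]] <- apply_observation_model(latent, site, config)
    aux_rows <- clim$year >= config$aux_start_year
    aux <- with_seed(derive_seed(config$master_seed, site$site_index, "aux"), {
      a <- lapply(BANDS, function(b)
        0.9 * veg$reflectance[[b]][aux_rows] +
          0.02 + rnorm(sum(aux_rows), 0, config$noise$aux))
      names(a) <- paste0("aux_", BANDS)
      data.frame(site_id = site$site_id, year = clim$year[aux_rows],
                 month = clim$month[aux_rows], as.data.frame(a))
    })
    auxs[[i]] <- aux
  }
  structure(list(sites = sites, panels = do.call(rbind, panels),
                 truth = do.call(rbind, truths), aux = do.call(rbind, auxs),
                 config = config),
            class = "fm_dataset")
}

#' Write / read a dataset directory
#'
#' Serializes a dataset to plain CSV: `sites.csv`, one `panel_<site>.csv`
#' per site (missing values as empty fields), `ground_truth.csv` and
#' `aux.csv`. `read_dataset()` inverts the layout.
#'
#' @param dataset an `fm_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; `read_dataset()` returns the dataset list
#'   (without the original config).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- dataset$sites
  sites_out <- data.frame(site_id = s$site_id, latitude = s$latitude,
                          pft = s$pft, climate_class = s$climate_class,
                          age_class = s$age_class,
                          disturbance_year = s$disturbance_year,
                          window_start = sprintf("%04d-%02d", s$win_start_year,
                                                 s$win_start_month),
                          window_end = sprintf("%04d-%02d", s$win_end_year,
                                               s$win_end_month),
                          age_1982 = s$age_1982,
                          disturbance_month = s$disturbance_month,
                          site_index = s$site_index)
  write.csv(sites_out, file.path(dir, "sites.csv"), row.names = FALSE, na = "")
  for (sid in unique(dataset$panels$site_id)) {
    p <- dataset$panels[dataset$panels$site_id == sid, ]
    write.csv(p[, setdiff(names(p), "site_id")],
              file.path(dir, paste0("panel_", sid, ".csv")),
              row.names = FALSE, na = "")
  }
  write.csv(dataset$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE, na = "")
  write.csv(dataset$aux, file.path(dir, "aux.csv"), row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  so <- read.csv(file.path(dir, "sites.csv"), stringsAsFactors = FALSE)
  ws <- strsplit(so$window_start, "-"); we <- strsplit(so$window_end, "-")
  sites <- data.frame(site_id = so$site_id, site_index = so$site_index,
                      latitude = so$latitude, pft = so$pft,
                      climate_class = so$climate_class,
                      age_1982 = so$age_1982, age_class = so$age_class,
                      disturbance_year = so$disturbance_year,
                      disturbance_month = so$disturbance_month,
                      win_start_year = as.integer(sapply(ws, `[`, 1)),
                      win_start_month = as.integer(sapply(ws, `[`, 2)),
                      win_end_year = as.integer(sapply(we, `[`, 1)),
                      win_end_month = as.integer(sapply(we, `[`, 2)),
                      stringsAsFactors = FALSE)
  panels <- do.call(rbind, lapply(sites$site_id, function(sid) {
    p <- read.csv(file.path(dir, paste0("panel_", sid, ".csv")))
    cbind(site_id = sid, p)
  }))
  truth_path <- file.path(dir, "ground_truth.csv")
  aux_path <- file.path(dir, "aux.csv")
  structure(list(sites = sites, panels = panels,
                 truth = if (file.exists(truth_path)) read.csv(truth_path) else NULL,
                 aux = if (file.exists(aux_path)) read.csv(aux_path) else NULL,
                 config = NULL),
            class = "fm_dataset")
}
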