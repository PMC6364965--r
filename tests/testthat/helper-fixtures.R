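# Shared fixtures: everything is generated in code at test time.

# a small, fast configuration: 8 sites, 7-year panels, no reflectance gaps
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_sites = 8L, period = c(2000L, 2006L),
         window_period = c(2001L, 2006L), window_years = c(3L, 5L),
         gap_rate_reflectance = 0, master_seed = seed),
    list(...))
  do.call(generator_config, args)
}

# a hand-rolled site row for driving the simulators directly
manual_site <- function(latitude = 45, pft = "deciduous", site_index = 1,
                        disturbance_year = NA_integer_,
                        disturbance_month = NA_integer_) {
  data.frame(site_id = "TST", site_index = site_index, latitude = latitude,
             pft = pft, climate_class = fluxmem:::climate_class_of(latitude),
             age_1982 = 50, age_class = "50-100",
             disturbance_year = disturbance_year,
             disturbance_month = disturbance_month,
             win_start_year = 2001L, win_start_month = 1L,
             win_end_year = 2005L, win_end_month = 12L,
             stringsAsFactors = FALSE)
}

zero_noise <- function() list(tair = 0, rg = 0, vpd = 0, precip_sdlog = 0,
                              greenness = 0, greenness_iav = 0,
                              reflectance = 0, tir = 0, nee = 0, aux = 0)

# samples + standardized samples from a tiny dataset, cached per seed
tiny_samples <- local({
  cache <- list()
  function(seed = 1, ...) {
    key <- paste(seed, ...)
    if (is.null(cache[[key]])) {
      ds <- generate_dataset(tiny_config(seed, ...))
      p <- qc_filter(ds$panels)
      cache[[key]] <<- list(dataset = ds, samples = build_samples(p, ds$sites))
    }
    cache[[key]]
  }
})

# deterministic tiny LSTM weights for oracle comparisons
fixed_tiny_weights <- function(D = 2, H = 2) {
  list(Wx = matrix(seq(-0.4, 0.4, length.out = D * 4 * H), D, 4 * H),
       Wh = matrix(seq(0.3, -0.3, length.out = H * 4 * H), H, 4 * H),
       b = seq(-0.2, 0.2, length.out = 4 * H),
       Wy = c(0.5, -0.25)[seq_len(H)],
       by = 0.1)
}
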