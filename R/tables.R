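#' Packaged river-characteristics table for the 19 focal hatcheries
#'
#' Transcription of the published per-river habitat summary: watershed area
#' (km^2), isolation (km of water distance to the nearest potential stray
#' source; 1 km denotes intersecting rivers), migration distance from the
#' Columbia mouth (km), mean and sd of August flow (m^3 s^-1), August local
#' and confluence water temperatures (degrees C), and expanded adult
#' escapement. Static columns are constants of the river; mean/sd pairs
#' summarize the annual series.
#'
#' @return data.frame with one row per focal hatchery programme.
#' @export
chinook_rivers <- function() {
  read.csv(system.file("extdata", "columbia_chinook_rivers.csv",
                       package = "cwtstray"), stringsAsFactors = FALSE)
}

#' Packaged tag-recovery and stray-rate summary table
#'
#' Transcription of the published per-hatchery summary of expanded tag
#' recoveries for return years 1993-2016: pooled home/stray/ambiguous
#' counts and totals for the donor and recipient sides, with the mean and
#' sd of the annual stray-rate percentages. Note the published grand-totals
#' row is reproducible by summing these rows only to within one fish on the
#' donor side (the source table's own rounding).
#'
#' @return data.frame with one row per focal hatchery programme.
#' @export
chinook_recoveries <- function() {
  read.csv(system.file("extdata", "columbia_chinook_recoveries.csv",
                       package = "cwtstray"), stringsAsFactors = FALSE)
}

#' Yearly covariate table expanded from the packaged river summary
#'
#' The packaged river table stores static covariates and annual mean/sd
#' summaries. For model fitting a per-hatchery-year table is needed; this
#' helper replicates static values across years and, for annual covariates,
#' draws yearly values from normal distributions with the tabulated mean
#' and sd (a synthetic reconstruction: the true yearly series are not part
#' of the package).
#'
#' @param years integer vector of return years.
#' @param seed RNG seed for the synthetic yearly draws.
#' @return data.frame suitable for [build_design()].
#' @export
chinook_covariates_yearly <- function(years = 1993:2015, seed = 1) {
  t1 <- chinook_rivers()
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(t1)), function(i) {
    r <- t1[i, ]
    ny <- length(years)
    data.frame(
      hatchery = r$hatchery, year = years,
      area = r$area_km2, isolation = r$isolation_km, distance = r$distance_km,
      flow = pmax(rnorm(ny, r$flow_mean, r$flow_sd), 0.1),
      local_temp = rnorm(ny, r$local_temp_mean, r$local_temp_sd),
      confluence_temp = rnorm(ny, r$confluence_temp_mean, r$confluence_temp_sd),
      escapement = pmax(rnorm(ny, r$escapement_mean, r$escapement_sd), 1),
      stringsAsFactors = FALSE)
  }))
  out$diff_temp <- diff_temperature(out$local_temp, out$confluence_temp)
  rownames(out) <- NULL
  out
}
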