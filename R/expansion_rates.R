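#' Two-step expansion of a tag recovery to an absolute number of fish
#'
#' Each tag read stands for more fish than itself, for two reasons: only a
#' fraction of the carcasses or rack returns at a site were examined for
#' tags, and only a fraction of the release group was tagged at all. The
#' expansion factor is the product of the two corrections,
#' `(1/sampling_fraction) * ((tagged + untagged)/tagged)`, and each recovery
#' record (one tag read) represents `expansion_factor` fish.
#'
#' @param classified data.frame from [classify_recoveries()].
#' @return the input with numeric columns `expansion_factor` and
#'   `expanded_fish` appended. Expanded counts are kept as reals; rounding,
#'   if any, happens only in final reports.
#' @export
expand_recoveries <- function(classified) {
  sf <- classified$sampling_fraction
  if (any(is.na(sf) | sf <= 0 | sf > 1))
    stop("sampling_fraction must lie in (0, 1]", call. = FALSE)
  tc <- classified$tagged_count
  uc <- classified$untagged_count
  if (any(is.na(tc) | tc < 1)) stop("tagged_count must be >= 1", call. = FALSE)
  classified$expansion_factor <- (1 / sf) * ((tc + uc) / tc)
  classified$expanded_fish <- classified$expansion_factor
  classified
}

#' @rdname expand_recoveries
#' @param sampling_fraction fraction of the sample examined for tags, in (0,1].
#' @param tagged_count,untagged_count release-group tag composition.
#' @return `expansion_factor()`: the scalar multiplier.
#' @export
expansion_factor <- function(sampling_fraction, tagged_count, untagged_count) {
  if (any(sampling_fraction <= 0 | sampling_fraction > 1))
    stop("sampling_fraction must lie in (0, 1]", call. = FALSE)
  if (any(tagged_count < 1)) stop("tagged_count must be >= 1", call. = FALSE)
  (1 / sampling_fraction) * ((tagged_count + untagged_count) / tagged_count)
}

sum_by <- function(values, f1, f2) {
  tapply(values, list(f1, f2), sum, default = 0)
}

#' Donor and recipient stray rates per hatchery programme and return year
#'
#' The donor rate of a programme in a year is the expanded number of its
#' fish that strayed divided by the expanded number that homed or strayed,
#' over recoveries at all locations. The recipient rate of a hatchery in a
#' year is the expanded number of strays recovered there divided by the sum
#' of local fish and strays; strays may originate from any programme, not
#' only the focal ones. Ambiguous recoveries enter neither numerator nor
#' denominator. A year with an empty denominator yields `NA` (missing), not
#' zero: an absence of recoveries is not an observation of no straying. A
#' year in which every recovery is a stray would give a rate of exactly 1;
#' such years are set to `NA` with a warning, since the model's support is
#' [0, 1).
#'
#' @param expanded data.frame from [expand_recoveries()].
#' @param rivers a [river_map()] whose `focal` table lists the hatchery
#'   programmes to tabulate.
#' @param scope how recipient recoveries are attributed: `"hatchery"`
#'   (recoveries at the focal hatchery site itself; distinguishes two
#'   programmes on one river) or `"river"` (all recoveries in the focal
#'   hatchery's river).
#' @return data.frame with one row per (hatchery, year): expanded counts
#'   `donor_home`, `donor_stray`, `donor_ambiguous`, `recipient_local`,
#'   `recipient_stray`, `recipient_ambiguous`, and rates `donor_rate`,
#'   `recipient_rate` in [0, 1) or NA.
#' @export
rate_table <- function(expanded, rivers, scope = c("hatchery", "river")) {
  scope <- match.arg(scope)
  stopifnot(inherits(rivers, "river_map"))
  focal <- rivers$focal
  if (nrow(focal) == 0) stop("river map declares no focal hatcheries", call. = FALSE)
  use <- expanded[expanded$label != "excluded", , drop = FALSE]
  years <- sort(unique(use$return_year))
  if (length(years) == 0) {
    warning("no usable recoveries; rate table is empty")
    return(data.frame(hatchery = character(0), year = integer(0),
                      donor_home = numeric(0), donor_stray = numeric(0),
                      donor_ambiguous = numeric(0), recipient_local = numeric(0),
                      recipient_stray = numeric(0), recipient_ambiguous = numeric(0),
                      donor_rate = numeric(0), recipient_rate = numeric(0)))
  }
  grid <- expand.grid(hatchery = focal$hatchery, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$hatchery, focal$hatchery), grid$year), ]
  rownames(grid) <- NULL
  key <- paste(canon_name(grid$hatchery), grid$year)

  # donor side: group by release site over all recovery locations
  rel_site <- canon_name(use$release_site)
  dkey <- paste(rel_site, use$return_year)
  pick <- function(rows, keys) {
    v <- tapply(use$expanded_fish[rows], keys[rows], sum)
    out <- as.vector(v[key]); out[is.na(out)] <- 0; out
  }
  grid$donor_home <- pick(use$label == "home", dkey)
  grid$donor_stray <- pick(use$label == "stray", dkey)
  grid$donor_ambiguous <- pick(use$label == "ambiguous", dkey)

  # recipient side: group by where the fish was recovered
  if (scope == "hatchery") {
    rkey <- paste(canon_name(use$recovery_site), use$return_year)
  } else {
    focal_river <- setNames(canon_name(focal$river), canon_name(focal$hatchery))
    rkey <- paste(use$recovery_river, use$return_year)
    key_r <- paste(focal_river[canon_name(grid$hatchery)], grid$year)
  }
  pick_r <- function(rows, keys) {
    v <- tapply(use$expanded_fish[rows], keys[rows], sum)
    out <- as.vector(v[if (scope == "hatchery") key else key_r])
    out[is.na(out)] <- 0
    out
  }
  grid$recipient_local <- pick_r(use$label == "home", rkey)
  grid$recipient_stray <- pick_r(use$label == "stray", rkey)
  grid$recipient_ambiguous <- pick_r(use$label == "ambiguous", rkey)

  grid$donor_rate <- safe_rate(grid$donor_stray, grid$donor_home, "donor")
  grid$recipient_rate <- safe_rate(grid$recipient_stray, grid$recipient_local,
                                   "recipient")
  # drop all-empty hatchery-years (no recoveries on either side)
  keep <- grid$donor_home + grid$donor_stray + grid$donor_ambiguous +
    grid$recipient_local + grid$recipient_stray + grid$recipient_ambiguous > 0
  grid <- grid[keep, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

safe_rate <- function(stray, home, what) {
  denom <- home + stray
  rate <- ifelse(denom > 0, stray / denom, NA_real_)
  all_stray <- !is.na(rate) & rate == 1 & stray > 0
  if (any(all_stray)) {
    warning(sprintf(
      "%d %s hatchery-year(s) had strays but no home/local fish (rate would be 1); set to NA",
      sum(all_stray), what))
    rate[all_stray] <- NA_real_
  }
  rate
}

#' Donor or recipient rate for one hatchery-year
#'
#' Convenience accessors over [rate_table()].
#'
#' @param hatchery,year the programme and return year.
#' @param rates a data.frame from [rate_table()].
#' @return a single rate in [0,1), or NA if the year is missing.
#' @export
donor_rate <- function(hatchery, year, rates) {
  row <- rates[canon_name(rates$hatchery) == canon_name(hatchery) &
                 rates$year == year, ]
  if (nrow(row) == 0) return(NA_real_)
  row$donor_rate[1]
}

#' @rdname donor_rate
#' @export
recipient_rate <- function(hatchery, year, rates) {
  row <- rates[canon_name(rates$hatchery) == canon_name(hatchery) &
                 rates$year == year, ]
  if (nrow(row) == 0) return(NA_real_)
  row$recipient_rate[1]
}

#' Per-hatchery summary of recoveries and annual stray rates
#'
#' Pools expanded home/stray/ambiguous counts across years and reports the
#' mean and standard deviation of the *annual* rates. The average is
#' deliberately not the pooled stray total divided by the pooled recovery
#' total: a year with ten fish counts as much as a year with ten thousand.
#' A grand-totals row sums the counts across hatcheries.
#'
#' @param rates data.frame from [rate_table()].
#' @param digits counts in the returned table are rounded half-to-even to
#'   this many digits (default 0); rates are percentages.
#' @return data.frame mirroring the published summary layout, one row per
#'   hatchery plus a `GRAND TOTALS` row.
#' @export
summarize_rates <- function(rates, digits = 0) {
  hs <- unique(rates$hatchery)
  one <- function(h) {
    r <- rates[rates$hatchery == h, ]
    data.frame(
      hatchery = h,
      donor_home = sum(r$donor_home), donor_stray = sum(r$donor_stray),
      donor_ambiguous = sum(r$donor_ambiguous),
      donor_total = sum(r$donor_home + r$donor_stray + r$donor_ambiguous),
      donor_pct_mean = 100 * mean(r$donor_rate, na.rm = TRUE),
      donor_pct_sd = 100 * sd(r$donor_rate, na.rm = TRUE),
      recipient_home = sum(r$recipient_local), recipient_stray = sum(r$recipient_stray),
      recipient_ambiguous = sum(r$recipient_ambiguous),
      recipient_total = sum(r$recipient_local + r$recipient_stray + r$recipient_ambiguous),
      recipient_pct_mean = 100 * mean(r$recipient_rate, na.rm = TRUE),
      recipient_pct_sd = 100 * sd(r$recipient_rate, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(hs, one))
  totals <- out[1, ]
  totals$hatchery <- "GRAND TOTALS"
  count_cols <- c("donor_home", "donor_stray", "donor_ambiguous", "donor_total",
                  "recipient_home", "recipient_stray", "recipient_ambiguous",
                  "recipient_total")
  totals[count_cols] <- lapply(out[count_cols], sum)
  totals[c("donor_pct_mean", "donor_pct_sd",
           "recipient_pct_mean", "recipient_pct_sd")] <- NA_real_
  out <- rbind(out, totals)
  out[count_cols] <- lapply(out[count_cols], round, digits = digits)
  rownames(out) <- NULL
  out
}
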