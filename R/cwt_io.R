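#' Column dialect for CWT release/recovery tables
#'
#' Release and recovery extracts come with site-specific column headers and
#' boolean encodings. A dialect maps the columns this package needs onto the
#' file's actual headers and declares how logical flags are written.
#'
#' @param releases named character vector mapping canonical release fields
#'   (`tag_code`, `release_river`, `release_site`, `rearing_rivers`,
#'   `brood_year`, `tagged_count`, `untagged_count`, `experimental`) to
#'   column names in the file.
#' @param recoveries named character vector mapping canonical recovery fields
#'   (`tag_code`, `recovery_site`, `return_year`, `sampling_fraction`,
#'   `recovery_context`) to column names.
#' @param true_values,false_values character vectors of accepted encodings of
#'   logical TRUE/FALSE (case-insensitive).
#' @param sep field separator.
#' @param rearing_sep separator inside the multi-valued rearing-rivers field.
#' @return A list of class `cwt_dialect`.
#' @export
cwt_dialect <- function(releases = NULL, recoveries = NULL,
                        true_values = c("TRUE", "T", "Y", "YES", "1"),
                        false_values = c("FALSE", "F", "N", "NO", "0", ""),
                        sep = ",", rearing_sep = ";") {
  rel_default <- c(tag_code = "tag_code", release_river = "release_river",
                   release_site = "release_site", rearing_rivers = "rearing_rivers",
                   brood_year = "brood_year", tagged_count = "tagged_count",
                   untagged_count = "untagged_count", experimental = "experimental")
  rec_default <- c(tag_code = "tag_code", recovery_site = "recovery_site",
                   return_year = "return_year", sampling_fraction = "sampling_fraction",
                   recovery_context = "recovery_context")
  rel <- rel_default
  if (!is.null(releases)) rel[names(releases)] <- releases
  rec <- rec_default
  if (!is.null(recoveries)) rec[names(recoveries)] <- recoveries
  structure(list(releases = rel, recoveries = rec,
                 true_values = toupper(true_values),
                 false_values = toupper(false_values),
                 sep = sep, rearing_sep = rearing_sep),
            class = "cwt_dialect")
}

parse_logical <- function(x, dialect, field) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% dialect$true_values] <- TRUE
  out[up %in% dialect$false_values] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("cannot parse '%s' as logical in field '%s' (row %d)",
                 x[bad], field, bad), call. = FALSE)
  }
  out
}

read_delim_checked <- function(path, dialect, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- tryCatch(
    read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
             check.names = FALSE, strip.white = TRUE),
    error = function(e) stop(sprintf("malformed %s file '%s': %s",
                                     what, path, conditionMessage(e)), call. = FALSE))
  missing <- setdiff(unname(required), names(df))
  if (length(missing) > 0)
    stop(sprintf("%s file '%s' is missing column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Read a table of tag-group releases
#'
#' One row per coded-wire-tag release group: where the group was reared,
#' where it was released, and how many fish were tagged and untagged.
#'
#' @param path delimited text file with a header row.
#' @param dialect a [cwt_dialect()].
#' @return data.frame with columns `tag_code`, `release_river`,
#'   `release_site`, `rearing_rivers` (separator-joined, possibly empty),
#'   `brood_year`, `tagged_count`, `untagged_count`, `experimental`.
#' @export
read_releases <- function(path, dialect = cwt_dialect()) {
  cols <- dialect$releases
  df <- read_delim_checked(path, dialect, cols, "releases")
  out <- data.frame(
    tag_code = as.character(df[[cols["tag_code"]]]),
    release_river = as.character(df[[cols["release_river"]]]),
    release_site = as.character(df[[cols["release_site"]]]),
    rearing_rivers = as.character(df[[cols["rearing_rivers"]]]),
    brood_year = as.integer(df[[cols["brood_year"]]]),
    tagged_count = suppressWarnings(as.numeric(df[[cols["tagged_count"]]])),
    untagged_count = suppressWarnings(as.numeric(df[[cols["untagged_count"]]])),
    stringsAsFactors = FALSE)
  out$experimental <- parse_logical(df[[cols["experimental"]]], dialect, "experimental")
  bad <- which(is.na(out$tagged_count) | out$tagged_count < 1)
  if (length(bad) > 0)
    stop(sprintf("releases '%s': tagged_count missing or < 1 at row(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  bad <- which(is.na(out$untagged_count) | out$untagged_count < 0)
  if (length(bad) > 0)
    stop(sprintf("releases '%s': untagged_count missing or negative at row(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  if (any(!nzchar(trimws(out$release_river))))
    stop(sprintf("releases '%s': empty release_river", path), call. = FALSE)
  dup <- out$tag_code[duplicated(out$tag_code)]
  if (length(dup) > 0)
    stop(sprintf("releases '%s': duplicate tag_code(s): %s",
                 path, paste(unique(dup), collapse = ", ")), call. = FALSE)
  attr(out, "rearing_sep") <- dialect$rearing_sep
  out
}

#' Read a table of tag recoveries
#'
#' One row per tag read: the site of recovery, the sampling fraction of the
#' sample the fish came from, and the recovery context (hatchery rack,
#' spawning-ground survey, or fishery).
#'
#' @inheritParams read_releases
#' @return data.frame with columns `tag_code`, `recovery_site`,
#'   `return_year`, `sampling_fraction`, `recovery_context`.
#' @export
read_recoveries <- function(path, dialect = cwt_dialect()) {
  cols <- dialect$recoveries
  df <- read_delim_checked(path, dialect, cols, "recoveries")
  out <- data.frame(
    tag_code = as.character(df[[cols["tag_code"]]]),
    recovery_site = as.character(df[[cols["recovery_site"]]]),
    return_year = as.integer(df[[cols["return_year"]]]),
    sampling_fraction = suppressWarnings(as.numeric(df[[cols["sampling_fraction"]]])),
    recovery_context = canon_name(df[[cols["recovery_context"]]]),
    stringsAsFactors = FALSE)
  bad <- which(is.na(out$sampling_fraction) | out$sampling_fraction <= 0 |
                 out$sampling_fraction > 1)
  if (length(bad) > 0)
    stop(sprintf("recoveries '%s': sampling_fraction outside (0,1] at row(s) %s",
                 path, paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  ok_ctx <- c("hatchery", "spawning_ground", "fishery")
  if (!all(out$recovery_context %in% ok_ctx))
    stop(sprintf("recoveries '%s': recovery_context must be one of %s",
                 path, paste(ok_ctx, collapse = "/")), call. = FALSE)
  out
}

#' Build or read the site-to-river map
#'
#' Maps every sampling site (hatcheries, spawning grounds, aliases) to the
#' river (sub-basin) it sits on, and flags the focal hatchery programmes whose
#' donor and recipient rates are being estimated. The sentinel sites/rivers
#' `OCEAN` and `MAINSTEM_EN_ROUTE` are always present: fish recovered there
#' had no opportunity to home or stray.
#'
#' @param sites data.frame with columns `site`, `river` and optionally
#'   `focal` (logical; TRUE marks a focal hatchery site).
#' @return list of class `river_map` with canonicalized lookup tables.
#' @export
river_map <- function(sites) {
  stopifnot(is.data.frame(sites), all(c("site", "river") %in% names(sites)))
  site <- canon_name(sites$site)
  river <- as.character(sites$river)
  river[!river %in% .sentinel_rivers] <- canon_name(river[!river %in% .sentinel_rivers])
  if (anyDuplicated(site)) {
    d <- unique(site[duplicated(site)])
    conf <- vapply(d, function(s) length(unique(river[site == s])) > 1, logical(1))
    if (any(conf))
      stop(sprintf("site(s) mapped to more than one river: %s",
                   paste(d[conf], collapse = ", ")), call. = FALSE)
    keep <- !duplicated(site)
    site <- site[keep]; river <- river[keep]
    sites <- sites[keep, , drop = FALSE]
  }
  lookup <- setNames(river, site)
  lookup[canon_name("OCEAN")] <- "OCEAN"
  lookup[canon_name("MAINSTEM_EN_ROUTE")] <- "MAINSTEM_EN_ROUTE"
  focal <- if ("focal" %in% names(sites)) {
    data.frame(hatchery = as.character(sites$site)[isTRUE_vec(sites$focal)],
               river = river[isTRUE_vec(sites$focal)],
               stringsAsFactors = FALSE)
  } else data.frame(hatchery = character(0), river = character(0))
  if (anyDuplicated(canon_name(focal$hatchery)))
    stop("a focal hatchery appears more than once in the river map", call. = FALSE)
  structure(list(site_to_river = lookup, focal = focal), class = "river_map")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @rdname river_map
#' @param path CSV with columns `site,river[,focal]`.
#' @param dialect a [cwt_dialect()] (used for the separator and logical encoding).
#' @export
read_river_map <- function(path, dialect = cwt_dialect()) {
  df <- read_delim_checked(path, dialect, c("site", "river"), "river map")
  if ("focal" %in% names(df)) df$focal <- parse_logical(df$focal, dialect, "focal")
  river_map(df)
}

site_river <- function(sites, rivers) {
  key <- canon_name(sites)
  hit <- rivers$site_to_river[key]
  if (anyNA(hit)) {
    missing <- unique(sites[is.na(hit)])
    stop(sprintf("recovery site(s) not in river map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unname(hit)
}

#' Classify joined recoveries as home, stray, ambiguous or excluded
#'
#' Applies the operational definitions at the river (sub-basin) scale:
#' a fish recovered in its river of release has homed (even at a different
#' hatchery in the same river); a fish recovered in a river it experienced
#' during incubation or rearing but was not released in is ambiguous; a fish
#' recovered in any other river has strayed. Recoveries in the ocean or in
#' the mainstem en route, fishery recoveries, and fish from release groups
#' flagged experimental are excluded: they carry no homing information.
#'
#' @param recoveries data.frame from [read_recoveries()].
#' @param releases data.frame from [read_releases()].
#' @param rivers a [river_map()].
#' @param rearing_sep separator of the multi-valued rearing field.
#' @return data.frame of recoveries joined to their releases with columns
#'   `recovery_river`, `label` (home/stray/ambiguous/excluded) and
#'   `exclusion_reason` (NA unless excluded). Recoveries with no matching
#'   release are dropped with a message.
#' @export
classify_recoveries <- function(recoveries, releases, rivers,
                                rearing_sep = attr(releases, "rearing_sep") %||% ";") {
  stopifnot(inherits(rivers, "river_map"))
  idx <- match(recoveries$tag_code, releases$tag_code)
  if (anyNA(idx)) {
    n_drop <- sum(is.na(idx))
    message(sprintf("dropping %d recover%s with no matching release tag code",
                    n_drop, if (n_drop == 1) "y" else "ies"))
    recoveries <- recoveries[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  rel <- releases[idx, , drop = FALSE]
  out <- cbind(recoveries,
               rel[c("release_river", "release_site", "rearing_rivers",
                     "brood_year", "tagged_count", "untagged_count",
                     "experimental")])
  rownames(out) <- NULL
  n <- nrow(out)
  if (n == 0) {
    out$recovery_river <- character(0)
    out$label <- character(0)
    out$exclusion_reason <- character(0)
    return(out)
  }
  out$recovery_river <- site_river(out$recovery_site, rivers)

  rel_river <- canon_name(out$release_river)
  reared <- strsplit(out$rearing_rivers, rearing_sep, fixed = TRUE)
  reared <- lapply(reared, function(x) canon_name(x[nzchar(trimws(x))]))

  label <- character(n)
  reason <- rep(NA_character_, n)
  excl_exp <- out$experimental
  excl_area <- out$recovery_river %in% .sentinel_rivers
  excl_fish <- out$recovery_context == "fishery"
  is_excl <- excl_exp | excl_area | excl_fish
  reason[is_excl] <- ifelse(excl_exp[is_excl], "experimental_release",
                     ifelse(excl_area[is_excl], "no_opportunity_to_home",
                            "fishery_recovery"))
  is_home <- !is_excl & out$recovery_river == rel_river
  is_amb <- !is_excl & !is_home &
    mapply(function(rv, rr) rv %in% rr, out$recovery_river, reared)
  label[is_excl] <- "excluded"
  label[is_home] <- "home"
  label[is_amb] <- "ambiguous"
  label[!is_excl & !is_home & !is_amb] <- "stray"
  out$label <- label
  out$exclusion_reason <- reason
  out
}

#' @rdname classify_recoveries
#' @param recovery,release single-row data.frames (or lists) for one
#'   recovery and its matching release; `tag_code` must agree.
#' @export
classify_recovery <- function(recovery, release, rivers) {
  recovery <- as.data.frame(recovery, stringsAsFactors = FALSE)
  release <- as.data.frame(release, stringsAsFactors = FALSE)
  if (!identical(as.character(recovery$tag_code), as.character(release$tag_code)))
    stop("recovery and release tag codes differ", call. = FALSE)
  out <- classify_recoveries(recovery, release, rivers,
                             rearing_sep = attr(release, "rearing_sep") %||% ";")
  as.list(out[1, c("label", "exclusion_reason", "recovery_river")])
}
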