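test_that("expansion factor combines sampling and tagging corrections", {
  expect_equal(expansion_factor(1, 100, 0), 1)
  expect_equal(expansion_factor(0.5, 100, 300), 8)  # (1/0.5) * (400/100)
  # typical field values: near-complete sampling, ~3 untagged per tagged fish
  expect_equal(expansion_factor(0.99, 100, 303), (1 / 0.99) * 4.03, tolerance = 1e-12)
  expect_equal(expansion_factor(0.99, 100, 303), 4.07, tolerance = 1e-2)
  expect_error(expansion_factor(0, 100, 0), "sampling_fraction")
  expect_error(expansion_factor(1, 0, 10), "tagged_count")
})

make_expanded <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(tag_code = r$tag, recovery_site = r$site, recovery_river = "x",
               return_year = r$year %||% 2000L,
               sampling_fraction = r$sf %||% 1,
               recovery_context = "hatchery", release_river = "x",
               release_site = r$release, rearing_rivers = "",
               brood_year = 1996L, tagged_count = r$tagged %||% 100,
               untagged_count = r$untagged %||% 0, experimental = FALSE,
               label = r$label, exclusion_reason = NA_character_,
               stringsAsFactors = FALSE)
  }))
  expand_recoveries(df)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_rivers <- function() river_map(data.frame(
  site = c("H1", "H2", "elsewhere"), river = c("r1", "r2", "r3"),
  focal = c(TRUE, TRUE, FALSE)))

test_that("donor and recipient rates match a brute-force sum oracle", {
  # six recoveries with mixed labels and expansion factors
  rows <- list(
    list(tag = "t1", site = "H1", release = "H1", label = "home", sf = 0.5),        # 2 fish
    list(tag = "t1", site = "H1", release = "H1", label = "home"),                  # 1 fish
    list(tag = "t2", site = "elsewhere", release = "H1", label = "stray",
         tagged = 100, untagged = 100),                                             # 2 fish
    list(tag = "t3", site = "H1", release = "H2", label = "stray", sf = 0.25),      # 4 fish
    list(tag = "t4", site = "H1", release = "H1", label = "ambiguous"),             # ignored
    list(tag = "t5", site = "H2", release = "H2", label = "home"))                  # other hatchery
  ex <- make_expanded(rows)
  rt <- rate_table(ex, toy_rivers())
  # oracle, by hand: H1 donor home = 2+1 = 3, donor stray = 2 (the t2 fish);
  # H1 recipient local = 3, recipient stray = 4 (the t3 fish)
  expect_equal(donor_rate("H1", 2000, rt), 2 / (3 + 2))
  expect_equal(recipient_rate("H1", 2000, rt), 4 / (3 + 4))
  expect_equal(donor_rate("H2", 2000, rt), 4 / (1 + 4))
  expect_equal(recipient_rate("H2", 2000, rt), 0)
  # conservation: expanded fish are partitioned over labels
  h1 <- rt[rt$hatchery == "H1", ]
  expect_equal(h1$donor_home + h1$donor_stray + h1$donor_ambiguous, 3 + 2 + 1)
})

test_that("simple rate identities hold", {
  rows <- c(replicate(9, list(tag = "a", site = "H1", release = "H1", label = "home"),
                      simplify = FALSE),
            list(list(tag = "b", site = "elsewhere", release = "H1", label = "stray")))
  ex <- make_expanded(rows)
  rt <- rate_table(ex, toy_rivers())
  expect_equal(donor_rate("H1", 2000, rt), 0.1)
  # all-home year: a true zero, the zero-inflation case
  ex2 <- make_expanded(replicate(11, list(tag = "a", site = "H1",
                                          release = "H1", label = "home"),
                                 simplify = FALSE))
  rt2 <- rate_table(ex2, toy_rivers())
  expect_equal(donor_rate("H1", 2000, rt2), 0)
  expect_equal(recipient_rate("H1", 2000, rt2), 0)
})

test_that("empty denominators are missing, not zero; all-stray years are flagged", {
  # only ambiguous recoveries for H1: both rates missing
  ex <- make_expanded(list(list(tag = "a", site = "H1", release = "H1",
                                label = "ambiguous")))
  rt <- rate_table(ex, toy_rivers())
  expect_true(is.na(donor_rate("H1", 2000, rt)))
  expect_true(is.na(recipient_rate("H1", 2000, rt)))
  expect_true(is.na(donor_rate("H1", 1999, rt)))  # absent year
  # strays with no home fish would give rate 1: flagged and set missing
  ex3 <- make_expanded(list(list(tag = "a", site = "elsewhere", release = "H1",
                                 label = "stray")))
  expect_warning(rt3 <- rate_table(ex3, toy_rivers()), "rate would be 1")
  expect_true(is.na(donor_rate("H1", 2000, rt3)))
})

test_that("rates are invariant to uniform expansion scaling", {
  rows <- list(
    list(tag = "t1", site = "H1", release = "H1", label = "home"),
    list(tag = "t2", site = "elsewhere", release = "H1", label = "stray"),
    list(tag = "t3", site = "H1", release = "H2", label = "stray"))
  ex <- make_expanded(rows)
  rt1 <- rate_table(ex, toy_rivers())
  ex$expanded_fish <- ex$expanded_fish * 7.3
  ex$expansion_factor <- ex$expansion_factor * 7.3
  rt2 <- rate_table(ex, toy_rivers())
  expect_equal(rt1$donor_rate, rt2$donor_rate)
  expect_equal(rt1$recipient_rate, rt2$recipient_rate)
})

test_that("summaries average annual rates rather than pooling counts", {
  rows <- c(
    # year 2000: 10 home, 0 stray -> rate 0
    replicate(10, list(tag = "a", site = "H1", release = "H1",
                       label = "home", year = 2000L), simplify = FALSE),
    # year 2001: 8 home, 2 stray -> rate 0.2
    replicate(8, list(tag = "a", site = "H1", release = "H1",
                      label = "home", year = 2001L), simplify = FALSE),
    replicate(2, list(tag = "b", site = "elsewhere", release = "H1",
                      label = "stray", year = 2001L), simplify = FALSE))
  ex <- make_expanded(rows)
  rt <- rate_table(ex, toy_rivers())
  sm <- summarize_rates(rt)
  h1 <- sm[sm$hatchery == "H1", ]
  expect_equal(h1$donor_pct_mean, 10)       # mean(0, 0.2) = 0.1, not 2/20
  expect_equal(h1$donor_total, 20)
  gt <- sm[sm$hatchery == "GRAND TOTALS", ]
  expect_equal(gt$donor_total, sum(sm$donor_total[sm$hatchery != "GRAND TOTALS"]))
})
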