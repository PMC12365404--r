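test_that("release files round-trip through read_releases", {
  rel <- toy_releases()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rel, path, row.names = FALSE)
  got <- read_releases(path)
  expect_equal(nrow(got), 4)
  expect_equal(got$tag_code, rel$tag_code)
  expect_equal(got$tagged_count, rel$tagged_count)
  expect_identical(got$experimental, rel$experimental)
})

test_that("Y/N boolean dialect is parsed and round-trips", {
  rel <- toy_releases()
  rel$experimental <- c("N", "Y", "N", "N")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rel, path, row.names = FALSE)
  got <- read_releases(path)
  expect_identical(got$experimental, c(FALSE, TRUE, FALSE, FALSE))
  # write back with the parsed booleans and re-read: identical records
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(got, path2, row.names = FALSE)
  expect_equal(read_releases(path2), got, ignore_attr = TRUE)
})

test_that("invalid release rows are rejected with their row index", {
  rel <- toy_releases()
  rel$tagged_count[2] <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rel, path, row.names = FALSE)
  expect_error(read_releases(path), "tagged_count.*2")

  rel <- toy_releases()
  rel$tag_code[2] <- "A1"
  write.csv(rel, path, row.names = FALSE)
  expect_error(read_releases(path), "duplicate tag_code.*A1")

  rel <- toy_releases()[, -6]  # drop tagged_count column entirely
  write.csv(rel, path, row.names = FALSE)
  expect_error(read_releases(path), "missing column.*tagged_count")
})

test_that("recovery files are validated on read", {
  rec <- toy_recovery("A1", "Fallert Creek Hatchery")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, path, row.names = FALSE)
  expect_equal(nrow(read_recoveries(path)), 1)

  rec$sampling_fraction <- 0
  write.csv(rec, path, row.names = FALSE)
  expect_error(read_recoveries(path), "sampling_fraction")

  rec <- toy_recovery("A1", "x", context = "aquarium")
  write.csv(rec, path, row.names = FALSE)
  expect_error(read_recoveries(path), "recovery_context")
})

test_that("classification follows the river-scale operational definitions", {
  rel <- toy_releases()
  rivers <- toy_map()
  # released Fallert Creek (Kalama R.), recovered Kalama Falls (same river): home
  cls <- classify_recovery(toy_recovery("A1", "Kalama Falls Hatchery"),
                           rel[1, ], rivers)
  expect_equal(cls$label, "home")
  # reared in the Klickitat, released in the Wind, recovered in the Klickitat
  cls <- classify_recovery(toy_recovery("A2", "Klickitat site"), rel[2, ], rivers)
  expect_equal(cls$label, "ambiguous")
  # ocean recovery: excluded regardless of context
  cls <- classify_recovery(toy_recovery("A2", "OCEAN", context = "fishery"),
                           rel[2, ], rivers)
  expect_equal(cls$label, "excluded")
  # released in the Wind, recovered Little White Salmon: stray
  cls <- classify_recovery(toy_recovery("B1", "Little White Salmon NFH"),
                           rel[3, ], rivers)
  expect_equal(cls$label, "stray")
  # in-river fishery recovery: excluded (no volitional return)
  cls <- classify_recovery(toy_recovery("A1", "Fallert Creek Hatchery",
                                        context = "fishery"), rel[1, ], rivers)
  expect_equal(cls$label, "excluded")
  expect_equal(cls$exclusion_reason, "fishery_recovery")
})

test_that("experimental releases are excluded even at home", {
  rel <- toy_releases()
  rel$experimental[1] <- TRUE
  cls <- classify_recovery(toy_recovery("A1", "Fallert Creek Hatchery"),
                           rel[1, ], toy_map())
  expect_equal(cls$label, "excluded")
  expect_equal(cls$exclusion_reason, "experimental_release")
})

test_that("classification is total, exclusive, and order-invariant", {
  rel <- toy_releases()
  rivers <- toy_map()
  recs <- do.call(rbind, list(
    toy_recovery("A1", "Kalama Falls Hatchery"),
    toy_recovery("A2", "Klickitat site"),
    toy_recovery("A2", "OCEAN"),
    toy_recovery("B1", "Little White Salmon NFH"),
    toy_recovery("C1", "Fallert Creek Hatchery"),
    toy_recovery("A1", "Carson NFH")))
  cls <- classify_recoveries(recs, rel, rivers)
  expect_equal(nrow(cls), nrow(recs))
  expect_true(all(cls$label %in% c("home", "stray", "ambiguous", "excluded")))
  expect_identical(is.na(cls$exclusion_reason), cls$label != "excluded")
  for (perm in list(c(2, 4, 6, 1, 3, 5), 6:1)) {
    cls_p <- classify_recoveries(recs[perm, ], rel, rivers)
    expect_equal(sort(cls_p$label), sort(cls$label))
  }
})

test_that("unmapped sites and unmatched tags are surfaced", {
  rel <- toy_releases()
  rivers <- toy_map()
  expect_error(classify_recoveries(toy_recovery("A1", "Mystery Creek"), rel, rivers),
               "Mystery Creek")
  expect_message(
    cls <- classify_recoveries(
      rbind(toy_recovery("A1", "Fallert Creek Hatchery"),
            toy_recovery("ZZZ", "Fallert Creek Hatchery")), rel, rivers),
    "no matching release")
  expect_equal(nrow(cls), 1)
  expect_error(classify_recovery(toy_recovery("A1", "x"), rel[2, ], rivers),
               "tag codes differ")
})

test_that("river map rejects conflicting duplicates and honours aliases", {
  expect_error(river_map(data.frame(site = c("s", "S "), river = c("r1", "r2"))),
               "more than one river")
  rm <- river_map(data.frame(site = c("Fallert Creek Hatchery", "FALLERT CR. H"),
                             river = c("Kalama", "Kalama"),
                             focal = c(TRUE, FALSE)))
  cls <- classify_recovery(toy_recovery("A1", "fallert cr. h"),
                           toy_releases()[1, ], rm)
  expect_equal(cls$label, "home")
})
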