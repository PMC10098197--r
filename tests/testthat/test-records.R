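test_that("events survive a write/read round trip", {
  ev <- dplyr::bind_rows(
    make_event("A1-1", weights = list(c(380.5, 412)), nAnimalsTreated = 2L),
    make_event("A1-2", productId = "P01", quantityUsed = 12.25,
               durationDays = 3.5, weights = list(numeric(0))),
    make_event("A2-1", productId = "P12", administrator = "FARMER",
               indication = "FEVER")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$eventId, ev$eventId)
  expect_equal(back$quantityUsed, ev$quantityUsed)
  expect_equal(back$durationDays, ev$durationDays)
  expect_equal(back$weightsKg, ev$weightsKg)
  # a second round trip is byte-identical (column order and formatting fixed)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_events(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invalid event rows are rejected with row-level messages", {
  ev <- dplyr::bind_rows(
    make_event("OK-1"),
    make_event("BAD-1", durationDays = 0),
    make_event("BAD-2", indication = "COLIC"),
    make_event("BAD-3", weights = list(c(400, 410))) # 2 weights, 1 animal
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  expect_warning(back <- read_events(path), "invalid event row")
  expect_equal(back$eventId, "OK-1")
  errs <- attr(back, "errors")
  expect_equal(sort(errs$eventId), c("BAD-1", "BAD-2", "BAD-3"))
  expect_match(errs$message[errs$eventId == "BAD-1"], "durationDays")
  expect_match(errs$message[errs$eventId == "BAD-2"], "indication")
})

test_that("a header-only events file yields an empty list with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(make_event()[0, ], path)
  expect_warning(back <- read_events(path), "no event rows")
  expect_equal(nrow(back), 0)
})

test_that("bin deposits parse and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    herdId = "H1", month = 1:3, productId = "P05",
    emptiesCount = c(2, 0, 1),
    partialUseNote = c(NA, "prescription: 12 mL over 3 days", NA)
  ), path)
  b <- read_bin_deposits(path)
  expect_equal(nrow(b), 3)
  expect_equal(b$emptiesCount[2], 0) # prescription-only evidence accepted

  readr::write_csv(tibble::tibble(
    herdId = "H1", month = 13L, productId = "P05", emptiesCount = 1,
    partialUseNote = NA_character_
  ), path)
  expect_error(read_bin_deposits(path), "month")

  readr::write_csv(tibble::tibble(
    herdId = "H1", month = 1L, productId = "P05", emptiesCount = -1,
    partialUseNote = NA_character_
  ), path)
  expect_error(read_bin_deposits(path), "emptiesCount")
})

test_that("herd registry enforces the household/commercial size definition", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    herdId = c("H1", "H2"), herdType = c("HOUSEHOLD", "COMMERCIAL"),
    nCattle = c(3L, 30L), nBuffalo = c(5L, 10L), enrolmentDays = 365L
  ), path)
  h <- read_herds(path)
  expect_equal(h$herdType, c("HOUSEHOLD", "COMMERCIAL"))

  readr::write_csv(tibble::tibble(
    herdId = "H1", herdType = "HOUSEHOLD", nCattle = 30L, nBuffalo = 0L,
    enrolmentDays = 365L
  ), path)
  expect_error(read_herds(path), "household")

  readr::write_csv(tibble::tibble(
    herdId = "H1", herdType = "COMMERCIAL", nCattle = 10L, nBuffalo = 5L,
    enrolmentDays = 365L
  ), path)
  expect_error(read_herds(path), "commercial")
})

no_deposits <- function() {
  tibble::tibble(herdId = character(), month = integer(),
                 productId = character(), emptiesCount = double(),
                 partialUseNote = character())
}

test_that("perfect agreement between streams matches every event", {
  ev <- make_event(quantityUsed = 60) # P05: unitSize 30 -> 2 full vials
  dep <- tibble::tibble(herdId = "H1", month = 1L, productId = "P05",
                        emptiesCount = 2, partialUseNote = NA_character_)
  rec <- reconcile(ev, dep, CAT)
  expect_equal(rec$matched, 1)
  expect_equal(rec$historyOnly, 0)
  expect_equal(rec$binOnly, 0)
  expect_equal(sum(rec$massDiscrepancyMg$discrepancyMg), 0)
})

test_that("unilateral evidence is classified as history-only or bin-only", {
  ev <- make_event(quantityUsed = 60)
  rec <- reconcile(ev, no_deposits(), CAT)
  expect_equal(rec$historyOnly, 1)
  expect_equal(rec$matched, 0)

  dep <- tibble::tibble(herdId = "H9", month = 2L, productId = "P01",
                        emptiesCount = 1, partialUseNote = NA_character_)
  rec2 <- reconcile(ev, dep, CAT)
  expect_equal(rec2$historyOnly, 1)
  expect_equal(rec2$binOnly, 1) # candidate unrecorded/unauthorized use
  expect_equal(rec2$matched + rec2$historyOnly, nrow(ev))
})

test_that("swapping the streams swaps history-only and bin-only counts", {
  # one record per stream per group, so the swap is well-typed
  ev <- dplyr::bind_rows(
    make_event("E1-1", herdId = "H1", month = 1L, quantityUsed = 60),
    make_event("E2-1", herdId = "H2", month = 3L, productId = "P01",
               quantityUsed = 10)
  )
  dep <- tibble::tibble(herdId = c("H1", "H3"), month = c(1L, 5L),
                        productId = c("P05", "P10"), emptiesCount = c(2, 1),
                        partialUseNote = NA_character_)
  fwd <- reconcile(ev, dep, CAT)
  # swapped: events built from the deposits, deposits built from the events
  unit_of <- setNames(CAT$products$unitSize, CAT$products$productId)
  ev_swap <- dplyr::bind_rows(purrr::map(seq_len(nrow(dep)), function(i) {
    make_event(sprintf("S%d-1", i), herdId = dep$herdId[i],
               month = dep$month[i], productId = dep$productId[i],
               quantityUsed = dep$emptiesCount[i] * unit_of[dep$productId[i]])
  }))
  dep_swap <- tibble::tibble(
    herdId = ev$herdId, month = ev$month, productId = ev$productId,
    emptiesCount = ev$quantityUsed / unit_of[ev$productId],
    partialUseNote = NA_character_
  )
  bwd <- reconcile(ev_swap, dep_swap, CAT)
  expect_equal(fwd$historyOnly, bwd$binOnly)
  expect_equal(fwd$binOnly, bwd$historyOnly)
  expect_equal(fwd$matched, bwd$matched)
})

test_that("the match tolerance is relative and configurable", {
  ev <- make_event(quantityUsed = 57.6) # 4% short of 2 full vials
  dep <- tibble::tibble(herdId = "H1", month = 1L, productId = "P05",
                        emptiesCount = 2, partialUseNote = NA_character_)
  expect_equal(reconcile(ev, dep, CAT, tolerance = 0.05)$matched, 1)
  expect_equal(reconcile(ev, dep, CAT, tolerance = 0.01)$matched, 0)
})

test_that("partial-use notes carry the unused remainder into the bin mass", {
  ev <- make_event(quantityUsed = 47.5) # 2 vials, 12.5 mL leftover
  dep <- tibble::tibble(herdId = "H1", month = 1L, productId = "P05",
                        emptiesCount = 2,
                        partialUseNote = "leftover_mL=12.5")
  rec <- reconcile(ev, dep, CAT, tolerance = 0)
  expect_equal(rec$matched, 1)
  expect_equal(sum(rec$massDiscrepancyMg$discrepancyMg), 0)
})

test_that("history-implied mass conserves the event-level active masses", {
  ev <- random_events(25, seed = 11)
  rec <- reconcile(ev, no_deposits(), CAT)
  implied <- sum(rec$detail$historyMassMg)
  direct <- sum(vapply(seq_len(nrow(ev)), function(i) {
    m <- total_active_mass(CAT, ev$productId[i], ev$quantityUsed[i])
    m$massMg[m$role == "DOSE_DETERMINING"]
  }, numeric(1)))
  expect_equal(implied, direct)
})
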