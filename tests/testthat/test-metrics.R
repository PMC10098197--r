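test_that("the ADD is the recommended dose scaled by weight, in g/day", {
  expect_equal(animal_daily_dose(7.5, 500), 3.75)
  expect_equal(animal_daily_dose(1.0, 1000), 1.0)
  expect_equal(animal_daily_dose(0.625, 400), 0.25)
  expect_error(animal_daily_dose(0, 400), "> 0")
})

test_that("the intramammary ADD is dose x units x frequency", {
  expect_equal(intramammary_add(200, 1, 2), 400)
  expect_equal(intramammary_add(100, 1, 1), 100)
  expect_equal(intramammary_add(250, 2, 3), 1500)
  expect_error(intramammary_add(0, 1, 1), "> 0")
})

test_that("nADD divides administered grams by the standard daily dose", {
  expect_equal(n_add(3750, 3.75), 1.0)
  expect_equal(n_add(0, 3.75), 0)
  expect_equal(n_add(11250, 3.75), 3.0)
  expect_error(n_add(100, 0), "ADD")
})

test_that("the UDD is mass over animals x weight x days", {
  expect_equal(used_daily_dose(7500, 1, 500, 2), 7.5)
  expect_equal(used_daily_dose(30000, 2, 500, 3), 10.0)
  # consistency: administering exactly the recommended dose recovers DDDkg
  ddd <- 5.26; w <- 430; n <- 2; days <- 3
  expect_equal(used_daily_dose(ddd * w * n * days, n, w, days), ddd)
  expect_error(used_daily_dose(100, 0, 500, 2), "> 0")
})

test_that("nUADD divides mass by the used animal daily dose", {
  expect_equal(n_uadd(7500, 7.5, 500), 2.0)
  expect_equal(n_uadd(30000, 10.0, 500), 6.0) # 2 animals x 3 days
  expect_error(n_uadd(100, 0, 500), "UADD")
})

test_that("ADUR normalizes use to 1000 animal-days and scales as a rate", {
  expect_equal(adur(300, 2.0, 365, 1010), 300 * 1000 / (2 * 365 * 1010))
  expect_equal(adur(0, 2.0, 365, 1010), 0)
  set.seed(3)
  for (i in 1:20) {
    m <- runif(1, 1, 500); a <- runif(1, 0.1, 6)
    d <- sample(30:365, 1); n <- sample(10:2000, 1); k <- runif(1, 0.5, 4)
    expect_equal(adur(k * m, a, d, n), k * adur(m, a, d, n))
    expect_equal(adur(m, a, d, 2 * n), adur(m, a, d, n) / 2)
    expect_equal(adur(m, k * a, d, n), adur(m, a, d, n) / k)
    expect_equal(adur(m, a, k * d, n), adur(m, a, d, n) / k)
  }
})

test_that("dosing classification uses an inclusive 0.8-1.2 band", {
  expect_equal(dosing_classification(0.95 * 5, 5)$dosingClass, "CORRECT")
  expect_equal(dosing_classification(2.00 * 5, 5)$dosingClass, "OVER")
  expect_equal(dosing_classification(0.19 * 5, 5)$dosingClass, "UNDER")
  expect_equal(dosing_classification(0.8 * 5, 5)$dosingClass, "CORRECT")
  expect_equal(dosing_classification(1.2 * 5, 5)$dosingClass, "CORRECT")
  expect_equal(dosing_classification(5, 5, band = c(0.9, 1.1))$doseRatio, 1)
  expect_error(dosing_classification(5, 0), "dddKg")
})

test_that("event metrics satisfy the internal dose-count identities", {
  ev <- make_event(quantityUsed = 30, weights = list(c(380, 420)),
                   nAnimalsTreated = 2L, durationDays = 3)
  m <- compute_event_metrics(ev, CAT)
  expect_equal(m$nAdd * m$addGPerDay, m$totalMassMg / 1000)
  expect_equal(m$nUadd, 2 * 3)
  expect_equal(m$uaddMgPerDay, m$uddMgPerKgDay * 400)
  # doseRatio == UADD / (ADD in mg/day) when the same weight enters both
  expect_equal(m$doseRatio, m$uaddMgPerDay / (m$addGPerDay * 1000))
})

test_that("an intramammary event follows the syringe-based dose chain", {
  # 2 syringes x 2/day x 3 days of a 200 mg/unit product
  ev <- make_event(productId = "P17", quantityUsed = 12,
                   route = "INTRAMAMMARY", durationDays = 3,
                   adminsPerDay = 2L)
  m <- compute_event_metrics(ev, CAT)
  expect_equal(m$totalMassMg, 2400)
  expect_equal(m$addGPerDay * 1000, 800) # mg/day
  expect_equal(m$nAdd, 3.0)
  expect_equal(m$nUadd, 3.0) # 1 animal x 3 days
  expect_equal(m$doseRatio, 1.0) # used daily amount equals the standard
})

test_that("events with no recorded weights fall back to the species median", {
  ev <- make_event(weights = list(numeric(0)), quantityUsed = 10)
  m <- compute_event_metrics(ev, CAT)
  m400 <- compute_event_metrics(make_event(quantityUsed = 10), CAT)
  expect_equal(m$addGPerDay, m400$addGPerDay)
  cfg <- metric_config(fallbackWeightsKg = c(CATTLE = 500, BUFFALO = 500))
  m500 <- compute_event_metrics(ev, CAT, cfg)
  expect_equal(m500$addGPerDay / m$addGPerDay, 500 / 400)
})

test_that("metric errors are annotated with the offending event", {
  ev <- make_event(eventId = "BROKEN-1", productId = "NOPE")
  expect_error(compute_event_metrics(ev, CAT), "BROKEN-1")
})

test_that("nUADD equals animal-treatment-days for every computed event", {
  ev <- random_events(200, seed = 5)
  m <- compute_event_metrics(ev, CAT)
  expect_equal(m$nUadd, ev$nAnimalsTreated * ev$durationDays,
               tolerance = 1e-9)
})

test_that("herd-level nADD matches the per-animal-per-day expansion oracle", {
  for (seed in 1:4) {
    ev <- random_events(sample(3:10, 1), seed = seed)
    m <- compute_event_metrics(ev, CAT)
    expect_equal(sum(m$nAdd), brute_force_nadd(ev, CAT), tolerance = 1e-9)
  }
})

test_that("mass conservation holds from events to herd totals", {
  ev <- random_events(50, seed = 9)
  m <- compute_event_metrics(ev, CAT)
  herd_totals <- m |>
    dplyr::group_by(herdId, substance) |>
    dplyr::summarise(mass = sum(totalMassMg), .groups = "drop")
  expect_equal(sum(herd_totals$mass), sum(m$totalMassMg))
  direct <- vapply(seq_len(nrow(ev)), function(i) {
    x <- total_active_mass(CAT, ev$productId[i], ev$quantityUsed[i])
    x$massMg[x$role == "DOSE_DETERMINING"]
  }, numeric(1))
  expect_equal(sum(m$totalMassMg), sum(direct))
})

test_that("metrics tables round trip through CSV at full precision", {
  ev <- random_events(20, seed = 2)
  m <- compute_event_metrics(ev, CAT)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(m, path)
  back <- read_metrics(path)
  expect_equal(back$nAdd, m$nAdd)
  expect_equal(back$doseRatio, m$doseRatio)
})

test_that("the ADUR table supports herd-level and pooled denominators", {
  fx <- reference_dataset()
  m <- compute_event_metrics(fx$events, fx$catalogue)
  pooled <- adur_table(m, fx$herds, denominator = "pooled")
  expect_equal(
    pooled$adur[pooled$substance == "ceftriaxone"],
    1000 * sum(m$nAdd[m$substance == "ceftriaxone"]) / (365 * 1010)
  )
  herd <- adur_table(m, fx$herds, denominator = "herd")
  expect_true(all(c("medianAdur", "meanAdur") %in% names(herd)))
  expect_equal(sort(herd$substance), sort(pooled$substance))
})
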