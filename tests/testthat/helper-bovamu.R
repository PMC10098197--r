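# shared fixtures and independent oracles, built in code

CAT <- default_catalogue()

make_event <- function(eventId = "E1", herdId = "H1", month = 1L,
                       indication = "MASTITIS", productId = "P05",
                       quantityUsed = 10, nAnimalsTreated = 1L,
                       weights = list(400), durationDays = 2,
                       route = "PARENTERAL",
                       administrator = "VETERINARIAN", adminsPerDay = 1L) {
  tibble::tibble(
    eventId = eventId, herdId = herdId, month = month,
    indication = indication, productId = productId,
    quantityUsed = quantityUsed, quantityUnit = "mL",
    nAnimalsTreated = nAnimalsTreated, weightsKg = weights,
    durationDays = durationDays, route = route,
    administrator = administrator, adminsPerDay = adminsPerDay
  )
}

# random parenteral events against the bundled catalogue (integer durations
# so the per-animal-per-day oracle is exact)
random_events <- function(n, seed = 1) {
  set.seed(seed)
  prods <- c("P01", "P02", "P05", "P07", "P08", "P10", "P12", "P13")
  purrr::map_dfr(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    make_event(
      eventId = sprintf("R%04d-1", i),
      herdId = sprintf("H%02d", sample(1:5, 1)),
      month = sample(1:12, 1),
      indication = sample(c("MASTITIS", "FEVER", "REPRODUCTIVE",
                            "DIARRHEA", "MISC"), 1),
      productId = sample(prods, 1),
      quantityUsed = runif(1, 0.5, 80),
      nAnimalsTreated = k,
      weights = list(round(runif(k, 300, 650), 1)),
      durationDays = sample(1:5, 1)
    )
  })
}

# independent oracle: expand an event into per-animal, per-day doses and sum
# standard-dose counts; assumes the administered mass splits evenly over
# animals and days and doses against the mean recorded weight
brute_force_nadd <- function(events, catalogue, config = metric_config()) {
  total <- 0
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    dd <- resolve_dose_determining(catalogue, ev$productId)
    masses <- total_active_mass(catalogue, ev$productId, ev$quantityUsed)
    mass_mg <- masses$massMg[masses$role == "DOSE_DETERMINING"]
    w <- if (length(ev$weightsKg[[1]])) mean(ev$weightsKg[[1]]) else 400
    ddd <- lookup_ddd(catalogue, dd$substance, "CATTLE", ev$route)$dddKg
    per_dose <- mass_mg / (ev$nAnimalsTreated * ev$durationDays)
    for (a in seq_len(ev$nAnimalsTreated)) {
      for (d in seq_len(ev$durationDays)) {
        total <- total + (per_dose / 1000) / (ddd * w / 1000)
      }
    }
  }
  total
}

write_fixture_dir <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fx <- reference_dataset()
  write_dataset(dir, fx$catalogue, fx$herds, fx$events, fx$deposits)
  dir
}
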