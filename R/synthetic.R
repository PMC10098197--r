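# Synthetic surveillance data: herd populations, treatment events and bin
# deposits with the statistical structure of the modelled study design
# (38 herds, 1010 adult bovines, 12 months), plus ground truth for
# parameter-recovery checks.

# Per-substance reference table used both by the generator (indication mix,
# dosing-behaviour targets) and by the deterministic reference dataset:
# administration counts per indication, herd counts, summed dose-count
# metrics, median used daily dose, and dosing ratio. The mastitis,
# reproductive and fever columns and all metric columns are the published
# surveillance totals; the diarrhea/misc split is a fixed editorial
# allocation of the residual (the source tables pool them).
substance_reference <- function() {
  tibble::tribble(
    ~substance,                  ~mastitis, ~reproductive, ~fever, ~diarrhea, ~misc, ~nHerds, ~nAdd, ~nUadd, ~uddMed, ~ratio,
    "ceftriaxone",               25, 4, 3,  0, 2, 19, 79.55, 74.35,  7.50, 1.07,
    "ceftiofur",                 2,  8, 1,  0, 2, 8,  45.77, 22.89,  1.25, 2.00,
    "cefoperazone",              10, 0, 0,  0, 2, 10, 19.01, 19.01, 11.25, 1.00,
    "ceftizoxime",               6,  0, 0,  0, 1, 6,  16.50, 11.00,  7.50, 1.50,
    "enrofloxacin",              31, 6, 16, 1, 3, 34, 78.93, 83.08,  5.00, 0.95,
    "levofloxacin",              2,  0, 0,  0, 0, 2,  1.60,  1.78,   4.00, 0.90,
    "gentamicin",                12, 0, 5,  0, 1, 13, 5.69,  29.95,  1.80, 0.19,
    "amoxicillin",               24, 5, 5,  0, 0, 19, 31.68, 35.20,  7.50, 0.90,
    "ampicillin",                2,  0, 0,  0, 0, 2,  3.19,  6.13,   4.50, 0.52,
    "oxytetracycline",           7,  4, 18, 1, 1, 21, 18.63, 49.03,  3.25, 0.38,
    "cefalexin",                 0,  9, 0,  0, 0, 7,  9.26,  17.15,  6.75, 0.54,
    "procaine benzylpenicillin", 23, 1, 3,  0, 5, 18, 43.50, 124.29, 3.25, 0.35,
    "sulphadiazine",             1,  0, 1,  7, 1, 10, 4.51,  19.61,  3.00, 0.23,
    "metronidazole",             0,  4, 0,  0, 0, 4,  2.50,  10.00,  1.25, 0.25
  )
}

# disease cases per indication in the modelled study year (208 total)
CASE_COUNTS <- c(MASTITIS = 105L, FEVER = 43L, REPRODUCTIVE = 36L,
                 DIARRHEA = 9L, MISC = 15L)

#' Simulation configuration
#'
#' Defaults encode the modelled study conditions: 20 household and 18
#' commercial herds totalling about 1010 adult bovines (cattle fraction
#' 519/1010), four-parameter weight distributions per species, a yearly
#' case rate calibrated to about 208 cases, the observed indication and
#' administrator mixes, indication-specific substance-choice weights, and
#' per-substance dosing-behaviour multipliers targeting the observed
#' UDD/DDDkg ratios.
#'
#' @param nHouseholdHerds,nCommercialHerds herd counts per type.
#' @param householdSize,commercialSize inclusive animal-count ranges.
#' @param cattleProportion probability an animal is a cow (vs buffalo).
#' @param weightDist per-species named vectors `min`, `median`, `mean`, `max`
#'   (kg); realized as a scaled Beta fitted to median and mean.
#' @param periodDays observation period.
#' @param caseRatePerAnimalYear expected disease cases per animal-year in
#'   household herds.
#' @param commercialUsageMultiplier case-rate multiplier for commercial herds
#'   (drives the household-vs-commercial usage contrast).
#' @param indicationMix named case-mix probabilities (must sum to 1).
#' @param extraAdminRate Poisson rate of additional product administrations
#'   per case beyond the first (265 administrations / 208 cases observed).
#' @param dosingMultipliers named per-substance multipliers applied to the
#'   recommended dose (target UDD/DDDkg ratios).
#' @param doseNoiseSdlog lognormal (median-preserving) dosing noise.
#' @param durationRange inclusive integer range of treatment days.
#' @param nTreatedProbs probabilities of treating 1, 2, 3 animals per event.
#' @param administratorMix named administrator probabilities.
#' @param binCompliance probability a herd-month-product group's empties
#'   reach the bin.
#' @return validated config list.
#' @export
sim_config <- function(nHouseholdHerds = 20, nCommercialHerds = 18,
                       householdSize = c(5, 20), commercialSize = c(21, 63),
                       cattleProportion = 519 / 1010,
                       weightDist = list(
                         CATTLE = c(min = 300, median = 400, mean = 421, max = 520),
                         BUFFALO = c(min = 425, median = 500, mean = 525, max = 650)
                       ),
                       periodDays = 365,
                       caseRatePerAnimalYear = 0.15,
                       commercialUsageMultiplier = 1.5,
                       indicationMix = c(MASTITIS = 0.5048, FEVER = 0.2067,
                                         REPRODUCTIVE = 0.1731,
                                         DIARRHEA = 0.0432, MISC = 0.0722),
                       extraAdminRate = 265 / 208 - 1,
                       dosingMultipliers = NULL,
                       doseNoiseSdlog = 0.1,
                       durationRange = c(2, 5),
                       nTreatedProbs = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
                       administratorMix = c(PARA_VETERINARIAN = 0.3421,
                                            UNAUTHORIZED = 0.2632,
                                            FARMER = 0.2368,
                                            VETERINARIAN = 0.1579),
                       binCompliance = 1.0) {
  ref <- substance_reference()
  if (is.null(dosingMultipliers)) {
    dosingMultipliers <- stats::setNames(ref$ratio, ref$substance)
  }
  cfg <- list(
    nHouseholdHerds = nHouseholdHerds, nCommercialHerds = nCommercialHerds,
    householdSize = householdSize, commercialSize = commercialSize,
    cattleProportion = cattleProportion, weightDist = weightDist,
    periodDays = periodDays, caseRatePerAnimalYear = caseRatePerAnimalYear,
    commercialUsageMultiplier = commercialUsageMultiplier,
    indicationMix = indicationMix, extraAdminRate = extraAdminRate,
    dosingMultipliers = dosingMultipliers, doseNoiseSdlog = doseNoiseSdlog,
    durationRange = durationRange, nTreatedProbs = nTreatedProbs,
    administratorMix = administratorMix, binCompliance = binCompliance
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$nHouseholdHerds < 0 || cfg$nCommercialHerds < 0 ||
      cfg$nHouseholdHerds + cfg$nCommercialHerds < 1) {
    amu_stop("herd counts must be positive")
  }
  if (cfg$householdSize[1] < 5 || cfg$householdSize[2] > 20 ||
      cfg$householdSize[1] > cfg$householdSize[2]) {
    amu_stop("householdSize must lie within 5-20")
  }
  if (cfg$commercialSize[1] <= 20 || cfg$commercialSize[1] > cfg$commercialSize[2]) {
    amu_stop("commercialSize must exceed 20")
  }
  for (p in list(cfg$indicationMix, cfg$nTreatedProbs, cfg$administratorMix)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      amu_stop("probability mixes must be non-negative and sum to 1")
    }
  }
  if (cfg$binCompliance < 0 || cfg$binCompliance > 1) {
    amu_stop("binCompliance must be in [0,1]")
  }
  if (cfg$cattleProportion < 0 || cfg$cattleProportion > 1) {
    amu_stop("cattleProportion must be in [0,1]")
  }
  if (cfg$caseRatePerAnimalYear <= 0 || cfg$periodDays <= 0) {
    amu_stop("rates and periods must be positive")
  }
  invisible(cfg)
}

#' Fit a scaled Beta to four weight summaries
#'
#' Finds Beta shape parameters on `[min, max]` whose mean and median best
#' match the stated values (least squares on the two moments; the four
#' summaries over-determine a two-parameter family, so the fit is a
#' compromise; see the methods vignette).
#'
#' @param min,median,mean,max weight summaries in kg.
#' @return list with `shape1`, `shape2`, `min`, `max`, and the achieved
#'   `fittedMean` / `fittedMedian` on the kg scale.
#' @export
fit_beta_weights <- function(min, median, mean, max) {
  m <- (mean - min) / (max - min)
  med <- (median - min) / (max - min)
  # shapes constrained >= 1 (unimodal: every weight in [min, max] without
  # edge spikes); the median is weighted above the mean because the stated
  # median > midpoint-relative mean combination is infeasible for a Beta
  loss <- function(par) {
    a <- 1 + exp(par[1]); b <- 1 + exp(par[2])
    4 * (stats::qbeta(0.5, a, b) - med)^2 + (a / (a + b) - m)^2
  }
  fit <- stats::optim(c(log(2), log(2)), loss, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  a <- 1 + exp(fit$par[1]); b <- 1 + exp(fit$par[2])
  list(shape1 = a, shape2 = b, min = min, max = max,
       fittedMean = min + (max - min) * a / (a + b),
       fittedMedian = min + (max - min) * stats::qbeta(0.5, a, b))
}

draw_weights <- function(n, dist, fit) {
  dist[["min"]] + (dist[["max"]] - dist[["min"]]) *
    stats::rbeta(n, fit$shape1, fit$shape2)
}

#' Generate the herd population
#'
#' Draws herd sizes per type, assigns species by the configured cattle
#' proportion, and draws weights from the fitted per-species distributions.
#' Deterministic under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `herds` and `animals` tibbles.
#' @export
generate_population <- function(config, seed = 1) {
  validate_sim_config(config)
  with_seed(seed, {
    fits <- lapply(config$weightDist, function(d) {
      fit_beta_weights(d[["min"]], d[["median"]], d[["mean"]], d[["max"]])
    })
    n_h <- config$nHouseholdHerds
    n_c <- config$nCommercialHerds
    sizes <- c(
      sample(seq(config$householdSize[1], config$householdSize[2]), n_h,
             replace = TRUE),
      sample(seq(config$commercialSize[1], config$commercialSize[2]), n_c,
             replace = TRUE)
    )
    herd_ids <- sprintf("H%02d", seq_len(n_h + n_c))
    types <- c(rep("HOUSEHOLD", n_h), rep("COMMERCIAL", n_c))
    animals <- purrr::map2(herd_ids, sizes, function(h, n) {
      species <- ifelse(stats::runif(n) < config$cattleProportion,
                        "CATTLE", "BUFFALO")
      w <- numeric(n)
      for (sp in unique(species)) {
        idx <- species == sp
        w[idx] <- draw_weights(sum(idx), config$weightDist[[sp]], fits[[sp]])
      }
      tibble::tibble(
        animalId = sprintf("%s-A%03d", h, seq_len(n)),
        herdId = h, species = species, weightKg = w
      )
    }) |> dplyr::bind_rows()
    herds <- animals |>
      dplyr::count(.data$herdId, .data$species) |>
      tidyr::pivot_wider(names_from = "species", values_from = "n",
                         values_fill = 0L) |>
      dplyr::rename_with(~ c(CATTLE = "nCattle", BUFFALO = "nBuffalo")[.x],
                         dplyr::any_of(c("CATTLE", "BUFFALO")))
    if (!"nCattle" %in% names(herds)) herds$nCattle <- 0L
    if (!"nBuffalo" %in% names(herds)) herds$nBuffalo <- 0L
    herds <- herds |>
      dplyr::mutate(herdType = types[match(.data$herdId, herd_ids)],
                    enrolmentDays = as.integer(config$periodDays)) |>
      dplyr::select("herdId", "herdType", "nCattle", "nBuffalo",
                    "enrolmentDays")
    validate_herds(herds)
    list(herds = herds, animals = animals)
  })
}

# indication-specific substance-choice weights from the reference counts
substance_weights <- function() {
  ref <- substance_reference()
  list(
    MASTITIS = stats::setNames(ref$mastitis, ref$substance),
    REPRODUCTIVE = stats::setNames(ref$reproductive, ref$substance),
    FEVER = stats::setNames(ref$fever, ref$substance),
    DIARRHEA = stats::setNames(ref$diarrhea, ref$substance),
    MISC = stats::setNames(ref$misc, ref$substance)
  )
}

# the single-substance parenteral product for each reference substance
substance_products <- function(catalogue) {
  ref <- substance_reference()
  single <- catalogue$components |>
    dplyr::count(.data$productId) |>
    dplyr::filter(.data$n == 1)
  par <- catalogue$products$productId[
    catalogue$products$formulation == "PARENTERAL"]
  comp <- catalogue$components[
    catalogue$components$productId %in% intersect(single$productId, par), ]
  stats::setNames(comp$productId, comp$substance)[ref$substance]
}

#' Generate treatment events, bin deposits and ground truth
#'
#' Cases arrive per herd as Poisson draws with rate proportional to herd
#' size (commercial herds scaled by the usage multiplier); each case emits
#' one or more product administrations with substance chosen by
#' indication-specific weights. The administered mass targets
#' `DDDkg x mean weight x duration x animals x dosingMultiplier`, with
#' median-preserving lognormal dosing noise, dispensed as a continuous
#' syringe volume. Empties are deposited per herd-month-product with
#' probability `binCompliance`; a partially used final container is
#' accompanied by a machine-readable prescription note recording the
#' leftover volume.
#'
#' @param population output of [generate_population()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param catalogue an `amu_catalogue` (defaults to the bundled one).
#' @return list with `events`, `deposits`, and `groundTruth` (per-substance
#'   true masses, per-event true dose ratios, per-herd true nADD,
#'   per-indication case counts).
#' @export
generate_treatments <- function(population, config, seed = 1,
                                catalogue = default_catalogue()) {
  validate_sim_config(config)
  if (nrow(population$animals) == 0) amu_stop("empty population")
  herds <- population$herds
  animals <- population$animals
  prod_of <- substance_products(catalogue)
  weights_by_ind <- substance_weights()
  ref <- substance_reference()
  ddd_of <- stats::setNames(
    vapply(ref$substance, function(s) {
      lookup_ddd(catalogue, s, "BOVINE_ANY", "PARENTERAL")$dddKg
    }, numeric(1)),
    ref$substance
  )
  comp <- catalogue$components
  conc_of <- stats::setNames(
    concentration_mg(comp$concentration, comp$concentrationUnit,
                     catalogue$iu_per_mg),
    comp$productId
  )[prod_of]
  names(conc_of) <- ref$substance

  with_seed(seed, {
    case_rows <- list()
    event_rows <- list()
    truth_rows <- list()
    ev_n <- 0L
    case_n <- 0L
    for (hi in seq_len(nrow(herds))) {
      h <- herds[hi, ]
      n_animals <- h$nCattle + h$nBuffalo
      mult <- if (h$herdType == "COMMERCIAL") config$commercialUsageMultiplier else 1
      lambda <- config$caseRatePerAnimalYear * n_animals * mult *
        h$enrolmentDays / 365
      n_cases <- stats::rpois(1, lambda)
      if (n_cases == 0) next
      herd_weights <- animals$weightKg[animals$herdId == h$herdId]
      for (ci in seq_len(n_cases)) {
        case_n <- case_n + 1L
        indication <- sample(names(config$indicationMix), 1,
                             prob = config$indicationMix)
        month <- sample.int(12, 1)
        administrator <- sample(names(config$administratorMix), 1,
                                prob = config$administratorMix)
        n_admin <- 1L + stats::rpois(1, config$extraAdminRate)
        case_rows[[case_n]] <- tibble::tibble(indication = indication)
        for (ai in seq_len(n_admin)) {
          ev_n <- ev_n + 1L
          wts <- weights_by_ind[[indication]]
          if (sum(wts) == 0) wts <- wts + 1
          substance <- sample(names(wts), 1, prob = wts)
          n_treated <- as.integer(sample(names(config$nTreatedProbs), 1,
                                         prob = config$nTreatedProbs))
          n_treated <- min(n_treated, n_animals)
          w <- round(sample(herd_weights, n_treated,
                            replace = n_treated > length(herd_weights)), 1)
          duration <- sample(seq(config$durationRange[1],
                                 config$durationRange[2]), 1)
          target_mult <- config$dosingMultipliers[[substance]] %||% 1
          noise <- stats::rlnorm(1, 0, config$doseNoiseSdlog)
          mass <- ddd_of[[substance]] * mean(w) * duration * n_treated *
            target_mult * noise
          quantity <- mass / conc_of[[substance]]
          event_rows[[ev_n]] <- tibble::tibble(
            eventId = sprintf("C%05d-%d", case_n, ai),
            herdId = h$herdId, month = month, indication = indication,
            productId = prod_of[[substance]], quantityUsed = quantity,
            quantityUnit = "mL", nAnimalsTreated = n_treated,
            weightsKg = paste(w, collapse = ";"),
            durationDays = duration, route = "PARENTERAL",
            administrator = administrator, adminsPerDay = 1L
          )
          truth_rows[[ev_n]] <- tibble::tibble(
            eventId = sprintf("C%05d-%d", case_n, ai),
            herdId = h$herdId, substance = substance,
            trueMassMg = mass,
            trueRatio = target_mult * noise,
            trueNAdd = mass / (ddd_of[[substance]] * mean(w))
          )
        }
      }
    }
    if (ev_n == 0) {
      amu_stop("no cases generated; increase caseRatePerAnimalYear or herd sizes")
    }
    events <- dplyr::bind_rows(event_rows)
    truth <- dplyr::bind_rows(truth_rows)

    unit_of <- stats::setNames(catalogue$products$unitSize,
                               catalogue$products$productId)
    dep <- events |>
      dplyr::group_by(.data$herdId, .data$month, .data$productId) |>
      dplyr::summarise(totalQty = sum(.data$quantityUsed), .groups = "drop") |>
      dplyr::mutate(
        unitSize = unit_of[.data$productId],
        emptiesCount = ceiling(.data$totalQty / .data$unitSize - 1e-9),
        leftover = .data$emptiesCount * .data$unitSize - .data$totalQty,
        partialUseNote = ifelse(
          .data$leftover > 1e-9,
          sprintf("leftover_mL=%.9g", .data$leftover), NA_character_)
      )
    keep <- stats::runif(nrow(dep)) < config$binCompliance
    deposits <- dep[keep, c("herdId", "month", "productId", "emptiesCount",
                            "partialUseNote")]
    ground_truth <- list(
      substanceMass = truth |>
        dplyr::group_by(.data$substance) |>
        dplyr::summarise(trueMassMg = sum(.data$trueMassMg), .groups = "drop"),
      eventTruth = truth,
      perHerdNAdd = truth |>
        dplyr::group_by(.data$herdId) |>
        dplyr::summarise(trueNAdd = sum(.data$trueNAdd), .groups = "drop"),
      indicationCounts = dplyr::bind_rows(case_rows) |>
        dplyr::count(.data$indication, name = "nCases")
    )
    list(events = events, deposits = deposits, groundTruth = ground_truth)
  })
}

#' Write a dataset as delimited-text files
#'
#' Emits the `products.csv` / `ddd.csv` / `cia_map.csv` / `herds.csv` /
#' `events.csv` / `bins.csv` dialects consumed by [load_catalogue()],
#' [read_herds()], [read_events()] and [read_bin_deposits()].
#'
#' @param dir output directory (created if needed).
#' @param catalogue an `amu_catalogue`.
#' @param herds,events,deposits data tibbles (`events` with either a
#'   serialized or list-column `weightsKg`).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(dir, catalogue, herds, events, deposits = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    products = file.path(dir, "products.csv"),
    ddd = file.path(dir, "ddd.csv"),
    cia_map = file.path(dir, "cia_map.csv"),
    substances = file.path(dir, "substances.csv"),
    herds = file.path(dir, "herds.csv"),
    events = file.path(dir, "events.csv"),
    bins = file.path(dir, "bins.csv")
  )
  prod_rows <- catalogue$components |>
    dplyr::left_join(catalogue$products, by = "productId") |>
    dplyr::select("productId", "tradeName", "formulation", "unitSize",
                  "substance", "concentration", "concentrationUnit", "role")
  readr::write_csv(prod_rows, paths["products"], progress = FALSE)
  readr::write_csv(
    dplyr::rename(catalogue$ddd, dddKg_mg_per_kg_day = "dddKg"),
    paths["ddd"], progress = FALSE)
  readr::write_csv(catalogue$cia_map, paths["cia_map"], progress = FALSE)
  readr::write_csv(catalogue$substances, paths["substances"], progress = FALSE)
  readr::write_csv(herds, paths["herds"], progress = FALSE)
  if (is.list(events$weightsKg)) {
    write_events(events, paths["events"])
  } else {
    readr::write_csv(events[, EVENT_COLUMNS], paths["events"], progress = FALSE)
  }
  if (is.null(deposits)) {
    deposits <- tibble::tibble(herdId = character(), month = integer(),
                               productId = character(),
                               emptiesCount = double(),
                               partialUseNote = character())
  }
  readr::write_csv(deposits, paths["bins"], progress = FALSE)
  invisible(paths)
}

# deterministic 38-herd registry for the reference dataset: 20 household
# (5-20 animals) + 18 commercial herds, 1010 animals, 519 cattle
reference_herds <- function() {
  hh_sizes <- 5 + (seq(0, 19) * 15) %/% 19   # 5..20, sum 241
  co_sizes <- c(rep(43, 13), rep(42, 5))     # sum 769
  sizes <- c(hh_sizes, co_sizes)
  stopifnot(sum(sizes) == 1010)
  n_cattle <- floor(sizes * 519 / 1010)
  short <- 519 - sum(n_cattle)
  # distribute the rounding residual over the largest herds
  ord <- order(-sizes)
  n_cattle[ord[seq_len(short)]] <- n_cattle[ord[seq_len(short)]] + 1L
  tibble::tibble(
    herdId = sprintf("F%02d", 1:38),
    herdType = c(rep("HOUSEHOLD", 20), rep("COMMERCIAL", 18)),
    nCattle = as.integer(n_cattle),
    nBuffalo = as.integer(sizes - n_cattle),
    enrolmentDays = 365L
  )
}

#' Deterministic reference dataset
#'
#' A fixed dataset whose pipeline outputs reproduce the published summary
#' surfaces of the modelled surveillance study: the product-administration
#' frequency table (265 administrations of 14 substances, by indication),
#' the overall herd-usage counts (38 herds), and per-substance summed nADD
#' and nUADD equal to the published dose-metric totals. Events are
#' constructed to carry the tabulated metric totals (single treated animal
#' at 400 kg, fractional durations), not to be raw-record realistic; the
#' stochastic generator provides raw-level realism instead.
#'
#' @return list: `catalogue`, `herds`, `events`, `deposits` (deposits are
#'   consistent with the events, so reconciliation matches everything).
#' @examples
#' fx <- reference_dataset()
#' nrow(fx$events) # 265 product administrations
#' @export
reference_dataset <- function() {
  catalogue <- default_catalogue()
  herds <- reference_herds()
  ref <- substance_reference()
  prod_of <- substance_products(catalogue)
  comp <- catalogue$components
  conc_of <- stats::setNames(
    concentration_mg(comp$concentration, comp$concentrationUnit,
                     catalogue$iu_per_mg),
    comp$productId
  )
  ddd_of <- stats::setNames(
    vapply(ref$substance, function(s) {
      lookup_ddd(catalogue, s, "BOVINE_ANY", "PARENTERAL")$dddKg
    }, numeric(1)),
    ref$substance
  )
  ind_cols <- c(MASTITIS = "mastitis", REPRODUCTIVE = "reproductive",
                FEVER = "fever", DIARRHEA = "diarrhea", MISC = "misc")
  admin_cycle <- c("PARA_VETERINARIAN", "UNAUTHORIZED", "FARMER",
                   "VETERINARIAN")
  w <- 400 # kg, the recorded cow weight used throughout the fixture

  rows <- list()
  for (j in seq_len(nrow(ref))) {
    s <- ref$substance[j]
    k <- sum(ref[j, ind_cols])
    indication <- rep(names(ind_cols), times = unlist(ref[j, ind_cols]))
    herd_pool <- sprintf("F%02d", ((3 * (j - 1) + seq_len(ref$nHerds[j]) - 1) %% 38) + 1)
    mass_mg <- ref$nAdd[j] / k * ddd_of[[s]] * w
    rows[[j]] <- tibble::tibble(
      substance = s,
      indication = indication,
      herdId = herd_pool[((seq_len(k) - 1) %% length(herd_pool)) + 1],
      month = ((seq_len(k) - 1) %% 12) + 1,
      productId = prod_of[[s]],
      quantityUsed = mass_mg / conc_of[[prod_of[[s]]]],
      quantityUnit = "mL",
      nAnimalsTreated = 1L,
      durationDays = ref$nUadd[j] / k,
      route = "PARENTERAL",
      administrator = admin_cycle[((seq_len(k) - 1) %% 4) + 1],
      adminsPerDay = 1L
    )
  }
  events <- dplyr::bind_rows(rows)
  # assign case-structured event ids per indication (208 cases over 265
  # administrations; repeat administrations cycle over the early cases)
  code <- c(MASTITIS = "MAS", FEVER = "FEV", REPRODUCTIVE = "REP",
            DIARRHEA = "DIA", MISC = "MSC")
  events <- events |>
    dplyr::group_by(.data$indication) |>
    dplyr::mutate(caseNum = ((dplyr::row_number() - 1) %%
                               CASE_COUNTS[[.data$indication[1]]]) + 1) |>
    dplyr::group_by(.data$indication, .data$caseNum) |>
    dplyr::mutate(eventId = sprintf("%s%03d-%d",
                                    code[[.data$indication[1]]],
                                    .data$caseNum, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select(-"caseNum")
  events$weightsKg <- rep(list(w), nrow(events))
  events <- events[, c("eventId", setdiff(EVENT_COLUMNS, "eventId"))]

  unit_of <- stats::setNames(catalogue$products$unitSize,
                             catalogue$products$productId)
  deposits <- events |>
    dplyr::group_by(.data$herdId, .data$month, .data$productId) |>
    dplyr::summarise(totalQty = sum(.data$quantityUsed), .groups = "drop") |>
    dplyr::mutate(
      unitSize = unit_of[.data$productId],
      emptiesCount = ceiling(.data$totalQty / .data$unitSize - 1e-9),
      leftover = .data$emptiesCount * .data$unitSize - .data$totalQty,
      partialUseNote = ifelse(.data$leftover > 1e-9,
                              sprintf("leftover_mL=%.9g", .data$leftover),
                              NA_character_)
    ) |>
    dplyr::select("herdId", "month", "productId", "emptiesCount",
                  "partialUseNote")
  list(catalogue = catalogue, herds = herds, events = events,
       deposits = deposits)
}
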