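# Dose-based AMU metrics: ADD, nADD, UDD, UADD, nUADD, ADUR, and the
# UDD/DDDkg dosing-adequacy classification. All computations are carried at
# full precision; rounding happens only in the reporting layer.

DOSING_CLASSES <- c("UNDER", "CORRECT", "OVER")

#' Metric configuration
#'
#' @param band dosing-adequacy band on the UDD/DDDkg ratio; edges inclusive
#'   (`CORRECT` within the band).
#' @param iuPerMg IU-to-mg conversion factor.
#' @param fallbackWeightsKg named vector of species median weights used when
#'   an event carries no recorded weights.
#' @param defaultSpecies species assumed for DDD lookup when events carry no
#'   species information.
#' @param adurDenominator `"herd"` (enrolmentDays x herd animal count) or
#'   `"pooled"` (study period x total animals).
#' @param reconcileTolerance relative mass tolerance for stream matching.
#' @return a list of options.
#' @export
metric_config <- function(band = c(0.8, 1.2), iuPerMg = 1598,
                          fallbackWeightsKg = c(CATTLE = 400, BUFFALO = 500),
                          defaultSpecies = "CATTLE",
                          adurDenominator = c("herd", "pooled"),
                          reconcileTolerance = 0.05) {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] > 0,
            reconcileTolerance >= 0)
  list(band = band, iuPerMg = iuPerMg, fallbackWeightsKg = fallbackWeightsKg,
       defaultSpecies = match.arg(toupper(defaultSpecies), SPECIES),
       adurDenominator = match.arg(adurDenominator),
       reconcileTolerance = reconcileTolerance)
}

#' Animal daily dose (ADD)
#'
#' The standard daily dose for one animal: the recommended daily dose DDDkg
#' (mg/kg/day) times the animal's weight, converted to grams per day.
#'
#' @param dddKg recommended daily dose, mg/kg/day.
#' @param weightKg animal weight at treatment, kg.
#' @return ADD in g/day.
#' @examples
#' animal_daily_dose(7.5, 500) # 3.75 g/day
#' @export
animal_daily_dose <- function(dddKg, weightKg) {
  if (any(dddKg <= 0) || any(weightKg <= 0)) {
    amu_stop("dddKg and weightKg must be > 0")
  }
  dddKg * weightKg / 1000
}

#' Intramammary animal daily dose
#'
#' Intramammary products are dosed per syringe, not per kg: the daily dose is
#' the product of the mass per dispensing unit, the units per administration,
#' and the administrations per day.
#'
#' @param mgPerUnit dose contained in one syringe/unit, mg.
#' @param unitsPerAdmin units used per administration.
#' @param adminsPerDay administrations per day.
#' @return ADD in mg/day.
#' @examples
#' intramammary_add(200, 1, 2) # 400 mg/day
#' @export
intramammary_add <- function(mgPerUnit, unitsPerAdmin, adminsPerDay) {
  if (any(mgPerUnit <= 0) || any(unitsPerAdmin <= 0) || any(adminsPerDay <= 0)) {
    amu_stop("intramammary dose factors must be > 0")
  }
  mgPerUnit * unitsPerAdmin * adminsPerDay
}

#' Number of animal daily doses (nADD)
#'
#' Administered mass divided by the standard daily dose; herd-level nADD is
#' the sum of event-level values.
#'
#' @param totalMassMg administered mass of the active substance, mg.
#' @param addGPerDay animal daily dose, g/day.
#' @return dimensionless dose count.
#' @export
n_add <- function(totalMassMg, addGPerDay) {
  if (any(addGPerDay <= 0)) amu_stop("ADD must be > 0")
  if (any(totalMassMg < 0)) amu_stop("mass must be >= 0")
  (totalMassMg / 1000) / addGPerDay
}

#' Used daily dose (UDD)
#'
#' The dose actually administered per kg and day: administered mass divided
#' by (animals treated x average weight x treatment days).
#'
#' @param totalMassMg administered mass, mg.
#' @param nTreated number of animals treated.
#' @param avgWeightKg average weight of the treated animals, kg.
#' @param durationDays treatment duration, days.
#' @return UDD in mg/kg/day.
#' @examples
#' used_daily_dose(7500, 1, 500, 2) # 7.5 mg/kg/day
#' @export
used_daily_dose <- function(totalMassMg, nTreated, avgWeightKg, durationDays) {
  if (any(nTreated <= 0) || any(avgWeightKg <= 0) || any(durationDays <= 0)) {
    amu_stop("UDD denominator factors must be > 0")
  }
  totalMassMg / (nTreated * avgWeightKg * durationDays)
}

#' Number of used animal daily doses (nUADD)
#'
#' Administered mass divided by the used animal daily dose (UADD = UDD x
#' weight). For an event computed end-to-end this equals animals x days.
#'
#' @param totalMassMg administered mass, mg.
#' @param uddMgPerKgDay used daily dose, mg/kg/day.
#' @param weightKg average animal weight, kg.
#' @return dimensionless dose count.
#' @export
n_uadd <- function(totalMassMg, uddMgPerKgDay, weightKg) {
  if (any(uddMgPerKgDay * weightKg <= 0)) amu_stop("UADD must be > 0")
  totalMassMg / (uddMgPerKgDay * weightKg)
}

#' Antimicrobial drug use rate (ADUR)
#'
#' nADD normalized to 1000 animal-days at risk:
#' `mass_g * 1000 / (ADD * periodDays * nAnimalsAtRisk)`.
#'
#' @param totalMassG administered mass over the period, g.
#' @param addGPerDay animal daily dose, g/day.
#' @param periodDays days in the observation period.
#' @param nAnimalsAtRisk animals under observation.
#' @return ADD per 1000 animal-days.
#' @export
adur <- function(totalMassG, addGPerDay, periodDays, nAnimalsAtRisk) {
  if (any(addGPerDay <= 0) || any(periodDays <= 0) || any(nAnimalsAtRisk <= 0)) {
    amu_stop("ADUR denominator factors must be > 0")
  }
  totalMassG * 1000 / (addGPerDay * periodDays * nAnimalsAtRisk)
}

#' Dosing-adequacy classification
#'
#' The UDD/DDDkg ratio indexes how far the administered dose deviates from
#' the recommendation: below the band is under-dosing, above is over-dosing,
#' inside (edges inclusive) is correct dosing.
#'
#' @param uddMgPerKgDay used daily dose, mg/kg/day.
#' @param dddKg recommended daily dose, mg/kg/day.
#' @param band classification band, default `c(0.8, 1.2)`.
#' @return tibble with `doseRatio` and `dosingClass`
#'   (`UNDER`/`CORRECT`/`OVER`).
#' @examples
#' dosing_classification(5.0, 5.26) # ratio 0.95, CORRECT
#' @export
dosing_classification <- function(uddMgPerKgDay, dddKg, band = c(0.8, 1.2)) {
  if (any(dddKg <= 0)) amu_stop("dddKg must be > 0")
  ratio <- uddMgPerKgDay / dddKg
  tibble::tibble(
    doseRatio = ratio,
    dosingClass = classify_ratio(ratio, band)
  )
}

classify_ratio <- function(ratio, band) {
  dplyr::case_when(
    ratio < band[1] ~ "UNDER",
    ratio > band[2] ~ "OVER",
    TRUE ~ "CORRECT"
  )
}

# mean recorded weight of an event, or the configured species fallback
event_weight <- function(weights, config) {
  if (length(weights) > 0) return(mean(weights))
  fb <- config$fallbackWeightsKg[[config$defaultSpecies]] %||%
    config$fallbackWeightsKg[[1]]
  fb
}

#' Compute dose metrics for every treatment event
#'
#' Orchestrates, per event: product resolution into the dose-determining
#' substance mass, ADD (weight-based for parenteral/oral routes, syringe
#' based for intramammary), nADD, UDD, UADD, nUADD, and the dosing
#' classification. Calculations are per observation; herd- or study-level
#' totals are sums over events.
#'
#' @param events events tibble (see [read_events()]).
#' @param catalogue an `amu_catalogue`.
#' @param config a [metric_config()].
#' @return tibble, one row per event, carrying identifiers (`eventId`,
#'   `herdId`, `month`, `indication`, `route`, `administrator`), the
#'   substance and its class/WHO category, and all metric fields at full
#'   precision.
#' @export
compute_event_metrics <- function(events, catalogue,
                                  config = metric_config()) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      eventId = character(), herdId = character(), month = integer(),
      indication = character(), route = character(),
      administrator = character(), substance = character(),
      amClass = character(), whoCategory = character(), totalMassMg = double(),
      addGPerDay = double(), nAdd = double(), uddMgPerKgDay = double(),
      uaddMgPerDay = double(), nUadd = double(), doseRatio = double(),
      dosingClass = character()
    ))
  }
  if (!is.list(events$weightsKg)) {
    events$weightsKg <- parse_weights(events$weightsKg)
  }
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    tryCatch(event_metrics_one(ev, catalogue, config),
             error = function(e) {
               amu_stop("event ", ev$eventId, ": ", conditionMessage(e))
             })
  })
  dplyr::bind_rows(rows)
}

event_metrics_one <- function(ev, catalogue, config) {
  dd <- resolve_dose_determining(catalogue, ev$productId)
  masses <- total_active_mass(catalogue, ev$productId, ev$quantityUsed)
  mass <- masses$massMg[masses$role == "DOSE_DETERMINING"]
  w <- event_weight(ev$weightsKg[[1]], config)
  route <- ev$route

  if (route == "INTRAMAMMARY") {
    if (dd$concentrationUnit != "mg/unit") {
      amu_stop("intramammary product ", ev$productId,
               " must be denominated in mg/unit")
    }
    units_per_admin <- ev$quantityUsed /
      (ev$nAnimalsTreated * ev$durationDays * ev$adminsPerDay)
    add_mg <- intramammary_add(dd$concentration, units_per_admin,
                               ev$adminsPerDay)
    add_g <- add_mg / 1000
    ddk <- NA_real_
  } else {
    ddk <- lookup_ddd(catalogue, dd$substance, config$defaultSpecies,
                      route)$dddKg
    add_g <- animal_daily_dose(ddk, w)
    add_mg <- add_g * 1000
  }

  udd <- if (mass > 0) {
    used_daily_dose(mass, ev$nAnimalsTreated, w, ev$durationDays)
  } else 0
  uadd <- udd * w
  nuadd <- if (mass > 0) n_uadd(mass, udd, w) else 0
  # for weight-dosed routes the ratio is UDD/DDDkg; intramammary products are
  # unit-dosed, so the used daily amount is compared to the standard daily
  # amount directly (UADD/ADD), the same quantity when weights are shared
  ratio <- if (route == "INTRAMAMMARY") uadd / add_mg else udd / ddk

  tibble::tibble(
    eventId = ev$eventId, herdId = ev$herdId, month = ev$month,
    indication = ev$indication, route = route,
    administrator = ev$administrator,
    substance = dd$substance,
    amClass = substance_class(catalogue, dd$substance),
    whoCategory = who_category(catalogue, dd$substance),
    totalMassMg = mass,
    addGPerDay = add_g,
    nAdd = n_add(mass, add_g),
    uddMgPerKgDay = udd,
    uaddMgPerDay = uadd,
    nUadd = nuadd,
    doseRatio = ratio,
    dosingClass = classify_ratio(ratio, config$band)
  )
}

#' Write / read the per-event metrics table
#'
#' Deterministic column order, full-precision floats.
#'
#' @param metrics metrics tibble from [compute_event_metrics()].
#' @param path output path.
#' @return `path` invisibly (writer); metrics tibble (reader).
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  m <- read_schema_csv(
    path,
    c("eventId", "herdId", "month", "indication", "route", "administrator",
      "substance", "amClass", "whoCategory", "totalMassMg", "addGPerDay",
      "nAdd", "uddMgPerKgDay", "uaddMgPerDay", "nUadd", "doseRatio",
      "dosingClass"),
    readr::cols(
      eventId = "c", herdId = "c", month = "i", indication = "c",
      route = "c", administrator = "c", substance = "c", amClass = "c",
      whoCategory = "c", totalMassMg = "d", addGPerDay = "d", nAdd = "d",
      uddMgPerKgDay = "d", uaddMgPerDay = "d", nUadd = "d", doseRatio = "d",
      dosingClass = "c"
    )
  )
  m
}

#' Herd-period ADUR table
#'
#' Aggregates per-substance ADUR. With `denominator = "herd"` each herd's
#' animal-days are its enrolment days times its animal count and the median
#' and mean across herds are reported; with `"pooled"` a single study-wide
#' denominator (period x total animals) is used.
#'
#' @param metrics metrics tibble.
#' @param herds herd registry tibble.
#' @param periodDays study period for the pooled denominator (default 365).
#' @param denominator `"herd"` or `"pooled"`.
#' @return tibble per substance with total mass, nADD and ADUR columns.
#' @export
adur_table <- function(metrics, herds, periodDays = 365,
                       denominator = c("herd", "pooled")) {
  denominator <- match.arg(denominator)
  if (denominator == "pooled") {
    n_animals <- sum(herds$nCattle + herds$nBuffalo)
    metrics |>
      dplyr::group_by(.data$substance) |>
      dplyr::summarise(
        nAdd = sum(.data$nAdd),
        totalMassG = sum(.data$totalMassMg) / 1000,
        medianAddGPerDay = stats::median(.data$addGPerDay),
        adur = 1000 * sum(.data$nAdd) / (periodDays * n_animals),
        .groups = "drop"
      )
  } else {
    per_herd <- metrics |>
      dplyr::left_join(
        herds |> dplyr::mutate(animalDays = .data$enrolmentDays *
                                 (.data$nCattle + .data$nBuffalo)) |>
          dplyr::select("herdId", "animalDays"),
        by = "herdId"
      ) |>
      dplyr::group_by(.data$substance, .data$herdId) |>
      dplyr::summarise(nAdd = sum(.data$nAdd),
                       totalMassG = sum(.data$totalMassMg) / 1000,
                       adur = 1000 * sum(.data$nAdd) / .data$animalDays[1],
                       .groups = "drop")
    per_herd |>
      dplyr::group_by(.data$substance) |>
      dplyr::summarise(
        nAdd = sum(.data$nAdd),
        totalMassG = sum(.data$totalMassG),
        medianAdur = stats::median(.data$adur),
        meanAdur = mean(.data$adur),
        .groups = "drop"
      )
  }
}
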