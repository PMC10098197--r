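# Treatment-event and bin-deposit record schemas, validation, and
# reconciliation of the two data streams (treatment history vs. the contents
# of the on-farm empty-container bins).

HERD_TYPES <- c("HOUSEHOLD", "COMMERCIAL")
INDICATIONS <- c("MASTITIS", "FEVER", "REPRODUCTIVE", "DIARRHEA", "MISC")
ADMINISTRATORS <- c("VETERINARIAN", "PARA_VETERINARIAN", "UNAUTHORIZED",
                    "FARMER")

EVENT_COLUMNS <- c("eventId", "herdId", "month", "indication", "productId",
                   "quantityUsed", "quantityUnit", "nAnimalsTreated",
                   "weightsKg", "durationDays", "route", "administrator",
                   "adminsPerDay")

#' Read the herd registry
#'
#' Enforces the enrolment definition: household herds hold 5-20 adult
#' bovines, commercial herds more than 20; `enrolmentDays` must be positive
#' (at most a year of observation).
#'
#' @param path path to `herds.csv` (herdId, herdType, nCattle, nBuffalo,
#'   enrolmentDays).
#' @return tibble of herds.
#' @export
read_herds <- function(path) {
  h <- read_schema_csv(
    path, c("herdId", "herdType", "nCattle", "nBuffalo", "enrolmentDays"),
    readr::cols(herdId = "c", herdType = "c", nCattle = "i", nBuffalo = "i",
                enrolmentDays = "i")
  )
  h$herdType <- match_enum(h$herdType, HERD_TYPES, "herdType")
  validate_herds(h)
  h
}

validate_herds <- function(h) {
  n <- h$nCattle + h$nBuffalo
  bad_hh <- h$herdType == "HOUSEHOLD" & (n < 5 | n > 20)
  bad_co <- h$herdType == "COMMERCIAL" & n <= 20
  if (any(bad_hh)) {
    amu_stop("household herds must hold 5-20 animals: ",
             paste(h$herdId[bad_hh], collapse = ", "))
  }
  if (any(bad_co)) {
    amu_stop("commercial herds must hold more than 20 animals: ",
             paste(h$herdId[bad_co], collapse = ", "))
  }
  if (any(h$enrolmentDays <= 0 | h$enrolmentDays > 366)) {
    amu_stop("enrolmentDays must be in 1-366")
  }
  invisible(h)
}

parse_weights <- function(x) {
  lapply(x, function(w) {
    if (is.na(w) || !nzchar(trimws(w))) return(numeric(0))
    as.numeric(strsplit(w, ";", fixed = TRUE)[[1]])
  })
}

#' Read treatment events
#'
#' Parses and validates `events.csv`. Invalid rows are dropped from the
#' returned tibble and collected (with row numbers and messages) in the
#' `"errors"` attribute; a warning summarises how many were rejected.
#'
#' @param path path to `events.csv`.
#' @return tibble of valid events; `weightsKg` is a list-column of numeric
#'   vectors (empty vector = no recorded weights, species fallback applies
#'   downstream).
#' @export
read_events <- function(path) {
  raw <- read_schema_csv(
    path, EVENT_COLUMNS,
    readr::cols(
      eventId = "c", herdId = "c", month = "i", indication = "c",
      productId = "c", quantityUsed = "d", quantityUnit = "c",
      nAnimalsTreated = "i", weightsKg = "c", durationDays = "d",
      route = "c", administrator = "c", adminsPerDay = "i"
    )
  )
  if (nrow(raw) == 0) {
    amu_warn("no event rows in ", path)
    raw$weightsKg <- list()
    return(raw)
  }
  msgs <- character(nrow(raw))
  add_err <- function(i, msg) {
    msgs[i] <<- ifelse(nzchar(msgs[i]), paste(msgs[i], msg, sep = "; "), msg)
  }
  chk_enum <- function(col, levels, field) {
    bad <- which(!toupper(trimws(raw[[col]])) %in% levels)
    if (length(bad)) add_err(bad, paste0("unknown ", field))
  }
  chk_enum("indication", INDICATIONS, "indication")
  chk_enum("route", FORMULATIONS, "route")
  chk_enum("administrator", ADMINISTRATORS, "administrator")
  add_err(which(is.na(raw$durationDays) | raw$durationDays <= 0),
          "durationDays must be > 0")
  add_err(which(is.na(raw$quantityUsed) | raw$quantityUsed <= 0),
          "quantityUsed must be > 0")
  add_err(which(is.na(raw$nAnimalsTreated) | raw$nAnimalsTreated < 1),
          "nAnimalsTreated must be >= 1")
  add_err(which(is.na(raw$month) | raw$month < 1 | raw$month > 12),
          "month must be in 1-12")
  add_err(which(is.na(raw$adminsPerDay) | raw$adminsPerDay < 1),
          "adminsPerDay must be >= 1")
  weights <- parse_weights(raw$weightsKg)
  nw <- lengths(weights)
  add_err(which(nw != 0 & nw != raw$nAnimalsTreated),
          "weightsKg must be empty or one weight per treated animal")
  add_err(which(vapply(weights, function(w) any(!is.finite(w) | w <= 0),
                       logical(1))),
          "weights must be positive")
  bad <- which(nzchar(msgs))
  errors <- tibble::tibble(row = bad, eventId = raw$eventId[bad],
                           message = msgs[bad])
  if (length(bad)) {
    amu_warn(length(bad), " invalid event row(s) rejected; see attr(x, 'errors')")
  }
  out <- raw[setdiff(seq_len(nrow(raw)), bad), ]
  w <- weights[setdiff(seq_len(nrow(raw)), bad)]
  out$indication <- toupper(trimws(out$indication))
  out$route <- toupper(trimws(out$route))
  out$administrator <- toupper(trimws(out$administrator))
  out$weightsKg <- w
  # plausibility warnings only: adult bovine weight ranges
  flat <- unlist(w)
  if (length(flat) && any(flat < 300 | flat > 650)) {
    amu_warn("some recorded weights fall outside the adult bovine range (300-650 kg)")
  }
  attr(out, "errors") <- errors
  out
}

#' Write treatment events
#'
#' Inverse of [read_events()]: the weights list-column is serialized as a
#' semicolon-joined string.
#'
#' @param events events tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  out$weightsKg <- vapply(events$weightsKg, paste, character(1), collapse = ";")
  readr::write_csv(out[, EVENT_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Read bin deposits
#'
#' A deposit row with `emptiesCount = 0` and a `partialUseNote` is accepted:
#' it models the treatment prescription requested when a container was only
#' partially used.
#'
#' @param path path to `bins.csv` (herdId, month, productId, emptiesCount,
#'   partialUseNote).
#' @return tibble of deposits.
#' @export
read_bin_deposits <- function(path) {
  b <- read_schema_csv(
    path, c("herdId", "month", "productId", "emptiesCount", "partialUseNote"),
    readr::cols(herdId = "c", month = "i", productId = "c",
                emptiesCount = "d", partialUseNote = "c")
  )
  if (any(is.na(b$month) | b$month < 1 | b$month > 12)) {
    amu_stop("bin deposit month must be in 1-12 (row ",
             paste(which(is.na(b$month) | b$month < 1 | b$month > 12),
                   collapse = ", "), ")")
  }
  if (any(is.na(b$emptiesCount) | b$emptiesCount < 0)) {
    amu_stop("emptiesCount must be >= 0 (row ",
             paste(which(is.na(b$emptiesCount) | b$emptiesCount < 0),
                   collapse = ", "), ")")
  }
  b
}

# mass (mg of dose-determining substance) implied by a bin deposit group;
# a machine-readable partialUseNote "leftover_mL=x" subtracts the unused
# remainder of the last container (the prescription stand-in)
bin_implied_mass <- function(emptiesCount, unitSize, concMg, partialUseNote) {
  leftover <- rep(0, length(partialUseNote))
  hit <- grepl("leftover_mL=", partialUseNote %||% "")
  hit[is.na(hit)] <- FALSE
  leftover[hit] <- as.numeric(sub(".*leftover_mL=([0-9.eE+-]+).*", "\\1",
                                  partialUseNote[hit]))
  pmax(emptiesCount * unitSize - leftover, 0) * concMg
}

#' Reconcile treatment history with bin contents
#'
#' Both streams are reduced, per herd x month x product, to the implied mass
#' of the dose-determining substance: `emptiesCount * unitSize *
#' concentration` for the bin stream (less any leftover recorded in the
#' partial-use note) and `sum(quantityUsed) * concentration` for the history
#' stream. Groups agreeing within `tolerance` (relative) are matched;
#' discrepancies are data, not errors.
#'
#' @param events events tibble (see [read_events()]).
#' @param deposits deposits tibble (see [read_bin_deposits()]).
#' @param catalogue an `amu_catalogue`.
#' @param tolerance relative mass tolerance for a match (default 0.05).
#' @return an `amu_reconciliation` list: `matched`, `historyOnly` (event
#'   counts), `binOnly` (herd x month x product groups with bin evidence but
#'   no history), `massDiscrepancyMg` per product, and a per-group `detail`
#'   tibble.
#' @export
reconcile <- function(events, deposits, catalogue, tolerance = 0.05) {
  stopifnot(tolerance >= 0)
  dd <- lapply(unique(c(events$productId, deposits$productId)), function(p) {
    cmp <- resolve_dose_determining(catalogue, p)
    tibble::tibble(
      productId = p,
      concMg = concentration_mg(cmp$concentration, cmp$concentrationUnit,
                                catalogue$iu_per_mg),
      unitSize = catalogue_product(catalogue, p)$unitSize
    )
  }) |> dplyr::bind_rows()

  hist <- events |>
    dplyr::left_join(dd, by = "productId") |>
    dplyr::group_by(.data$herdId, .data$month, .data$productId) |>
    dplyr::summarise(nEvents = dplyr::n(),
                     historyMassMg = sum(.data$quantityUsed * .data$concMg),
                     .groups = "drop")
  bin <- deposits |>
    dplyr::left_join(dd, by = "productId") |>
    dplyr::group_by(.data$herdId, .data$month, .data$productId) |>
    dplyr::summarise(
      binMassMg = sum(bin_implied_mass(.data$emptiesCount, .data$unitSize,
                                       .data$concMg, .data$partialUseNote)),
      hasDeposit = TRUE, .groups = "drop")

  detail <- dplyr::full_join(hist, bin,
                             by = c("herdId", "month", "productId")) |>
    dplyr::mutate(
      nEvents = dplyr::coalesce(.data$nEvents, 0L),
      historyMassMg = dplyr::coalesce(.data$historyMassMg, 0),
      binMassMg = dplyr::coalesce(.data$binMassMg, 0),
      hasDeposit = dplyr::coalesce(.data$hasDeposit, FALSE),
      discrepancyMg = abs(.data$binMassMg - .data$historyMassMg),
      status = dplyr::case_when(
        nEvents > 0 & hasDeposit &
          discrepancyMg <= tolerance * pmax(historyMassMg, binMassMg) ~ "MATCHED",
        nEvents > 0 ~ "HISTORY_ONLY",
        TRUE ~ "BIN_ONLY"
      )
    )

  res <- structure(list(
    matched = sum(detail$nEvents[detail$status == "MATCHED"]),
    historyOnly = sum(detail$nEvents[detail$status == "HISTORY_ONLY"]),
    binOnly = sum(detail$status == "BIN_ONLY"),
    massDiscrepancyMg = detail |>
      dplyr::group_by(.data$productId) |>
      dplyr::summarise(discrepancyMg = sum(.data$discrepancyMg),
                       .groups = "drop"),
    tolerance = tolerance,
    detail = detail
  ), class = "amu_reconciliation")
  res
}

#' @export
print.amu_reconciliation <- function(x, ...) {
  cat("<amu_reconciliation>\n")
  cat("  events matched by bin contents:", x$matched, "\n")
  cat("  events without bin corroboration:", x$historyOnly, "\n")
  cat("  bin-only groups (candidate unrecorded use):", x$binOnly, "\n")
  cat("  total mass discrepancy (mg):",
      format(sum(x$massDiscrepancyMg$discrepancyMg)), "\n")
  invisible(x)
}
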