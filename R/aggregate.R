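# Reporting surfaces: product-frequency and herd-usage tables, nADD/nUADD
# shares, WHO critical-importance summaries, condition case mix, and the
# household-vs-commercial comparison. Percentages are rounded half-up to two
# decimals here and only here; upstream metrics carry full precision.

# dose-determining substance (+ class, WHO category) per event
event_substances <- function(events, catalogue) {
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, substance = character(0),
                         amClass = character(0), whoCategory = character(0)))
  }
  map <- lapply(unique(events$productId), function(p) {
    dd <- resolve_dose_determining(catalogue, p)
    tibble::tibble(productId = p, substance = dd$substance)
  }) |> dplyr::bind_rows()
  events |>
    dplyr::left_join(map, by = "productId") |>
    dplyr::mutate(
      amClass = substance_class(catalogue, .data$substance),
      whoCategory = who_category(catalogue, .data$substance)
    )
}

pct <- function(n, total) round_half_up(100 * n / total, 2)

#' Product-administration frequency table
#'
#' Counts product administrations (one event = one administered product) per
#' dose-determining substance, overall and by indication. Percentages are
#' taken against the respective column total.
#'
#' @param events events tibble.
#' @param catalogue an `amu_catalogue`.
#' @return tibble with one row per substance: `nProducts`, `pctProducts`,
#'   and `n`/`pct` pairs per indication; column totals in the
#'   `"totals"` attribute.
#' @export
product_frequency_table <- function(events, catalogue) {
  if (nrow(events) == 0) {
    return(tibble::tibble(substance = character(), amClass = character(),
                          nProducts = integer(), pctProducts = double()))
  }
  ev <- event_substances(events, catalogue)
  overall <- ev |>
    dplyr::count(.data$substance, .data$amClass, name = "nProducts")
  by_ind <- ev |>
    dplyr::count(.data$substance, .data$indication) |>
    tidyr::pivot_wider(names_from = "indication", values_from = "n",
                       values_fill = 0L, names_prefix = "n")
  tot <- nrow(ev)
  ind_tot <- ev |> dplyr::count(.data$indication)
  out <- overall |>
    dplyr::left_join(by_ind, by = "substance") |>
    dplyr::mutate(pctProducts = pct(.data$nProducts, tot),
                  .after = "nProducts")
  for (ind in INDICATIONS) {
    ncol_ <- paste0("n", ind)
    if (!ncol_ %in% names(out)) out[[ncol_]] <- 0L
    coltot <- ind_tot$n[ind_tot$indication == ind]
    out[[paste0("pct", ind)]] <-
      if (length(coltot) && coltot > 0) pct(out[[ncol_]], coltot) else NA_real_
  }
  out <- out[order(-out$nProducts, out$substance), ]
  attr(out, "totals") <- c(stats::setNames(tot, "overall"),
                           stats::setNames(ind_tot$n, ind_tot$indication))
  out
}

#' Herd-usage table
#'
#' A herd counts once per substance regardless of how often it administered
#' it; percentages are against the number of enrolled herds.
#'
#' @param events events tibble.
#' @param herds herd registry tibble.
#' @param catalogue an `amu_catalogue`.
#' @return tibble per substance: `nHerds`, `pctHerds`, and per-indication
#'   herd counts.
#' @export
herd_usage_table <- function(events, herds, catalogue) {
  unknown <- setdiff(events$herdId, herds$herdId)
  if (length(unknown)) {
    amu_stop("events reference unknown herds: ", paste(unknown, collapse = ", "))
  }
  ev <- event_substances(events, catalogue)
  n_herds <- nrow(herds)
  overall <- ev |>
    dplyr::distinct(.data$substance, .data$amClass, .data$herdId) |>
    dplyr::count(.data$substance, .data$amClass, name = "nHerds")
  by_ind <- ev |>
    dplyr::distinct(.data$substance, .data$indication, .data$herdId) |>
    dplyr::count(.data$substance, .data$indication) |>
    tidyr::pivot_wider(names_from = "indication", values_from = "n",
                       values_fill = 0L, names_prefix = "nHerds")
  out <- overall |>
    dplyr::left_join(by_ind, by = "substance") |>
    dplyr::mutate(pctHerds = pct(.data$nHerds, n_herds), .after = "nHerds")
  out[order(-out$nHerds, out$substance), ]
}

#' Shares of total nADD or nUADD
#'
#' Group sums of a dose-count metric divided by the grand total, as
#' percentages.
#'
#' @param metrics metrics tibble from [compute_event_metrics()].
#' @param groupBy `"substance"`, `"amClass"` or `"whoCategory"`.
#' @param metric `"nAdd"` or `"nUadd"`.
#' @return tibble: grouping key, summed `value`, `pctOfTotal` (half-up, 2
#'   decimals).
#' @export
share_of_total <- function(metrics,
                           groupBy = c("substance", "amClass", "whoCategory"),
                           metric = c("nAdd", "nUadd")) {
  groupBy <- match.arg(groupBy)
  metric <- match.arg(metric)
  total <- sum(metrics[[metric]])
  if (!is.finite(total) || total <= 0) amu_stop("zero grand total for ", metric)
  metrics |>
    dplyr::group_by(groupingKey = .data[[groupBy]]) |>
    dplyr::summarise(value = sum(.data[[metric]]), .groups = "drop") |>
    dplyr::mutate(metric = metric,
                  pctOfTotal = pct(.data$value, total)) |>
    dplyr::arrange(dplyr::desc(.data$value))
}

#' WHO critical-importance summary of administered products
#'
#' Product counts and percentages per WHO category, overall and per
#' indication. The critically-important (CIA) total is the HPCIA plus
#' high-priority-CIA count.
#'
#' @param events events tibble.
#' @param catalogue an `amu_catalogue`.
#' @return list with `byCategory` (tibble; overall and per-indication counts
#'   and percents), `ciaProducts`, `ciaPct`, `totalProducts`.
#' @export
cia_summary <- function(events, catalogue) {
  ev <- event_substances(events, catalogue)
  tot <- nrow(ev)
  by_cat <- ev |>
    dplyr::count(whoCategory = factor(.data$whoCategory,
                                      levels = WHO_CATEGORIES)) |>
    tidyr::complete(.data$whoCategory, fill = list(n = 0L)) |>
    dplyr::mutate(whoCategory = as.character(.data$whoCategory),
                  pctOfProducts = if (tot > 0) pct(.data$n, tot) else NA_real_)
  ind_tot <- ev |> dplyr::count(.data$indication, name = "total")
  by_ind <- ev |>
    dplyr::count(.data$whoCategory, .data$indication) |>
    dplyr::left_join(ind_tot, by = "indication") |>
    dplyr::mutate(pctInd = pct(.data$n, .data$total))
  for (ind in intersect(INDICATIONS, unique(by_ind$indication))) {
    sub <- by_ind[by_ind$indication == ind, ]
    by_cat[[paste0("n", ind)]] <-
      sub$n[match(by_cat$whoCategory, sub$whoCategory)] |>
      dplyr::coalesce(0L)
    by_cat[[paste0("pct", ind)]] <-
      sub$pctInd[match(by_cat$whoCategory, sub$whoCategory)] |>
      dplyr::coalesce(0)
  }
  n_cia <- sum(by_cat$n[by_cat$whoCategory %in%
                          c("HPCIA", "HIGH_PRIORITY_CIA")])
  list(
    byCategory = by_cat,
    ciaProducts = n_cia,
    ciaPct = if (tot > 0) pct(n_cia, tot) else NA_real_,
    totalProducts = tot
  )
}

# caseId = eventId prefix before the final "-" (administrations of the same
# disease case share the prefix); events without a "-" are their own case
case_ids <- function(eventId) {
  ifelse(grepl("-", eventId), sub("-[^-]*$", "", eventId), eventId)
}

#' Condition case summary
#'
#' Groups treatment events into disease cases via the eventId prefix and
#' reports case counts and percentages per indication. A case may involve
#' several product administrations; cases, not administrations, are counted.
#'
#' @param events events tibble.
#' @return tibble: `indication`, `nCases`, `pctCases`.
#' @export
condition_case_summary <- function(events) {
  if (nrow(events) == 0) {
    return(tibble::tibble(indication = character(), nCases = integer(),
                          pctCases = double()))
  }
  cases <- events |>
    dplyr::mutate(caseId = case_ids(.data$eventId)) |>
    dplyr::distinct(.data$caseId, .data$indication)
  tot <- nrow(cases)
  cases |>
    dplyr::count(.data$indication, name = "nCases") |>
    dplyr::mutate(pctCases = pct(.data$nCases, tot)) |>
    dplyr::arrange(dplyr::desc(.data$nCases))
}

#' Household vs commercial usage comparison
#'
#' Splits per-herd total nADD by herd type (herds without any recorded
#' administration contribute zero) and reports a Welch two-sample t test
#' alongside per-type, per-substance totals.
#'
#' @param metrics metrics tibble.
#' @param herds herd registry tibble.
#' @return list: `perHerd` (herdId, herdType, nAdd), `byType` summary tibble,
#'   `test` (the `htest`), `perSubstance` per-type substance totals.
#' @export
herd_type_comparison <- function(metrics, herds) {
  per_herd <- herds |>
    dplyr::select("herdId", "herdType") |>
    dplyr::left_join(
      metrics |>
        dplyr::group_by(.data$herdId) |>
        dplyr::summarise(nAdd = sum(.data$nAdd), .groups = "drop"),
      by = "herdId"
    ) |>
    dplyr::mutate(nAdd = dplyr::coalesce(.data$nAdd, 0))
  counts <- table(per_herd$herdType)
  if (length(counts) < 2 || any(counts[HERD_TYPES] < 2) ||
      anyNA(counts[HERD_TYPES])) {
    amu_stop("herd-type comparison needs at least 2 herds of each type")
  }
  x <- per_herd$nAdd[per_herd$herdType == "HOUSEHOLD"]
  y <- per_herd$nAdd[per_herd$herdType == "COMMERCIAL"]
  test <- if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    # degenerate: identical constant samples; statistic is 0 by definition
    structure(list(statistic = c(t = 0), p.value = 1,
                   method = "Welch Two Sample t-test (degenerate)",
                   estimate = c(mean_household = mean(x),
                                mean_commercial = mean(y))),
              class = "htest")
  } else {
    stats::t.test(x, y)
  }
  by_type <- per_herd |>
    dplyr::group_by(.data$herdType) |>
    dplyr::summarise(nHerds = dplyr::n(), totalNAdd = sum(.data$nAdd),
                     meanNAdd = mean(.data$nAdd),
                     medianNAdd = stats::median(.data$nAdd), .groups = "drop")
  per_sub <- metrics |>
    dplyr::left_join(dplyr::select(herds, "herdId", "herdType"),
                     by = "herdId") |>
    dplyr::group_by(.data$herdType, .data$substance) |>
    dplyr::summarise(nAdd = sum(.data$nAdd), .groups = "drop")
  list(perHerd = per_herd, byType = by_type, test = test,
       perSubstance = per_sub)
}

#' Plot shares of total usage
#'
#' Bar chart companion to [share_of_total()]; requires ggplot2.
#'
#' @param shares output of [share_of_total()].
#' @return a ggplot object.
#' @export
plot_share_of_total <- function(shares) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    amu_stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = stats::reorder(.data$groupingKey,
                                                  .data$pctOfTotal),
                               y = .data$pctOfTotal)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("% of total ", shares$metric[1]))
}
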