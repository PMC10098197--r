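#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median optim qbeta rbinom rlnorm rpois runif setNames t.test
#' @importFrom utils packageVersion
NULL

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published surveillance tables are
#' conventionally rounded half-up, so reported percentages use this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a consistent prefix; all user-facing validation errors funnel here
amu_stop <- function(..., class = "bovamu_error") {
  rlang::abort(paste0(...), class = class)
}

amu_warn <- function(...) {
  rlang::warn(paste0(...), class = "bovamu_warning")
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

match_enum <- function(x, levels, field, row = NULL) {
  x <- toupper(trimws(x))
  bad <- !x %in% levels
  if (any(bad)) {
    amu_stop(
      field, " must be one of ", paste(levels, collapse = ", "),
      "; got ", paste(unique(x[bad]), collapse = ", "),
      if (!is.null(row)) paste0(" (row ", paste(row[bad], collapse = ", "), ")")
    )
  }
  x
}

#' @keywords internal
"_PACKAGE"
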