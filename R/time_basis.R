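#' Time and weight basis constants
#'
#' The model expresses every cost per *weekly batch*. Inputs entered on a
#' monthly basis (salaries, utilities, fuel, consumer goods) are divided by
#' `omega`, the average number of weeks in a month of a 365-day year, stored
#' as the literal 4.345. Inputs entered on an annual basis (depreciation,
#' maintenance, taxes, capital and land remuneration, culling) are divided by
#' `phi`, the number of weeks in a 365-day year, 365/7. Market-hog prices are
#' commonly quoted per arroba, a Brazilian livestock weight unit of 18.75 kg.
#'
#' `omega` is deliberately the printed constant 4.345 rather than the exact
#' (365/7)/12 = 4.3452...; the two differ in the fourth decimal and the model
#' follows the convention used in Brazilian farm budgeting.
#'
#' @return A list of class `time_basis` with elements `omega` (weeks/month,
#'   4.345), `phi` (weeks/year, 365/7) and `arroba_kg` (kg per arroba, 18.75).
#' @examples
#' tb <- time_basis()
#' 1000 / tb$omega  # weekly cost of a 1000/month expense
#' 365 / tb$phi     # weekly cost of a 365/year expense (= 7)
#' @export
time_basis <- function() {
  structure(
    list(omega = 4.345, phi = 365 / 7, arroba_kg = 18.75),
    class = "time_basis"
  )
}

#' @export
print.time_basis <- function(x, ...) {
  cat("Time basis: omega =", x$omega, "weeks/month; phi = 365/7 =",
      format(x$phi, digits = 10), "weeks/year; arroba =", x$arroba_kg, "kg\n")
  invisible(x)
}
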