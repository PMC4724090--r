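#' Fractionation scheme
#'
#' Total prescribed dose, number of fractions and dose per fraction. Exactly
#' two of the three determine the third; supply total dose and fraction
#' count. The bundled study scheme is 60 Gy in 5 fractions of 12 Gy.
#'
#' @param total_dose_gy Total dose in Gy, > 0.
#' @param n_fractions Positive integer number of fractions.
#' @return An object of class `fractionation_scheme` with fields
#'   `total_dose_gy`, `n_fractions`, `dose_per_fraction_gy`.
#' @examples
#' fractionation_scheme(60, 5)  # 12 Gy per fraction
#' @export
fractionation_scheme <- function(total_dose_gy, n_fractions) {
  if (!is.numeric(total_dose_gy) || total_dose_gy <= 0)
    stop("total_dose_gy must be > 0")
  if (!is.numeric(n_fractions) || n_fractions < 1 ||
      abs(n_fractions - round(n_fractions)) > 1e-9)
    stop("n_fractions must be a positive integer")
  n_fractions <- as.integer(round(n_fractions))
  structure(
    list(total_dose_gy = total_dose_gy, n_fractions = n_fractions,
         dose_per_fraction_gy = total_dose_gy / n_fractions),
    class = "fractionation_scheme")
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("<fractionation> %.4g Gy in %d fx of %.4g Gy\n",
              x$total_dose_gy, x$n_fractions, x$dose_per_fraction_gy))
  invisible(x)
}
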