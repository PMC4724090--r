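# Closed-form radiobiological response models operating on DVHs.
# Probabilities are clipped to [1e-12, 1 - 1e-12] before logs and products to
# avoid underflow; the clip is documented on each function it affects.

.prob_clip <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' Linear-quadratic fractionation correction
#' `EQD2 = D * (1 + d / (a/b)) / (1 + 2 / (a/b))`, where `D` is the cumulative
#' physical dose and `d` the dose per fraction. At `d = 2` Gy the correction
#' is the identity for any alpha/beta.
#'
#' @param total_dose_gy Cumulative physical dose `D` in Gy (>= 0, vectorized).
#' @param dose_per_fraction_gy Dose per fraction `d` in Gy (> 0).
#' @param alpha_beta_gy Alpha/beta ratio in Gy (> 0).
#' @return EQD2 in Gy.
#' @examples
#' eqd2(60, 12, 10)   # 110 Gy
#' eqd2(6.5, 12, 10)  # 11.92 Gy
#' @export
eqd2 <- function(total_dose_gy, dose_per_fraction_gy, alpha_beta_gy) {
  if (any(total_dose_gy < 0)) stop("total_dose_gy must be >= 0")
  if (any(dose_per_fraction_gy <= 0)) stop("dose_per_fraction_gy must be > 0")
  if (any(alpha_beta_gy <= 0)) stop("alpha_beta_gy must be > 0")
  total_dose_gy * (1 + dose_per_fraction_gy / alpha_beta_gy) /
    (1 + 2 / alpha_beta_gy)
}

#' EQD2-correct a DVH for fractionation
#'
#' Maps every dose on the DVH's axis through [eqd2()], taking each dose `D`
#' as delivered evenly over the scheme's fractions (`d = D / n_fractions`),
#' which is the per-bin correction applied when converting a whole DVH to the
#' 2-Gy-fraction scale. Volumes are untouched; the output dose grid is the
#' (monotone) image of the input grid and is in general non-uniform.
#'
#' @param x A `dvh` (converted internally to differential).
#' @param scheme A [fractionation_scheme()].
#' @param alpha_beta_gy Alpha/beta in Gy for the structure being corrected.
#' @return A differential `dvh` on the EQD2 dose axis.
#' @export
eqd2_correct_dvh <- function(x, scheme, alpha_beta_gy) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  x <- to_differential(x)
  e <- x$dose_edges
  new_e <- ifelse(e > 0,
                  eqd2(e, pmax(e / scheme$n_fractions, 1e-12), alpha_beta_gy),
                  0)
  dvh(new_e, x$volume, "differential", x$structure_id, x$total_volume_cc)
}

#' Poisson linear-quadratic dose-response probability
#'
#' Sigmoid response `P(D) = 2 ^ (-exp(e * gamma * (1 - D / D50)))` in the
#' Poisson-LQ (Kallman) parameterization: `P(D50) = 0.5` exactly and `gamma`
#' is the normalized slope at the steepest point. Doses are on the same
#' effective-dose scale as D50 (here EQD2).
#'
#' @param dose_gy Dose in Gy (>= 0, vectorized), on the D50 scale.
#' @param params A [tcp_params()] or [seriality_params()] object (needs
#'   `d50_gy` and `gamma`).
#' @return Probability in `[0, 1]`.
#' @export
poisson_response <- function(dose_gy, params) {
  if (any(dose_gy < 0)) stop("dose_gy must be >= 0")
  stopifnot(!is.null(params$d50_gy), !is.null(params$gamma))
  2^(-exp(exp(1) * params$gamma * (1 - dose_gy / params$d50_gy)))
}

#' Tumor control probability from a DVH
#'
#' Aggregates the per-bin Poisson-LQ response over an EQD2-corrected
#' differential DVH under the voxel-independence assumption:
#' `TCP = prod_i P(D_i) ^ v_i`, with `D_i` the bin-center doses and `v_i`
#' the bin volume fractions. Per-bin probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` before the log-sum. An EUD-based reduction
#' (`method = "eud"`: response evaluated at the generalized EUD with
#' `n = 1`, i.e. at the mean dose) is available as an alternative.
#'
#' @param x An EQD2-corrected `dvh`.
#' @param params A [tcp_params()] object.
#' @param method `"product"` (default) or `"eud"`.
#' @return TCP in `[0, 1]`.
#' @export
tcp_from_dvh <- function(x, params, method = c("product", "eud")) {
  method <- match.arg(method)
  x <- to_differential(x)
  v <- x$volume
  if (abs(sum(v) - 1) > 1e-6) stop("DVH volumes must sum to 1")
  if (method == "eud")
    return(poisson_response(eud(x, n_volume = 1), params))
  p <- .prob_clip(poisson_response(bin_centers(x), params))
  exp(sum(v * log(p)))
}

#' Generalized equivalent uniform dose (EUD)
#'
#' `EUD = (sum_i v_i * D_i^(1/n)) ^ n`: the generalized mean of the
#' differential DVH's bin-center doses with exponent `a = 1/n`. `n = 1`
#' gives the mean dose; `n -> 0` approaches the maximum dose (serial
#' organs); zero-dose bins contribute zero.
#'
#' @param x A differential `dvh` (any mode accepted, converted internally),
#'   typically already EQD2-corrected.
#' @param n_volume Volume-effect exponent n, > 0.
#' @return EUD in Gy.
#' @export
eud <- function(x, n_volume) {
  if (!is.numeric(n_volume) || length(n_volume) != 1L || n_volume <= 0)
    stop("n_volume must be a single positive number")
  x <- to_differential(x)
  v <- x$volume
  if (abs(sum(v) - 1) > 1e-6) stop("DVH volumes must sum to 1")
  d <- bin_centers(x)
  a <- 1 / n_volume
  # compute in log space against overflow for small n (large a)
  nz <- v > 0 & d > 0
  if (!any(nz)) return(0)
  m <- max(d[nz])
  (sum(v[nz] * (d[nz] / m)^a))^n_volume * m
}

#' Lyman-Kutcher-Burman NTCP
#'
#' Probit dose-response on the equivalent uniform dose:
#' `NTCP = Phi(t)` with `t = (EUD - D50) / (m * D50)`, where `Phi` is the
#' standard normal CDF (evaluated in closed form via [stats::pnorm()]).
#'
#' @param eud_gy Equivalent uniform dose in Gy (>= 0), on the same
#'   effective-dose scale as the parameter set's D50.
#' @param params An [lkb_params()] object.
#' @return NTCP in `[0, 1]`.
#' @export
lkb_ntcp <- function(eud_gy, params) {
  stopifnot(inherits(params, "lkb_params"))
  if (any(eud_gy < 0)) stop("eud_gy must be >= 0")
  stats::pnorm((eud_gy - params$d50_gy) / (params$m_slope * params$d50_gy))
}

#' Relative-seriality NTCP from a DVH
#'
#' Poisson-based complication model weighting serial versus parallel organ
#' architecture:
#' `NTCP = (1 - prod_i (1 - P(D_i)^s)^(v_i)) ^ (1/s)`,
#' with `P` the Poisson-LQ response of [poisson_response()], `s` the relative
#' seriality, `D_i` bin-center doses of the EQD2-corrected differential DVH
#' and `v_i` the bin volume fractions. At uniform dose D50 the model returns
#' 0.5 for any `s`; at `s = 1` and uniform dose it collapses to `P(D)`.
#' Intermediate probabilities are clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param x An EQD2-corrected `dvh`.
#' @param params A [seriality_params()] object.
#' @return NTCP in `[0, 1]`.
#' @export
seriality_ntcp <- function(x, params) {
  stopifnot(inherits(params, "seriality_params"))
  s <- params$s_seriality
  x <- to_differential(x)
  v <- x$volume
  if (abs(sum(v) - 1) > 1e-6) stop("DVH volumes must sum to 1")
  p <- poisson_response(bin_centers(x), params)
  one_minus <- .prob_clip(1 - p^s)
  inner <- exp(sum(v * log(one_minus)))
  (1 - inner)^(1 / s)
}
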