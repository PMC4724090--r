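#' Dose-response model parameter sets
#'
#' Constructors for the three parameter families used in plan evaluation.
#' `tcp_params()` holds Poisson linear-quadratic tumor-control parameters:
#' D50 (the EQD2 giving 50% control), the normalized dose-response gradient
#' gamma, and the tumor alpha/beta used in the EQD2 correction.
#' `lkb_params()` holds Lyman-Kutcher-Burman parameters: D50, the
#' volume-effect exponent n of the generalized EUD, the probit slope m, and
#' the tissue alpha/beta. `seriality_params()` holds relative-seriality
#' parameters: D50, gamma, the seriality s, and alpha/beta.
#'
#' @param d50_gy D50 in Gy (> 0).
#' @param gamma Normalized dose-response gradient (> 0).
#' @param n_volume Volume-effect exponent, in (0, 1].
#' @param m_slope Probit slope parameter (> 0).
#' @param s_seriality Relative seriality (> 0); s near 0 is parallel, s = 1
#'   fully serial response at uniform dose, larger s more serial.
#' @param alpha_beta_gy Linear-quadratic alpha/beta ratio in Gy (> 0), used
#'   when EQD2-correcting the DVH for this parameter set.
#' @param label Provenance label (e.g. the source study).
#' @param endpoint Clinical endpoint the set was fitted to.
#' @return An object of class `tcp_params`, `lkb_params` or
#'   `seriality_params`.
#' @name model_params
NULL

#' @rdname model_params
#' @export
tcp_params <- function(d50_gy, gamma, alpha_beta_gy = 10, label = "custom") {
  stopifnot(d50_gy > 0, gamma > 0, alpha_beta_gy > 0)
  structure(list(d50_gy = d50_gy, gamma = gamma,
                 alpha_beta_gy = alpha_beta_gy, label = label),
            class = "tcp_params")
}

#' @rdname model_params
#' @export
lkb_params <- function(d50_gy, n_volume, m_slope, alpha_beta_gy,
                       label = "custom", endpoint = "") {
  stopifnot(d50_gy > 0, n_volume > 0, n_volume <= 1, m_slope > 0,
            alpha_beta_gy > 0)
  structure(list(d50_gy = d50_gy, n_volume = n_volume, m_slope = m_slope,
                 alpha_beta_gy = alpha_beta_gy, label = label,
                 endpoint = endpoint),
            class = "lkb_params")
}

#' @rdname model_params
#' @export
seriality_params <- function(d50_gy, gamma, s_seriality, alpha_beta_gy,
                             label = "custom", endpoint = "") {
  stopifnot(d50_gy > 0, gamma > 0, s_seriality > 0, alpha_beta_gy > 0)
  structure(list(d50_gy = d50_gy, gamma = gamma, s_seriality = s_seriality,
                 alpha_beta_gy = alpha_beta_gy, label = label,
                 endpoint = endpoint),
            class = "seriality_params")
}

#' Bundled published model parameter sets
#'
#' Loads the versioned registry shipped with the package
#' (`extdata/model_parameters.yaml`): three NSCLC TCP sets (Willner 24-month,
#' Martel 24- and 30-month local control, tumor alpha/beta 10 Gy), three lung
#' pneumonitis LKB sets (Kwa, Seppenwoolde, Burman; lung alpha/beta 1.3 Gy by
#' default with a Seppenwoolde alpha/beta 3 Gy variant), LKB sets for
#' esophagitis and pericarditis, and relative-seriality sets for spinal cord
#' myelitis and esophageal stricture.
#'
#' @param key Optional registry key such as `"tcp.martel_30mo"` or
#'   `"lung_lkb.burman"`; if omitted the full named list is returned.
#' @return A single parameter object, or a named list of all of them.
#' @examples
#' model_parameters("tcp.martel_30mo")
#' names(model_parameters())
#' @export
model_parameters <- function(key = NULL) {
  path <- system.file("extdata", "model_parameters.yaml", package = "dvhbio",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  out <- list()
  for (nm in names(raw$tcp)) {
    p <- raw$tcp[[nm]]
    out[[paste0("tcp.", nm)]] <-
      tcp_params(p$d50_gy, p$gamma, p$alpha_beta_gy, label = nm)
  }
  for (fam in c("lung_lkb", "lkb")) {
    for (nm in names(raw[[fam]])) {
      p <- raw[[fam]][[nm]]
      out[[paste0(fam, ".", nm)]] <-
        lkb_params(p$d50_gy, p$n_volume, p$m_slope, p$alpha_beta_gy,
                   label = nm, endpoint = p$endpoint)
    }
  }
  for (nm in names(raw$seriality)) {
    p <- raw$seriality[[nm]]
    out[[paste0("seriality.", nm)]] <-
      seriality_params(p$d50_gy, p$gamma, p$s_seriality, p$alpha_beta_gy,
                       label = nm, endpoint = p$endpoint)
  }
  if (is.null(key)) return(out)
  if (!key %in% names(out))
    stop("unknown parameter key '", key, "'; see names(model_parameters())")
  out[[key]]
}

#' @export
print.tcp_params <- function(x, ...) {
  cat(sprintf("<tcp_params %s> D50 %.1f Gy, gamma %.2f, a/b %.1f Gy\n",
              x$label, x$d50_gy, x$gamma, x$alpha_beta_gy))
  invisible(x)
}

#' @export
print.lkb_params <- function(x, ...) {
  cat(sprintf("<lkb_params %s> D50 %.1f Gy, n %.2f, m %.2f, a/b %.1f Gy %s\n",
              x$label, x$d50_gy, x$n_volume, x$m_slope, x$alpha_beta_gy,
              x$endpoint))
  invisible(x)
}

#' @export
print.seriality_params <- function(x, ...) {
  cat(sprintf("<seriality_params %s> D50 %.1f Gy, gamma %.2f, s %.2f, a/b %.1f Gy %s\n",
              x$label, x$d50_gy, x$gamma, x$s_seriality, x$alpha_beta_gy,
              x$endpoint))
  invisible(x)
}
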