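#' Study parameter bundle
#'
#' The default selection of bundled parameter sets for a lung SBRT plan:
#' all three NSCLC TCP sets for the PTV, the lung pneumonitis LKB sets
#' (three studies, plus the alpha/beta 3 Gy Seppenwoolde variant), the
#' esophagus and heart LKB sets, and the relative-seriality sets for spinal
#' cord and esophagus.
#'
#' @return A list with elements `tcp` (list of [tcp_params()]) and `ntcp`
#'   (named list, structure name to list of [lkb_params()] /
#'   [seriality_params()]).
#' @export
study_parameter_bundle <- function() {
  p <- model_parameters()
  list(
    tcp = p[grep("^tcp\\.", names(p))],
    ntcp = list(
      lung = p[grep("^lung_lkb\\.", names(p))],
      esophagus = list(p[["lkb.esophagus"]],
                       p[["seriality.esophagus_stricture"]]),
      heart = list(p[["lkb.heart"]]),
      cord = list(p[["seriality.cord_myelitis"]])))
}

.ntcp_one <- function(x, scheme, params) {
  xe <- eqd2_correct_dvh(x, scheme, params$alpha_beta_gy)
  if (inherits(params, "lkb_params")) {
    list(model = "lkb",
         value = lkb_ntcp(eud(xe, params$n_volume), params))
  } else if (inherits(params, "seriality_params")) {
    list(model = "seriality", value = seriality_ntcp(xe, params))
  } else {
    stop("unsupported NTCP parameter class: ", paste(class(params),
                                                     collapse = "/"))
  }
}

#' Evaluate one plan: dose metrics, TCP and NTCP
#'
#' Computes per-structure dose metrics, PTV tumor control probability under
#' each requested TCP parameter set (DVH EQD2-corrected with the set's
#' tumor alpha/beta, then aggregated with [tcp_from_dvh()]), and NTCP for
#' each organ-at-risk under each requested parameter set. Every NTCP set
#' carries its own alpha/beta, so the OAR DVH is EQD2-corrected separately
#' per set. A PTV DVH (named `"ptv"`) is required; parameter sets requested
#' for a structure that has no DVH are skipped with a warning.
#'
#' @param dvhs Named list of `dvh` objects; must contain `"ptv"`.
#' @param scheme A [fractionation_scheme()].
#' @param bundle Parameter bundle as from [study_parameter_bundle()]; a list
#'   with `tcp` (list of [tcp_params()]) and `ntcp` (named list mapping
#'   structure names to lists of NTCP parameter objects).
#' @param tcp_method Aggregation rule for [tcp_from_dvh()].
#' @param plan_id Label carried into the result.
#' @return An object of class `plan_eval` with data-frame fields `metrics`
#'   (per-structure mean/max/min/D95), `tcp` (label, value) and `ntcp`
#'   (structure, model, label, value).
#' @examples
#' p <- dvh(c(0, 59.9, 60.1), c(1, 1, 0), "cumulative", "ptv")
#' ev <- evaluate_plan(list(ptv = p), fractionation_scheme(60, 5),
#'                     study_parameter_bundle())
#' ev$tcp
#' @export
evaluate_plan <- function(dvhs, scheme, bundle = study_parameter_bundle(),
                          tcp_method = c("product", "eud"), plan_id = "plan") {
  tcp_method <- match.arg(tcp_method)
  stopifnot(is.list(dvhs), inherits(scheme, "fractionation_scheme"))
  if (!"ptv" %in% names(dvhs)) stop("missing PTV: dvhs must contain 'ptv'")

  metrics <- do.call(rbind, lapply(names(dvhs), function(nm) {
    s <- summary(dvhs[[nm]])
    data.frame(structure = nm, mean_gy = s$mean_gy, max_gy = s$max_gy,
               min_gy = s$min_gy, d95_gy = s$d95_gy,
               stringsAsFactors = FALSE)
  }))

  tcp <- do.call(rbind, lapply(bundle$tcp, function(ps) {
    ptv_eqd2 <- eqd2_correct_dvh(dvhs$ptv, scheme, ps$alpha_beta_gy)
    data.frame(label = ps$label,
               value = tcp_from_dvh(ptv_eqd2, ps, method = tcp_method),
               stringsAsFactors = FALSE)
  }))
  rownames(tcp) <- NULL

  ntcp_rows <- list()
  for (organ in names(bundle$ntcp)) {
    if (is.null(dvhs[[organ]])) {
      warning("no DVH for '", organ, "'; its NTCP sets were skipped")
      next
    }
    for (ps in bundle$ntcp[[organ]]) {
      r <- .ntcp_one(dvhs[[organ]], scheme, ps)
      ntcp_rows[[length(ntcp_rows) + 1L]] <-
        data.frame(structure = organ, model = r$model, label = ps$label,
                   value = r$value, stringsAsFactors = FALSE)
    }
  }
  ntcp <- if (length(ntcp_rows)) do.call(rbind, ntcp_rows) else
    data.frame(structure = character(), model = character(),
               label = character(), value = numeric(),
               stringsAsFactors = FALSE)

  structure(list(plan_id = plan_id, scheme = scheme, metrics = metrics,
                 tcp = tcp, ntcp = ntcp, tcp_method = tcp_method),
            class = "plan_eval")
}

#' @export
print.plan_eval <- function(x, ...) {
  cat(sprintf("<plan_eval> %s (%.4g Gy / %d fx)\n", x$plan_id,
              x$scheme$total_dose_gy, x$scheme$n_fractions))
  cat("Structure metrics (Gy):\n")
  print(format(x$metrics, digits = 4), row.names = FALSE)
  cat("TCP:\n")
  for (i in seq_len(nrow(x$tcp)))
    cat(sprintf("  %-22s %6.1f %%\n", x$tcp$label[i], 100 * x$tcp$value[i]))
  if (nrow(x$ntcp)) {
    cat("NTCP:\n")
    for (i in seq_len(nrow(x$ntcp)))
      cat(sprintf("  %-10s %-10s %-22s %6.2f %%\n", x$ntcp$structure[i],
                  x$ntcp$model[i], x$ntcp$label[i], 100 * x$ntcp$value[i]))
  }
  invisible(x)
}
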