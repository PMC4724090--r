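#' Normal-tissue dose criteria for SBRT lung plan evaluation
#'
#' The bundled rule set used for plan acceptability: maximum point dose limits
#' for spinal cord (30 Gy), heart (38 Gy) and esophagus (35 Gy), and
#' volume-above-threshold limits for heart (< 15 cc above 32 Gy), esophagus
#' (< 5 cc above 19.5 Gy) and bilateral lung minus ITV (< 1000 cc above
#' 13.5 Gy and < 1500 cc above 12.5 Gy). All inequalities are strict, so a
#' measured value exactly at the limit fails.
#'
#' @return A data frame with one rule per row: `structure`, `rule`
#'   (`"max_dose"` or `"volume_above"`), `limit` (Gy for max-dose rules, cc
#'   for volume rules) and `threshold_gy` (NA for max-dose rules).
#' @export
default_constraints <- function() {
  data.frame(
    structure = c("cord", "heart", "esophagus",
                  "heart", "esophagus", "lung", "lung"),
    rule = c(rep("max_dose", 3L), rep("volume_above", 4L)),
    limit = c(30, 38, 35, 15, 5, 1000, 1500),
    threshold_gy = c(NA, NA, NA, 32, 19.5, 13.5, 12.5),
    stringsAsFactors = FALSE)
}

#' Check normal-tissue dose constraints
#'
#' Evaluates each rule against the matching structure's DVH. Max-dose rules
#' compare the DVH maximum dose (bin-edge resolution) with the limit;
#' volume-above rules compare the absolute volume (cc) receiving at least the
#' threshold dose with the volume limit, which requires `total_volume_cc` on
#' the DVH. Rules whose structure is missing, or whose DVH lacks the needed
#' absolute volume, are reported as `"not evaluable"`, never silently passed.
#'
#' @param dvhs Named list of `dvh` objects; names must match the `structure`
#'   column of the constraint table.
#' @param constraints Constraint table as from [default_constraints()].
#' @return A data frame with the constraint columns plus `measured` and
#'   `verdict` (`"pass"`, `"fail"` or `"not evaluable"`).
#' @examples
#' lung <- dvh(c(0, 5, 10, 20), c(1, 0.4, 0.1, 0), "cumulative", "lung",
#'             total_volume_cc = 3000)
#' check_constraints(list(lung = lung))
#' @export
check_constraints <- function(dvhs, constraints = default_constraints()) {
  stopifnot(is.list(dvhs))
  res <- constraints
  res$measured <- NA_real_
  res$verdict <- "not evaluable"
  for (i in seq_len(nrow(res))) {
    d <- dvhs[[res$structure[i]]]
    if (is.null(d)) next
    if (res$rule[i] == "max_dose") {
      m <- summary(d)$max_gy
    } else {
      if (is.null(d$total_volume_cc)) next
      m <- volume_at_dose(d, res$threshold_gy[i], absolute = TRUE)
    }
    res$measured[i] <- m
    res$verdict[i] <- if (m < res$limit[i]) "pass" else "fail"
  }
  class(res) <- c("constraint_report", "data.frame")
  res
}

#' @export
print.constraint_report <- function(x, ...) {
  cat("Normal-tissue constraint check\n")
  for (i in seq_len(nrow(x))) {
    lim <- if (x$rule[i] == "max_dose")
      sprintf("max < %g Gy", x$limit[i])
    else
      sprintf("< %g cc above %g Gy", x$limit[i], x$threshold_gy[i])
    meas <- if (is.na(x$measured[i])) "-" else sprintf("%.2f", x$measured[i])
    cat(sprintf("  %-10s %-24s measured %-8s %s\n",
                x$structure[i], lim, meas, toupper(x$verdict[i])))
  }
  invisible(x)
}
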