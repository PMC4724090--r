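#' Evaluate every plan in a cohort
#'
#' Runs [evaluate_plan()] on the reference and recalculated plan of every
#' patient in a manifest (or an in-memory [generate_cohort()] result) and
#' checks the normal-tissue constraints on each plan. Malformed DVH files
#' fail their patient only: the run continues and the failures are returned
#' (and summarized in a warning), never silently dropped.
#'
#' @param cohort Path to a manifest CSV (see [read_manifest()]) or a
#'   `dvh_cohort` object.
#' @param scheme A [fractionation_scheme()].
#' @param bundle Parameter bundle, as in [evaluate_plan()].
#' @param tcp_method Aggregation rule for [tcp_from_dvh()].
#' @param constraints Constraint table for [check_constraints()], or `NULL`
#'   to skip checking.
#' @param out_file Optional path; when set the evaluations are written as a
#'   tidy CSV readable by [read_evaluations()].
#' @return A list of class `cohort_evaluations`: `records` (list of
#'   [patient_record()]s, each plan carrying a `constraints` report) and
#'   `failures` (data frame of patient_id / error message).
#' @export
run_evaluation <- function(cohort, scheme = fractionation_scheme(60, 5),
                           bundle = study_parameter_bundle(),
                           tcp_method = "product",
                           constraints = default_constraints(),
                           out_file = NULL) {
  if (inherits(cohort, "dvh_cohort")) {
    entries <- lapply(cohort$patients, function(p)
      list(patient_id = p$patient_id, location = p$location,
           ptv_cc = p$ptv_cc, ref = p$dvhs_ref, recalc = p$dvhs_recalc))
  } else {
    mf <- read_manifest(cohort)
    if (nrow(mf) == 0L) stop("no patients in manifest")
    entries <- lapply(seq_len(nrow(mf)), function(i)
      list(patient_id = mf$patient_id[i], location = mf$location[i],
           ptv_cc = mf$ptv_cc[i], ref = mf$ref_dvh_path[i],
           recalc = mf$recalc_dvh_path[i]))
  }
  if (!length(entries)) stop("no patients")

  records <- list()
  failures <- list()
  eval_one <- function(dvhs_or_path, plan_id) {
    dvhs <- if (is.character(dvhs_or_path)) read_dvh_csv(dvhs_or_path)
            else dvhs_or_path
    ev <- evaluate_plan(dvhs, scheme, bundle, tcp_method = tcp_method,
                        plan_id = plan_id)
    if (!is.null(constraints))
      ev$constraints <- check_constraints(dvhs, constraints)
    ev
  }
  for (e in entries) {
    rec <- tryCatch({
      ref <- eval_one(e$ref, paste0(e$patient_id, "/reference"))
      rec <- eval_one(e$recalc, paste0(e$patient_id, "/recalculated"))
      patient_record(e$patient_id, e$location, e$ptv_cc, ref, rec)
    }, error = function(err)
      structure(conditionMessage(err), class = "eval_failure"))
    if (inherits(rec, "eval_failure")) {
      failures[[length(failures) + 1L]] <-
        data.frame(patient_id = e$patient_id, error = unclass(rec),
                   stringsAsFactors = FALSE)
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(patient_id = character(), error = character(),
               stringsAsFactors = FALSE)
  if (nrow(failures))
    warning(nrow(failures), " patient(s) failed evaluation: ",
            paste(failures$patient_id, collapse = ", "))
  out <- structure(list(records = records, failures = failures,
                        scheme = scheme), class = "cohort_evaluations")
  if (!is.null(out_file)) write_evaluations(out, out_file)
  out
}

#' Write / read cohort evaluations as tidy CSV
#'
#' One row per evaluated quantity: dose metrics (`section = "metric"`), TCP
#' (`"tcp"`) and NTCP (`"ntcp"`) values per plan, with the patient
#' descriptors and scheme repeated on each row. The round-trip preserves
#' every field the comparison stage consumes; per-plan constraint reports
#' are not serialized.
#'
#' @param evaluations A `cohort_evaluations` object.
#' @param path CSV path.
#' @return `write_evaluations()`: `path`, invisibly; `read_evaluations()`:
#'   a `cohort_evaluations` object.
#' @export
write_evaluations <- function(evaluations, path) {
  stopifnot(inherits(evaluations, "cohort_evaluations"))
  rows <- lapply(evaluations$records, function(r) {
    per_plan <- function(ev, role) {
      m <- ev$metrics
      rbind(
        data.frame(section = "metric", structure = rep(m$structure, 4L),
                   model = "", label = rep(c("mean_gy", "max_gy", "min_gy",
                                             "d95_gy"), each = nrow(m)),
                   value = c(m$mean_gy, m$max_gy, m$min_gy, m$d95_gy),
                   stringsAsFactors = FALSE),
        data.frame(section = "tcp", structure = "ptv", model = "poisson_lq",
                   label = ev$tcp$label, value = ev$tcp$value,
                   stringsAsFactors = FALSE),
        if (nrow(ev$ntcp))
          data.frame(section = "ntcp", structure = ev$ntcp$structure,
                     model = ev$ntcp$model, label = ev$ntcp$label,
                     value = ev$ntcp$value, stringsAsFactors = FALSE))
    }
    both <- rbind(cbind(plan_role = "reference",
                        per_plan(r$reference, "reference")),
                  cbind(plan_role = "recalculated",
                        per_plan(r$recalculated, "recalculated")))
    cbind(patient_id = r$patient_id, location = r$location,
          ptv_cc = r$ptv_cc,
          total_dose_gy = evaluations$scheme$total_dose_gy,
          n_fractions = evaluations$scheme$n_fractions, both)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evaluations
#' @export
read_evaluations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scheme <- fractionation_scheme(df$total_dose_gy[1L], df$n_fractions[1L])
  rebuild_plan <- function(sub, plan_id) {
    met <- sub[sub$section == "metric", ]
    wide <- stats::reshape(met[, c("structure", "label", "value")],
                           idvar = "structure", timevar = "label",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    metrics <- wide[, c("structure", "mean_gy", "max_gy", "min_gy",
                        "d95_gy")]
    rownames(metrics) <- NULL
    tcp <- sub[sub$section == "tcp", c("label", "value")]
    rownames(tcp) <- NULL
    ntcp <- sub[sub$section == "ntcp", c("structure", "model", "label",
                                         "value")]
    rownames(ntcp) <- NULL
    structure(list(plan_id = plan_id, scheme = scheme, metrics = metrics,
                   tcp = tcp, ntcp = ntcp, tcp_method = "product"),
              class = "plan_eval")
  }
  records <- lapply(unique(df$patient_id), function(pid) {
    sub <- df[df$patient_id == pid, ]
    patient_record(pid, sub$location[1L], sub$ptv_cc[1L],
                   rebuild_plan(sub[sub$plan_role == "reference", ],
                                paste0(pid, "/reference")),
                   rebuild_plan(sub[sub$plan_role == "recalculated", ],
                                paste0(pid, "/recalculated")))
  })
  structure(list(records = records,
                 failures = data.frame(patient_id = character(),
                                       error = character(),
                                       stringsAsFactors = FALSE),
                 scheme = scheme), class = "cohort_evaluations")
}

.abs_value_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    one <- function(ev, role) {
      m <- ev$metrics[ev$metrics$structure == "ptv", ]
      vals <- c(`PTV (D95%)` = m$d95_gy, `PTV (mean)` = m$mean_gy,
                `PTV (max)` = m$max_gy, `PTV (min)` = m$min_gy)
      if ("lung" %in% ev$metrics$structure)
        vals <- c(vals, MLD = ev$metrics[
          ev$metrics$structure == "lung", "mean_gy"])
      tcp <- stats::setNames(ev$tcp$value, paste0("TCP ", ev$tcp$label))
      ntcp <- if (nrow(ev$ntcp))
        stats::setNames(ev$ntcp$value, paste0("NTCP ", ev$ntcp$structure,
                                              " ", ev$ntcp$label))
      else NULL
      v <- c(vals, tcp, ntcp)
      data.frame(patient_id = r$patient_id, location = r$location,
                 plan_role = role, metric = names(v), value = unname(v),
                 stringsAsFactors = FALSE)
    }
    rbind(one(r$reference, "reference"), one(r$recalculated, "recalculated"))
  }))
}

#' Compare a cohort of evaluated plan pairs
#'
#' Computes every paired difference ([compare_pair()]), the per-location
#' delta summaries ([cohort_summary()]), and a per-metric reference-versus-
#' recalculated table in the study's layout: per tumor location, the median
#' (range) of each metric under each plan role, with a Kruskal-Wallis
#' p-value comparing the two roles' samples. With `out_dir` set, writes
#' `comparison_summary.csv` and `plan_metrics.csv` (tidy) plus `report.txt`
#' (human-readable, including per-plan constraint verdict counts when
#' constraint reports are present).
#'
#' @param evaluations A `cohort_evaluations` object from [run_evaluation()]
#'   or [read_evaluations()].
#' @param out_dir Optional output directory.
#' @return An object of class `cohort_report`: `comparisons`,
#'   `delta_summary`, `metric_table` and `constraint_counts`.
#' @export
run_comparison <- function(evaluations, out_dir = NULL) {
  stopifnot(inherits(evaluations, "cohort_evaluations"))
  records <- evaluations$records
  if (!length(records)) stop("no evaluated patients to compare")
  comparisons <- lapply(records, compare_pair)
  delta_summary <- cohort_summary(comparisons, group_by = "location")

  abs_tab <- .abs_value_table(records)
  metric_rows <- list()
  for (grp in unique(abs_tab$location)) {
    gt <- abs_tab[abs_tab$location == grp, ]
    for (met in unique(gt$metric)) {
      a <- gt$value[gt$metric == met & gt$plan_role == "reference"]
      b <- gt$value[gt$metric == met & gt$plan_role == "recalculated"]
      kw <- kruskal_wallis(list(a, b), exact = "never")
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        group = grp, metric = met, n = length(a),
        ref_median = stats::median(a), ref_min = min(a), ref_max = max(a),
        recalc_median = stats::median(b), recalc_min = min(b),
        recalc_max = max(b), p_value = kw$p_value, stringsAsFactors = FALSE)
    }
  }
  metric_table <- do.call(rbind, metric_rows)

  constraint_counts <- NULL
  if (!is.null(records[[1L]]$reference$constraints)) {
    all_cr <- do.call(rbind, lapply(records, function(r)
      rbind(cbind(plan_role = "reference",
                  as.data.frame(r$reference$constraints)),
            cbind(plan_role = "recalculated",
                  as.data.frame(r$recalculated$constraints)))))
    constraint_counts <- as.data.frame(
      table(structure = all_cr$structure, rule = all_cr$rule,
            verdict = all_cr$verdict),
      stringsAsFactors = FALSE)
    constraint_counts <-
      constraint_counts[constraint_counts$Freq > 0, , drop = FALSE]
    rownames(constraint_counts) <- NULL
  }

  report <- structure(list(comparisons = comparisons,
                           delta_summary = delta_summary,
                           metric_table = metric_table,
                           constraint_counts = constraint_counts),
                      class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(delta_summary,
                     file.path(out_dir, "comparison_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(abs_tab, file.path(out_dir, "plan_metrics.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("Paired plan cohort report\n")
  cat("=========================\n\n")
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  for (grp in unique(x$metric_table$group)) {
    sub <- x$metric_table[x$metric_table$group == grp, ]
    cat(sprintf("%s tumors (n = %d): median (range), reference vs recalculated\n",
                grp, sub$n[1L]))
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-34s %s (%s, %s)  vs  %s (%s, %s)   p = %s\n",
                  sub$metric[i], fmt(sub$ref_median[i]), fmt(sub$ref_min[i]),
                  fmt(sub$ref_max[i]), fmt(sub$recalc_median[i]),
                  fmt(sub$recalc_min[i]), fmt(sub$recalc_max[i]),
                  format.pval(sub$p_value[i], digits = 2)))
    cat("\n")
  }
  cat("Paired differences (reference - recalculated): median (range)\n")
  ds <- x$delta_summary
  for (i in seq_len(nrow(ds)))
    cat(sprintf("  %-38s %-11s %s (%s, %s)\n", ds$metric[i], ds$group[i],
                fmt(ds$median[i]), fmt(ds$min[i]), fmt(ds$max[i])))
  if (!is.null(x$constraint_counts)) {
    cat("\nConstraint verdicts (plan-rule counts):\n")
    cc <- x$constraint_counts
    for (i in seq_len(nrow(cc)))
      cat(sprintf("  %-10s %-13s %-14s %d\n", cc$structure[i], cc$rule[i],
                  cc$verdict[i], cc$Freq[i]))
  }
  invisible(x)
}

#' @export
plot.cohort_report <- function(x, metric = "delta_tcp.martel_30mo", ...) {
  tab <- .delta_table(x$comparisons)
  d95 <- tab[tab$metric == "delta_d95_gy", ]
  dm <- tab[tab$metric == metric, ]
  m <- match(d95$patient_id, dm$patient_id)
  graphics::plot(d95$delta, dm$delta[m],
                 pch = ifelse(d95$location == "peripheral", 19, 17),
                 xlab = expression(Delta * "D95 (Gy)"),
                 ylab = metric, ...)
  graphics::legend("topleft", pch = c(19, 17),
                   legend = c("peripheral", "central"), bty = "n")
  invisible(x)
}
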