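#' Patient record: one evaluated plan pair
#'
#' Couples the two evaluations of one patient's plan pair — the reference
#' plan (the role played by the convolution-superposition AAA calculation in
#' the study design) and the recalculated plan (the Boltzmann-solver AXB
#' role) — with the patient's tumor location and PTV size.
#'
#' @param patient_id Identifier.
#' @param location `"peripheral"` or `"central"`.
#' @param ptv_cc PTV volume in cc.
#' @param reference,recalculated `plan_eval` objects from [evaluate_plan()],
#'   evaluated on identical structure sets and schemes.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, location, ptv_cc, reference,
                           recalculated) {
  location <- match.arg(location, c("peripheral", "central"))
  stopifnot(inherits(reference, "plan_eval"),
            inherits(recalculated, "plan_eval"))
  if (!setequal(reference$metrics$structure, recalculated$metrics$structure))
    stop("plan pair evaluated on different structure sets")
  structure(list(patient_id = patient_id, location = location,
                 ptv_cc = ptv_cc, reference = reference,
                 recalculated = recalculated),
            class = "patient_record")
}

#' Paired plan comparison
#'
#' All per-metric differences for one patient, defined reference minus
#' recalculated, so a positive delta means the reference plan reports the
#' higher value. Covers the PTV dose metrics (D95, mean, max, min), the mean
#' lung dose if a lung DVH was evaluated, every TCP set's probability, and
#' every NTCP set's probability.
#'
#' @param record A [patient_record()].
#' @return An object of class `paired_comparison` holding `deltas`, a named
#'   numeric vector (`delta_d95_gy`, `delta_mean_gy`, `delta_max_gy`,
#'   `delta_min_gy`, optionally `delta_mld_gy`, `delta_tcp.<label>`,
#'   `delta_ntcp.<structure>.<label>`), plus the patient descriptors.
#' @export
compare_pair <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  a <- record$reference
  b <- record$recalculated
  if (!identical(a$tcp$label, b$tcp$label) ||
      !identical(paste(a$ntcp$structure, a$ntcp$label),
                 paste(b$ntcp$structure, b$ntcp$label)))
    stop("plan pair evaluated under different parameter bundles")
  ma <- a$metrics[a$metrics$structure == "ptv", ]
  mb <- b$metrics[b$metrics$structure == "ptv", ]
  deltas <- c(delta_d95_gy = ma$d95_gy - mb$d95_gy,
              delta_mean_gy = ma$mean_gy - mb$mean_gy,
              delta_max_gy = ma$max_gy - mb$max_gy,
              delta_min_gy = ma$min_gy - mb$min_gy)
  if ("lung" %in% a$metrics$structure) {
    la <- a$metrics[a$metrics$structure == "lung", "mean_gy"]
    lb <- b$metrics[b$metrics$structure == "lung", "mean_gy"]
    deltas <- c(deltas, delta_mld_gy = la - lb)
  }
  dt <- a$tcp$value - b$tcp$value
  names(dt) <- paste0("delta_tcp.", a$tcp$label)
  dn <- a$ntcp$value - b$ntcp$value
  if (length(dn))
    names(dn) <- paste0("delta_ntcp.", a$ntcp$structure, ".", a$ntcp$label)
  structure(list(patient_id = record$patient_id, location = record$location,
                 ptv_cc = record$ptv_cc, deltas = c(deltas, dt, dn)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s (%s, %.1f cc)\n", x$patient_id,
              x$location, x$ptv_cc))
  print(round(x$deltas, 5))
  invisible(x)
}

.delta_table <- function(comparisons) {
  stopifnot(length(comparisons) > 0L,
            all(vapply(comparisons, inherits, TRUE, "paired_comparison")))
  do.call(rbind, lapply(comparisons, function(cmp)
    data.frame(patient_id = cmp$patient_id, location = cmp$location,
               ptv_cc = cmp$ptv_cc, metric = names(cmp$deltas),
               delta = unname(cmp$deltas), stringsAsFactors = FALSE)))
}

#' Cohort-level summary of paired differences
#'
#' Median and (min, max) range of every paired delta, stratified by tumor
#' location. Groups with no patients are omitted with a warning.
#'
#' @param comparisons List of [compare_pair()] results.
#' @param group_by Grouping field, currently `"location"` or `"none"`.
#' @return A data frame of class `cohort_summary`: `metric`, `group`, `n`,
#'   `median`, `min`, `max`.
#' @export
cohort_summary <- function(comparisons, group_by = c("location", "none")) {
  group_by <- match.arg(group_by)
  tab <- .delta_table(comparisons)
  tab$group <- if (group_by == "location") tab$location else "all"
  if (group_by == "location") {
    missing_grp <- setdiff(c("peripheral", "central"), unique(tab$group))
    for (g in missing_grp) warning("no patients in group '", g,
                                   "'; omitted from summary")
  }
  agg <- do.call(rbind, lapply(split(tab, list(tab$metric, tab$group),
                                     drop = TRUE), function(s)
    data.frame(metric = s$metric[1L], group = s$group[1L], n = nrow(s),
               median = stats::median(s$delta), min = min(s$delta),
               max = max(s$delta), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$metric, agg$group), ]
  rownames(agg) <- NULL
  class(agg) <- c("cohort_summary", "data.frame")
  agg
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) with the
#' chi-square approximation on k - 1 degrees of freedom. For small samples
#' (pooled n <= 10 under `exact = "auto"`) the p-value is instead taken from
#' the exact permutation distribution of H, enumerated over all distinct
#' assignments of the pooled values to the observed group sizes. If every
#' pooled value is identical the statistic is defined as H = 0, p = 1.
#'
#' @param groups List of two or more nonempty numeric vectors.
#' @param exact `"auto"`, `"never"` or `"always"` (enumeration; beware cost
#'   above pooled n ~ 12).
#' @return A list with `statistic` (H), `df`, `p_value`, and `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
#' @export
kruskal_wallis <- function(groups, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("each group must be nonempty")
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  df <- length(groups) - 1L
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, df = df, p_value = 1,
                method = "degenerate (all values identical)"))
  kt <- stats::kruskal.test(pooled, factor(g))
  h_obs <- unname(kt$statistic)
  n <- length(pooled)
  use_exact <- exact == "always" || (exact == "auto" && n <= 10L)
  if (!use_exact)
    return(list(statistic = h_obs, df = df, p_value = kt$p.value,
                method = "chi-square approximation"))
  r <- rank(pooled)
  ties <- table(pooled)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h_of <- function(assign_idx) {
    rs <- vapply(assign_idx, function(ix) sum(r[ix]), 0)
    h <- 12 / (n * (n + 1)) * sum(rs^2 / lengths(assign_idx)) - 3 * (n + 1)
    h / tie_corr
  }
  perms <- .group_assignments(seq_len(n), lengths(groups))
  hs <- vapply(perms, h_of, 0)
  p <- mean(hs >= h_obs - 1e-9)
  list(statistic = h_obs, df = df, p_value = p,
       method = sprintf("exact permutation (%d assignments)", length(perms)))
}

# all distinct assignments of idx into ordered groups of the given sizes
.group_assignments <- function(idx, sizes) {
  if (length(sizes) == 1L) return(list(list(idx)))
  first <- utils::combn(idx, sizes[1L], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- .group_assignments(setdiff(idx, f), sizes[-1L])
    for (rr in rest) out[[length(out) + 1L]] <- c(list(f), rr)
  }
  out
}

#' Paired delta versus a patient covariate
#'
#' Screens one paired-delta metric against a per-patient covariate (another
#' delta, PTV size, or tumor location) with the Spearman rank correlation
#' and a seeded permutation p-value (two-sided, label permutations of the
#' covariate). No model is fitted; this is a trend screen only.
#'
#' @param comparisons List of [compare_pair()] results (>= 3).
#' @param metric Name of a delta metric, e.g. `"delta_tcp.martel_30mo"`.
#' @param covariate `"delta_d95_gy"`, `"ptv_cc"` or `"location"`
#'   (peripheral = 0, central = 1).
#' @param n_perm Number of permutations for the p-value.
#' @param seed Integer seed for the permutation draw.
#' @return A list with `data` (ordered covariate/delta pairs), `rho`
#'   (Spearman; `NA` with an explanatory `note` when the covariate is
#'   constant) and `p_perm`.
#' @export
delta_vs_covariate <- function(comparisons, metric,
                               covariate = c("delta_d95_gy", "ptv_cc",
                                             "location"),
                               n_perm = 10000, seed = 1L) {
  covariate <- match.arg(covariate)
  tab <- .delta_table(comparisons)
  sub <- tab[tab$metric == metric, , drop = FALSE]
  if (nrow(sub) < 3L) stop("need at least 3 records with metric '", metric,
                           "'")
  cov_val <- switch(covariate,
    delta_d95_gy = {
      d95 <- tab[tab$metric == "delta_d95_gy", ]
      d95$delta[match(sub$patient_id, d95$patient_id)]
    },
    ptv_cc = sub$ptv_cc,
    location = as.numeric(sub$location == "central"))
  dat <- data.frame(patient_id = sub$patient_id, covariate = cov_val,
                    delta = sub$delta, stringsAsFactors = FALSE)
  dat <- dat[order(dat$covariate), ]
  rownames(dat) <- NULL
  if (length(unique(cov_val)) == 1L)
    return(list(data = dat, rho = NA_real_, p_perm = NA_real_,
                note = "covariate constant; correlation undefined"))
  rho <- stats::cor(dat$covariate, dat$delta, method = "spearman")
  set.seed(seed)
  rho_perm <- replicate(n_perm,
    stats::cor(sample(dat$covariate), dat$delta, method = "spearman"))
  p <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  list(data = dat, rho = rho, p_perm = p)
}
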