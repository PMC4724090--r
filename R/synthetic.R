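#' Synthetic paired-cohort specification
#'
#' Parameters of the seeded generator that emulates a lung SBRT cohort of
#' paired plans: a reference plan (higher reported PTV dose, the
#' convolution-superposition role) and a recalculated plan whose PTV D95 is
#' lower by a per-patient coverage degradation delta. Defaults reproduce the
#' study conditions: 60 Gy in 5 fractions prescribed so that the reference
#' D95 is exactly 60 Gy; delta drawn per tumor location from the observed
#' D95-difference ranges (peripheral 0.3-6.5 Gy, central 0.6-4.4 Gy); PTV
#' volumes from the observed per-location ranges; reference PTV maximum dose
#' within 63.7-73.2 Gy and minimum within 51.2-57.1 Gy. The mean-lung-dose
#' range (3-8 Gy) is invented: no lung DVH summaries are available to match,
#' so it is a plausible clinical range, and is labelled as such.
#'
#' @param n_patients Number of patients.
#' @param fraction_peripheral Fraction of patients with peripheral tumors
#'   (default 19/28).
#' @param seed Integer seed; all draws derive from it.
#' @param scheme [fractionation_scheme()], default 60 Gy / 5 fractions.
#' @param delta_d95_range Named list of c(min, max) Gy per location.
#' @param delta_d95_median Named list of medians in Gy, used only by the
#'   triangular draw.
#' @param delta_d95_dist `"uniform"` (minimal assumption, default) or
#'   `"triangular"` (peaked at the configured median).
#' @param ptv_cc_range Named list of c(min, max) PTV volumes in cc.
#' @param dmax_range_gy,dmin_range_gy Reference PTV max/min dose ranges, Gy.
#' @param mld_range_gy Mean lung dose range in Gy (invented default, see
#'   above).
#' @param oar_perturbation Half-width of the relative dose perturbation
#'   applied to recalculated OAR DVHs (default 0.02, i.e. +/- 2 percent).
#' @param bin_width_gy DVH dose grid resolution in Gy.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 28L, fraction_peripheral = 19 / 28,
                        seed = 1L, scheme = fractionation_scheme(60, 5),
                        delta_d95_range = list(peripheral = c(0.3, 6.5),
                                               central = c(0.6, 4.4)),
                        delta_d95_median = list(peripheral = 1.7,
                                                central = 1.0),
                        delta_d95_dist = c("uniform", "triangular"),
                        ptv_cc_range = list(peripheral = c(15.3, 107.3),
                                            central = c(19.0, 144.9)),
                        dmax_range_gy = c(63.7, 73.2),
                        dmin_range_gy = c(51.2, 57.1),
                        mld_range_gy = c(3, 8),
                        oar_perturbation = 0.02,
                        bin_width_gy = 0.1) {
  delta_d95_dist <- match.arg(delta_d95_dist)
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be a positive integer")
  if (fraction_peripheral < 0 || fraction_peripheral > 1)
    stop("fraction_peripheral must be in [0, 1]")
  for (r in c(delta_d95_range, ptv_cc_range,
              list(dmax_range_gy, dmin_range_gy, mld_range_gy)))
    if (length(r) != 2L || r[1L] > r[2L]) stop("ranges must be ordered pairs")
  stopifnot(inherits(scheme, "fractionation_scheme"), bin_width_gy > 0)
  structure(list(
    n_patients = as.integer(n_patients),
    fraction_peripheral = fraction_peripheral, seed = as.integer(seed),
    scheme = scheme, delta_d95_range = delta_d95_range,
    delta_d95_median = delta_d95_median, delta_d95_dist = delta_d95_dist,
    ptv_cc_range = ptv_cc_range, dmax_range_gy = dmax_range_gy,
    dmin_range_gy = dmin_range_gy, mld_range_gy = mld_range_gy,
    oar_perturbation = oar_perturbation, bin_width_gy = bin_width_gy),
    class = "cohort_spec")
}

.runif_range <- function(n, range) stats::runif(n, range[1L], range[2L])

# triangular draw on [a, b] with mode m, by inverse CDF
.rtri <- function(n, a, b, m) {
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

.draw_delta <- function(spec, location) {
  r <- spec$delta_d95_range[[location]]
  if (spec$delta_d95_dist == "uniform") .runif_range(1L, r)
  else .rtri(1L, r[1L], r[2L], spec$delta_d95_median[[location]])
}

#' Generate one reference/recalculated PTV DVH pair
#'
#' The reference cumulative PTV curve is a smooth monotone fall from 1 at
#' the drawn minimum dose to 0 at the drawn maximum dose, shaped so that D95
#' is exactly the prescription dose (a power-law quantile pinned at the 95
#' percent volume level). The recalculated curve applies a monotone,
#' volume-conserving dose-axis remap that lowers D95 by exactly `delta`:
#' doses at or below the prescription drop by the full delta (tapering to
#' zero below 20 Gy so the axis stays non-negative), and the drop tapers to
#' 0.2 delta at the maximum dose, so the mean drops less than D95, as paired
#' dose-engine recalculations show.
#'
#' @param spec A [cohort_spec()].
#' @param location `"peripheral"` or `"central"` (selects the delta range).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (as when called from [generate_cohort()]).
#' @param delta Optional fixed D95 drop in Gy; drawn from the location's
#'   range when `NULL`.
#' @return List with `reference` and `recalculated` `dvh` objects and the
#'   drawn `delta_d95_gy`.
#' @export
generate_ptv_pair <- function(spec, location = "peripheral", seed = NULL,
                              delta = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  rx <- spec$scheme$total_dose_gy
  dmax <- .runif_range(1L, spec$dmax_range_gy)
  dmin <- .runif_range(1L, spec$dmin_range_gy)
  if (is.null(delta)) delta <- .draw_delta(spec, location)
  if (delta < 0 || delta >= dmin)
    stop("delta would push doses negative; rejected")
  w <- spec$bin_width_gy
  edges <- seq(0, ceiling(dmax / w) * w + w, by = w)
  # power-law quantile pinned so the cumulative curve crosses 0.95 at rx
  t95 <- (rx - dmin) / (dmax - dmin)
  k <- log(t95) / log(0.05)
  u <- pmin(pmax((edges - dmin) / (dmax - dmin), 0), 1)
  cum <- 1 - u^(1 / k)
  cum[edges >= dmax] <- 0
  reference <- dvh(edges, cum, "cumulative", "ptv")
  taper <- ifelse(edges <= rx, pmin(edges / 20, 1),
                  1 - 0.8 * pmin((edges - rx) / (dmax - rx), 1))
  new_edges <- edges - delta * taper
  keep <- c(TRUE, diff(new_edges) > 1e-9)
  recalculated <- dvh(new_edges[keep], cum[keep], "cumulative", "ptv")
  list(reference = reference, recalculated = recalculated,
       delta_d95_gy = delta)
}

.oar_settings <- list(
  lung = list(cap_gy = 55, cc_range = c(2500, 4000)),
  esophagus = list(cap_gy = 33, mean_range = c(2, 6), cc_range = c(30, 60)),
  heart = list(cap_gy = 34, mean_range = c(1.5, 5), cc_range = c(400, 800)),
  cord = list(cap_gy = 27, mean_range = c(1, 4), cc_range = c(20, 50)))

#' Generate an organ-at-risk DVH (and its recalculated partner)
#'
#' OAR DVHs are exponentially decaying cumulative curves scaled to a drawn
#' mean dose and truncated (linearly renormalized to zero) at an
#' organ-specific dose cap chosen below the organ's maximum-point-dose
#' criterion, so generated plans satisfy the bundled normal-tissue
#' constraints by construction. The lung mean is drawn from the spec's
#' mean-lung-dose range; the other organs' mean ranges are fixed plausible
#' values (no data to match). The recalculated partner differs by one
#' multiplicative dose-axis perturbation drawn within
#' `+/- oar_perturbation`.
#'
#' @param organ `"lung"`, `"esophagus"`, `"heart"` or `"cord"`.
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @param paired If `TRUE` return `list(reference, recalculated)`, else a
#'   single `dvh`.
#' @return A `dvh`, or a list of two paired `dvh` objects.
#' @export
generate_oar_dvh <- function(organ = c("lung", "esophagus", "heart", "cord"),
                             spec, seed = NULL, paired = TRUE) {
  organ <- match.arg(organ)
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  st <- .oar_settings[[organ]]
  mean_range <- if (organ == "lung") spec$mld_range_gy else st$mean_range
  lambda <- .runif_range(1L, mean_range)
  cc <- .runif_range(1L, st$cc_range)
  w <- spec$bin_width_gy
  edges <- seq(0, ceiling(st$cap_gy / w) * w, by = w)
  cum <- exp(-edges / lambda)
  cum <- pmax((cum - cum[length(cum)]) / (1 - cum[length(cum)]), 0)
  reference <- dvh(edges, cum, "cumulative", organ, total_volume_cc = cc)
  if (!paired) return(reference)
  eps <- stats::runif(1L, -spec$oar_perturbation, spec$oar_perturbation)
  recalculated <- dvh(edges * (1 + eps), cum, "cumulative", organ,
                      total_volume_cc = cc)
  list(reference = reference, recalculated = recalculated)
}

#' Generate a synthetic paired-plan cohort
#'
#' Draws `n_patients` patients, assigning the first
#' `round(n * fraction_peripheral)` to peripheral tumors and the rest to
#' central, then per patient a PTV pair and the four OAR pairs. Each
#' patient's draws use a seed derived from the cohort seed and the patient
#' counter, so the cohort is reproducible and insensitive to evaluation
#' order. With `out_dir` set, writes one DVH CSV per plan, a manifest CSV
#' consumable by [run_evaluation()], and a YAML echo of the spec.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory (created if missing).
#' @return An object of class `dvh_cohort`: the spec plus a list `patients`,
#'   each with `patient_id`, `location`, `ptv_cc`, `delta_d95_gy` and named
#'   DVH lists `dvhs_ref` / `dvhs_recalc`. When files were written, the
#'   manifest path is attached as `manifest`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  n_per <- round(n * spec$fraction_peripheral)
  locations <- rep(c("peripheral", "central"), c(n_per, n - n_per))
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((spec$seed + 10007L * i) %% .Machine$integer.max)
    loc <- locations[i]
    ptv_cc <- .runif_range(1L, spec$ptv_cc_range[[loc]])
    pp <- generate_ptv_pair(spec, loc)
    oars <- lapply(c(lung = "lung", esophagus = "esophagus", heart = "heart",
                     cord = "cord"),
                   function(o) generate_oar_dvh(o, spec))
    ref <- c(list(ptv = pp$reference), lapply(oars, `[[`, "reference"))
    rec <- c(list(ptv = pp$recalculated),
             lapply(oars, `[[`, "recalculated"))
    ref$ptv$total_volume_cc <- ptv_cc
    rec$ptv$total_volume_cc <- ptv_cc
    patients[[i]] <- list(patient_id = sprintf("P%02d", i), location = loc,
                          ptv_cc = ptv_cc, delta_d95_gy = pp$delta_d95_gy,
                          dvhs_ref = ref, dvhs_recalc = rec)
  }
  cohort <- structure(list(spec = spec, patients = patients),
                      class = "dvh_cohort")
  if (!is.null(out_dir)) cohort$manifest <- .write_cohort(cohort, out_dir)
  cohort
}

.write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$patients, function(p) {
    ref_file <- paste0(p$patient_id, "_ref.csv")
    rec_file <- paste0(p$patient_id, "_recalc.csv")
    write_dvh_csv(p$dvhs_ref, file.path(out_dir, ref_file))
    write_dvh_csv(p$dvhs_recalc, file.path(out_dir, rec_file))
    data.frame(patient_id = p$patient_id, location = p$location,
               ptv_cc = p$ptv_cc, ref_dvh_path = ref_file,
               recalc_dvh_path = rec_file, stringsAsFactors = FALSE)
  })
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  spec <- cohort$spec
  echo <- list(n_patients = spec$n_patients,
               fraction_peripheral = spec$fraction_peripheral,
               seed = spec$seed,
               total_dose_gy = spec$scheme$total_dose_gy,
               n_fractions = spec$scheme$n_fractions,
               delta_d95_range = spec$delta_d95_range,
               delta_d95_dist = spec$delta_d95_dist,
               bin_width_gy = spec$bin_width_gy)
  yaml::write_yaml(echo, file.path(out_dir, "cohort_spec.yaml"))
  manifest
}

#' @export
print.dvh_cohort <- function(x, ...) {
  locs <- vapply(x$patients, `[[`, "", "location")
  cat(sprintf("<dvh_cohort> %d patients (%d peripheral / %d central), seed %d\n",
              length(x$patients), sum(locs == "peripheral"),
              sum(locs == "central"), x$spec$seed))
  invisible(x)
}
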