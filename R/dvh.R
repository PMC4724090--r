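#' Dose-volume histogram objects
#'
#' A `dvh` stores the dose distribution over one structure, either as a
#' cumulative curve (fraction of the structure receiving at least each dose,
#' one value per bin edge) or as a differential histogram (fraction of the
#' structure in each half-open dose bin `[edge_i, edge_{i+1})`, one value per
#' bin). Volumes are relative (fractions of structure volume); the absolute
#' structure volume in cc can be attached via `total_volume_cc` for
#' absolute-volume queries.
#'
#' @param dose_edges Strictly increasing numeric vector of bin edges in Gy,
#'   starting at a dose >= 0.
#' @param volume Numeric vector of volumes. In differential mode, one value
#'   per bin (length `length(dose_edges) - 1`), all >= 0, summing to 1. In
#'   cumulative mode, one value per edge, non-increasing, starting at 1 and
#'   ending at a value >= 0.
#' @param mode `"cumulative"` or `"differential"`.
#' @param structure_id Label naming the structure (e.g. `"ptv"`, `"lung"`).
#' @param total_volume_cc Optional absolute structure volume in cc.
#'
#' @return An object of class `dvh`.
#' @examples
#' # uniform 60 Gy structure, 0.2 Gy bin around the dose
#' d <- dvh(c(0, 59.9, 60.1), c(1, 1, 0), "cumulative", "ptv")
#' dose_at_volume(d, 0.95)
#' @export
dvh <- function(dose_edges, volume, mode = c("cumulative", "differential"),
                structure_id = "structure", total_volume_cc = NULL) {
  mode <- match.arg(mode)
  dose_edges <- as.numeric(dose_edges)
  volume <- as.numeric(volume)
  obj <- structure(
    list(structure_id = structure_id, dose_edges = dose_edges,
         volume = volume, mode = mode, total_volume_cc = total_volume_cc),
    class = "dvh")
  validate_dvh(obj)
  obj
}

validate_dvh <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "dvh"))
  e <- x$dose_edges
  v <- x$volume
  if (length(e) < 2L) stop("dvh: need at least two dose edges")
  if (anyNA(e) || anyNA(v)) stop("dvh: NA values not allowed")
  if (any(diff(e) <= 0)) stop("dvh: dose_edges must be strictly increasing")
  if (e[1L] < 0) stop("dvh: dose edges must be non-negative")
  if (x$mode == "differential") {
    if (length(v) != length(e) - 1L)
      stop("dvh: differential volume must have one value per bin")
    if (any(v < -tol)) stop("dvh: differential volumes must be >= 0")
    if (abs(sum(v) - 1) > 1e-6)
      stop("dvh: differential volumes must sum to 1 (got ", sum(v), ")")
  } else {
    if (length(v) != length(e))
      stop("dvh: cumulative volume must have one value per edge")
    if (any(diff(v) > tol))
      stop("dvh: cumulative volume must be non-increasing")
    if (abs(v[1L] - 1) > 1e-6)
      stop("dvh: cumulative volume must start at 1 (got ", v[1L], ")")
    if (v[length(v)] < -tol)
      stop("dvh: cumulative volume must end at a value >= 0")
  }
  invisible(x)
}

#' Bin centers of a differential DVH
#' @param x A `dvh` in differential mode (cumulative input is converted).
#' @return Numeric vector of bin-center doses in Gy.
#' @export
bin_centers <- function(x) {
  x <- to_differential(x)
  e <- x$dose_edges
  (e[-length(e)] + e[-1L]) / 2
}

#' Convert a DVH between cumulative and differential modes
#'
#' `to_differential()` takes successive differences of a cumulative curve;
#' `to_cumulative()` takes the reverse cumulative sum of a differential
#' histogram (the value at the final edge is the cumulative tail beyond the
#' last bin, zero for a DVH whose bins cover the full dose range). Both are
#' no-ops on input already in the requested mode, and are exact inverses at
#' shared edges.
#'
#' @param x A `dvh`.
#' @return A `dvh` in the requested mode.
#' @export
to_differential <- function(x) {
  validate_dvh(x)
  if (x$mode == "differential") return(x)
  v <- -diff(x$volume)
  # clamp tiny negative noise from upstream interpolation
  v[v < 0 & v > -1e-9] <- 0
  tail_mass <- x$volume[length(x$volume)]
  if (tail_mass > 1e-6)
    warning("cumulative DVH does not reach 0; tail mass ", signif(tail_mass, 3),
            " beyond last edge folded into last bin")
  v[length(v)] <- v[length(v)] + tail_mass
  dvh(x$dose_edges, v, "differential", x$structure_id, x$total_volume_cc)
}

#' @rdname to_differential
#' @export
to_cumulative <- function(x) {
  validate_dvh(x)
  if (x$mode == "cumulative") return(x)
  cum <- c(rev(cumsum(rev(x$volume))), 0)
  cum[1L] <- 1  # guard rounding of the unit sum
  dvh(x$dose_edges, cum, "cumulative", x$structure_id, x$total_volume_cc)
}

#' Dose covering a given volume fraction (Dx%)
#'
#' Returns the dose `D` such that `volume_fraction` of the structure receives
#' at least `D`, by linear interpolation on the cumulative curve. Where the
#' cumulative curve is flat at the requested fraction, the highest such dose
#' is returned. `D95 = dose_at_volume(x, 0.95)`.
#'
#' @param x A `dvh`.
#' @param volume_fraction Fraction in (0, 1].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(x, volume_fraction) {
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      volume_fraction <= 0 || volume_fraction > 1)
    stop("volume_fraction must be a single number in (0, 1]")
  x <- to_cumulative(x)
  e <- x$dose_edges
  cum <- x$volume
  k <- length(e)
  if (cum[k] >= volume_fraction) return(e[k])
  i <- max(which(cum >= volume_fraction))
  if (i == k) return(e[k])
  drop <- cum[i] - cum[i + 1L]
  if (drop <= 0) return(e[i])
  e[i] + (cum[i] - volume_fraction) / drop * (e[i + 1L] - e[i])
}

#' Volume receiving at least a given dose (Vx)
#'
#' Fraction (or, with `absolute = TRUE`, cc) of the structure receiving at
#' least `dose_gy`, by linear interpolation on the cumulative curve.
#'
#' @param x A `dvh`.
#' @param dose_gy Dose threshold in Gy, >= 0.
#' @param absolute If `TRUE`, return cc via `total_volume_cc` (which must be
#'   set).
#' @return Volume fraction in `[0, 1]`, or cc.
#' @export
volume_at_dose <- function(x, dose_gy, absolute = FALSE) {
  if (!is.numeric(dose_gy) || length(dose_gy) != 1L || dose_gy < 0)
    stop("dose_gy must be a single non-negative number")
  x <- to_cumulative(x)
  e <- x$dose_edges
  cum <- x$volume
  frac <- if (dose_gy <= e[1L]) {
    1
  } else if (dose_gy >= e[length(e)]) {
    if (dose_gy > e[length(e)]) 0 else cum[length(cum)]
  } else {
    stats::approx(e, cum, xout = dose_gy, method = "linear")$y
  }
  if (absolute) {
    if (is.null(x$total_volume_cc))
      stop("absolute volume requested but total_volume_cc is not set for ",
           x$structure_id)
    frac * x$total_volume_cc
  } else {
    frac
  }
}

#' Dose metrics of a DVH
#'
#' Mean dose (volume-weighted mean of differential bin centers), maximum and
#' minimum dose (upper/lower edge of the highest/lowest bin with nonzero
#' volume, i.e. at bin-edge resolution) and D95 in Gy.
#'
#' @param object A `dvh`.
#' @param ... Unused.
#' @return A named list with elements `mean_gy`, `max_gy`, `min_gy`, `d95_gy`.
#' @export
summary.dvh <- function(object, ...) {
  d <- to_differential(object)
  v <- d$volume
  if (sum(v) <= 0) stop("empty DVH: no volume recorded")
  centers <- bin_centers(d)
  nz <- which(v > 1e-12)
  out <- list(
    mean_gy = sum(v * centers) / sum(v),
    max_gy = d$dose_edges[max(nz) + 1L],
    min_gy = d$dose_edges[min(nz)],
    d95_gy = dose_at_volume(d, 0.95))
  class(out) <- "summary.dvh"
  out
}

#' @export
print.summary.dvh <- function(x, ...) {
  cat(sprintf("mean %.2f Gy | D95 %.2f Gy | min %.2f Gy | max %.2f Gy\n",
              x$mean_gy, x$d95_gy, x$min_gy, x$max_gy))
  invisible(x)
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s (%s), %d edges, %.1f-%.1f Gy%s\n",
              x$structure_id, x$mode, length(x$dose_edges),
              x$dose_edges[1L], x$dose_edges[length(x$dose_edges)],
              if (!is.null(x$total_volume_cc))
                sprintf(", %.1f cc", x$total_volume_cc) else ""))
  invisible(x)
}

#' @export
plot.dvh <- function(x, ..., xlab = "Dose (Gy)",
                     ylab = "Volume fraction ≥ dose", type = "l") {
  cx <- to_cumulative(x)
  graphics::plot(cx$dose_edges, cx$volume, type = type, xlab = xlab,
                 ylab = ylab, main = x$structure_id, ...)
  invisible(x)
}

#' Build a DVH from an explicit list of voxel doses
#'
#' Each dose becomes the center of its own narrow bin, so bin-center
#' computations (mean, EUD, TCP products) on the resulting DVH match
#' per-voxel brute force exactly. Duplicate doses accumulate volume.
#'
#' @param doses_gy Numeric vector of per-voxel doses in Gy.
#' @param weights Optional relative volumes per voxel (default equal); will be
#'   normalized to sum to 1.
#' @param bin_width Width in Gy of the bin placed around each distinct dose.
#'   Must be smaller than the smallest gap between distinct doses.
#' @param structure_id,total_volume_cc Passed to [dvh()].
#' @return A differential `dvh`.
#' @export
dvh_from_doses <- function(doses_gy, weights = NULL, bin_width = 0.01,
                           structure_id = "structure",
                           total_volume_cc = NULL) {
  if (length(doses_gy) == 0L) stop("doses_gy must be nonempty")
  if (any(doses_gy < 0)) stop("doses must be non-negative")
  if (is.null(weights)) weights <- rep(1, length(doses_gy))
  stopifnot(length(weights) == length(doses_gy), all(weights >= 0))
  w <- weights / sum(weights)
  agg <- tapply(w, factor(doses_gy, levels = sort(unique(doses_gy))), sum)
  ds <- as.numeric(names(agg))
  if (length(ds) > 1L && min(diff(ds)) < bin_width)
    stop("bin_width must be smaller than the smallest gap between doses")
  h <- bin_width / 2
  edges <- as.numeric(rbind(ds - h, ds + h))
  vols <- numeric(length(edges) - 1L)
  vols[seq(1L, length(vols), by = 2L)] <- as.numeric(agg)
  edges[1L] <- max(0, edges[1L])  # a zero-dose voxel gets the bin [0, h)
  dvh(edges, vols, "differential", structure_id, total_volume_cc)
}
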