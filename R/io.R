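#' Read and write plan DVH files (CSV schema)
#'
#' One CSV per plan, columns `structure,mode,dose_gy,volume`, any number of
#' structures per file. For cumulative structures each row is a (bin edge,
#' fraction receiving >= dose) pair. For differential structures each row is
#' a (bin lower edge, bin volume fraction) pair, with a terminal zero-volume
#' row carrying the last bin's upper edge. Absolute structure volumes travel
#' in comment lines of the form `# structure=<name> volume_cc=<v>`.
#' `write_dvh_csv()` always emits cumulative mode, which is lossless per
#' edge; the reader accepts both modes.
#'
#' @param path File path.
#' @param dvhs Named list of `dvh` objects (names are ignored in favour of
#'   each object's `structure_id`).
#' @return `read_dvh_csv()`: a named list of `dvh` objects, keyed by
#'   structure id. `write_dvh_csv()`: `path`, invisibly.
#' @export
read_dvh_csv <- function(path) {
  if (!file.exists(path)) stop("DVH file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vol_cc <- .parse_volume_comments(lines[startsWith(trimws(lines), "#")])
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("malformed DVH file (no data rows): ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("structure", "mode", "dose_gy", "volume")
  if (!all(need %in% names(df)))
    stop("malformed DVH file (missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), "): ", path)
  out <- list()
  for (nm in unique(df$structure)) {
    sub <- df[df$structure == nm, , drop = FALSE]
    mode <- unique(sub$mode)
    if (length(mode) != 1L)
      stop("structure '", nm, "' has mixed modes in ", path)
    cc <- if (nm %in% names(vol_cc)) vol_cc[[nm]] else NULL
    out[[nm]] <- if (mode == "cumulative") {
      dvh(sub$dose_gy, sub$volume, "cumulative", nm, cc)
    } else {
      k <- nrow(sub)
      if (abs(sub$volume[k]) > 1e-9)
        warning("differential structure '", nm, "' in ", path,
                " lacks a zero-volume terminal row; last volume dropped")
      dvh(sub$dose_gy, sub$volume[-k], "differential", nm, cc)
    }
  }
  out
}

.parse_volume_comments <- function(comment_lines) {
  out <- list()
  for (ln in comment_lines) {
    m <- regmatches(ln, regexec(
      "structure=([^ ]+)\\s+volume_cc=([0-9.eE+-]+)", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- as.numeric(m[3])
  }
  out
}

#' @rdname read_dvh_csv
#' @export
write_dvh_csv <- function(dvhs, path) {
  stopifnot(is.list(dvhs), length(dvhs) > 0L)
  con <- file(path, "w")
  on.exit(close(con))
  for (d in dvhs) {
    if (!is.null(d$total_volume_cc))
      writeLines(sprintf("# structure=%s volume_cc=%.6g", d$structure_id,
                         d$total_volume_cc), con)
  }
  writeLines("structure,mode,dose_gy,volume", con)
  for (d in dvhs) {
    cx <- to_cumulative(d)
    writeLines(sprintf("%s,cumulative,%.10g,%.10g", cx$structure_id,
                       cx$dose_edges, cx$volume), con)
  }
  invisible(path)
}

#' Read an Eclipse-style plain-text DVH export
#'
#' Parses the treatment-planning-system text dialect: blocks introduced by a
#' line starting `Structure:`, followed (possibly after other header lines,
#' e.g. `Volume [cm³]: <v>`) by a table whose header row names a `Dose` and
#' a `Volume` column. Units are auto-detected from the header: doses in
#' `cGy` are converted to Gy (x 0.01); volumes in `%` are converted to
#' fractions (/ 100); absolute volumes (`cm3`) are normalized by their
#' maximum, which is recorded as `total_volume_cc`. Curves are read as
#' cumulative DVHs.
#'
#' @param path File path.
#' @return Named list of cumulative `dvh` objects.
#' @export
read_dvh_eclipse <- function(path) {
  if (!file.exists(path)) stop("DVH file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\s*Structure\\s*:", lines)
  if (!length(starts)) stop("no 'Structure:' blocks found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    nm <- trimws(sub("^\\s*Structure\\s*:", "", block[1L]))
    cc <- NA_real_
    vline <- grep("^\\s*Volume\\s*\\[(cm|cc)", block, value = TRUE)
    if (length(vline))
      cc <- as.numeric(sub(".*:\\s*([0-9.eE+-]+).*", "\\1", vline[1L]))
    hdr <- grep("Dose", block)
    hdr <- hdr[grepl("Volume|Ratio", block[hdr])]
    if (!length(hdr)) stop("no Dose/Volume table header for structure '", nm,
                           "' in ", path)
    hdr <- hdr[1L]
    hline <- block[hdr]
    dose_scale <- if (grepl("cGy", hline)) 0.01 else 1
    vol_percent <- grepl("%", hline)
    rows <- block[(hdr + 1L):length(block)]
    rows <- rows[grepl("^\\s*-?[0-9]", rows)]
    if (!length(rows)) stop("empty DVH table for structure '", nm, "'")
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), function(f)
      as.numeric(f[1:2])))
    dose <- mat[, 1L] * dose_scale
    vol <- mat[, 2L]
    if (vol_percent) {
      vol <- vol / 100
    } else if (max(vol) > 1 + 1e-9) {  # absolute cm3 table
      if (is.na(cc)) cc <- max(vol)
      vol <- vol / max(vol)
    }
    vol <- vol / vol[1L]  # guard rounding of the 100% row
    out[[nm]] <- dvh(dose, vol, "cumulative", nm,
                     if (is.na(cc)) NULL else cc)
  }
  out
}

#' Read and write a cohort manifest
#'
#' The manifest is a CSV with columns
#' `patient_id,location,ptv_cc,ref_dvh_path,recalc_dvh_path`; DVH paths are
#' resolved relative to the manifest's directory.
#'
#' @param path Manifest path.
#' @return A data frame with the manifest columns plus `ref_dvh_path` and
#'   `recalc_dvh_path` resolved to absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "location", "ptv_cc", "ref_dvh_path",
            "recalc_dvh_path")
  if (!all(need %in% names(df)))
    stop("malformed manifest (missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), "): ", path)
  base <- dirname(normalizePath(path))
  for (col in c("ref_dvh_path", "recalc_dvh_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  df
}
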