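## 30-2 visual-field grid, SAP exams, reliability filtering.

#' Build the 30-2 visual-field test grid
#'
#' Returns the standard 76-point 30-2 lattice in the tested eye's field
#' orientation: test locations at odd multiples of 3 degrees (+-3 ... +-27)
#' with the four extreme corner blocks absent, indexed 1..76 row-major from
#' the most superior row, nasal to temporal within each row (right-eye
#' orientation).  With this convention the two blind-spot locations - the
#' pair straddling the horizontal meridian on the temporal side at
#' (x, y) = (+15, +-3) for a right eye - receive indices 36 and 46.
#'
#' `x_deg` is positive temporal for the tested eye and `y_deg` positive
#' superior, so `vf_build_grid("left")` is the point-for-point x-mirror of
#' `vf_build_grid("right")` and carries its blind spot at (-15, +-3).
#'
#' @param eye `"right"` or `"left"`.
#' @return A data.frame with columns `index`, `x_deg`, `y_deg`,
#'   `is_blind_spot` (76 rows).
#' @export
vf_build_grid <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  half_widths <- c(9, 15, 21, 27, 27)      # rows y = 27, 21, 15, 9, 3
  ys <- c(seq(27, 3, by = -6), seq(-3, -27, by = -6))
  rows <- lapply(ys, function(y) {
    hw <- half_widths[match(abs(y), c(27, 21, 15, 9, 3))]
    x <- seq(-hw, hw, by = 6)
    x <- x[x != 0]                          # lattice is at odd multiples of 3
    data.frame(x_deg = x, y_deg = y)
  })
  g <- do.call(rbind, rows)
  g$index <- seq_len(nrow(g))
  g$is_blind_spot <- g$x_deg == 15 & abs(g$y_deg) == 3
  if (eye == "left") g$x_deg <- -g$x_deg
  g[, c("index", "x_deg", "y_deg", "is_blind_spot")]
}

## Map indices of a left-eye grid onto the mirrored (right-orientation) grid.
mirror_index_map <- function() {
  right <- vf_build_grid("right")
  left <- vf_build_grid("left")
  match(paste(-left$x_deg, left$y_deg), paste(right$x_deg, right$y_deg))
}

#' Construct a visual-field exam record
#'
#' Holds per-location total deviations (focal visual-field deviation, fVFD,
#' in dB) together with the reliability indices used for quality control.
#' Left-eye exams are mirrored into right-eye field orientation at ingest so
#' all downstream code handles a single orientation.
#'
#' @param subject_id Character scalar.
#' @param eye `"right"` or `"left"` (orientation of the supplied `td`).
#' @param td Named numeric vector of total deviations (dB), names are grid
#'   indices in the supplied eye's orientation.
#' @param md Mean deviation (dB); if `NULL`, the unweighted mean of `td`
#'   over non-blind-spot locations is used as a stand-in.
#' @param fixation_loss_frac,fp_frac,fn_frac Reliability fractions in \[0, 1\].
#' @return An object of class `vf_exam`, always in right-eye orientation.
#' @export
vf_exam <- function(subject_id, eye, td, md = NULL,
                    fixation_loss_frac, fp_frac, fn_frac) {
  eye <- match.arg(eye, c("right", "left"))
  for (nm in c("fixation_loss_frac", "fp_frac", "fn_frac")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v < 0 || v > 1)
      stopf("%s must be a fraction in [0, 1]", nm)
  }
  if (is.null(names(td))) names(td) <- seq_along(td)
  idx <- as.integer(names(td))
  if (anyNA(idx) || any(idx < 1L | idx > 76L))
    stopf("td names must be grid indices in 1..76")
  bad <- td[!is.na(td) & (td < -40 | td > 10)]
  if (length(bad))
    stopf("total deviations outside plausible range [-40, 10] dB: %s",
          paste(round(bad, 1), collapse = ", "))
  if (eye == "left") {           # mirror to right-eye orientation
    m <- mirror_index_map()
    idx <- m[idx]
    ord <- order(idx)
    td <- stats::setNames(as.numeric(td)[ord], idx[ord])
  } else {
    td <- stats::setNames(as.numeric(td), idx)
  }
  grid <- vf_build_grid("right")
  if (is.null(md)) {
    keep <- !grid$is_blind_spot[as.integer(names(td))]
    md <- mean(td[keep], na.rm = TRUE)
  }
  structure(list(subject_id = as.character(subject_id), eye = eye, td = td,
                 md = md, fixation_loss_frac = fixation_loss_frac,
                 fp_frac = fp_frac, fn_frac = fn_frac),
            class = "vf_exam")
}

#' @export
print.vf_exam <- function(x, ...) {
  cat(sprintf("<vf_exam> subject %s (%s eye, mirrored to right orientation)\n",
              x$subject_id, x$eye))
  cat(sprintf("  %d locations, MD = %.2f dB; FL %.0f%%, FP %.0f%%, FN %.0f%%\n",
              length(x$td), x$md, 100 * x$fixation_loss_frac,
              100 * x$fp_frac, 100 * x$fn_frac))
  invisible(x)
}

#' Check SAP reliability criteria
#'
#' An exam passes when fixation losses are below 33% and both false-positive
#' and false-negative error rates are below 20% (all strict inequalities).
#'
#' @param exam A [vf_exam] object, or a list carrying the three fraction
#'   fields.
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty when passing).
#' @export
vf_check_reliability <- function(exam) {
  need <- c("fixation_loss_frac", "fp_frac", "fn_frac")
  miss <- need[!vapply(need, function(nm) !is.null(exam[[nm]]) &&
                         !is.na(exam[[nm]]), TRUE)]
  if (length(miss))
    stopf("reliability index missing from exam: %s", paste(miss, collapse = ", "))
  reasons <- character(0)
  if (!(exam$fixation_loss_frac < 0.33)) reasons <- c(reasons, "fixation losses")
  if (!(exam$fp_frac < 0.20)) reasons <- c(reasons, "false-positive errors")
  if (!(exam$fn_frac < 0.20)) reasons <- c(reasons, "false-negative errors")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Analysis locations of the 30-2 grid
#'
#' The grid minus the blind-spot pair minus any configured extra exclusions.
#' The default configuration excludes only the blind spot (74 locations);
#' a study wishing to analyse 73 locations supplies one extra index.
#'
#' @param grid Output of [vf_build_grid()].
#' @param exclude Integer vector of extra grid indices to drop.
#' @return The subset of `grid` rows retained for analysis.
#' @export
vf_analysis_locations <- function(grid, exclude = integer(0)) {
  if (length(exclude) && !all(exclude %in% grid$index))
    stopf("exclusions not in grid: %s",
          paste(setdiff(exclude, grid$index), collapse = ", "))
  out <- grid[!grid$is_blind_spot & !(grid$index %in% exclude), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write SAP exports
#'
#' The CSV dialect has columns `subject_id, eye, loc_index, x_deg, y_deg,
#' td_db`; the companion JSON holds `md`, `fixation_loss`, `fp`, `fn` per
#' subject.
#'
#' @param csv_path,json_path Paths to the per-location CSV and the
#'   per-subject JSON index.
#' @return `read_sap()`: a named list of [vf_exam] objects (right-eye
#'   orientation).
#' @export
read_sap <- function(csv_path, json_path) {
  if (!file.exists(csv_path)) stopf("SAP csv not found: %s", csv_path)
  if (!file.exists(json_path)) stopf("SAP json not found: %s", json_path)
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  out <- list()
  for (sid in unique(tab$subject_id)) {
    rows <- tab[tab$subject_id == sid, ]
    m <- meta[[as.character(sid)]]
    if (is.null(m)) stopf("subject %s present in csv but not in json", sid)
    out[[as.character(sid)]] <- vf_exam(
      subject_id = sid, eye = rows$eye[1],
      td = stats::setNames(rows$td_db, rows$loc_index),
      md = m$md, fixation_loss_frac = m$fixation_loss,
      fp_frac = m$fp, fn_frac = m$fn)
  }
  out
}

#' @rdname read_sap
#' @param exams Named list of [vf_exam] objects.
#' @export
write_sap <- function(exams, csv_path, json_path) {
  grid <- vf_build_grid("right")
  rows <- do.call(rbind, lapply(exams, function(e) {
    idx <- as.integer(names(e$td))
    data.frame(subject_id = e$subject_id, eye = "right", loc_index = idx,
               x_deg = grid$x_deg[idx], y_deg = grid$y_deg[idx],
               td_db = as.numeric(e$td))
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  meta <- lapply(exams, function(e)
    list(md = e$md, fixation_loss = e$fixation_loss_frac,
         fp = e$fp_frac, fn = e$fn_frac))
  names(meta) <- vapply(exams, function(e) e$subject_id, "")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
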