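## Focal and global capillary density and RNFL thickness.

#' Focal capillary density in a wedge ROI
#'
#' The proportion of perfused pixels in the ROI.  By default the denominator
#' excludes large-vessel pixels, so the measure is a capillary density
#' rather than a total vascular density;
#' `include_large_vessel_area = TRUE` restores the literal
#' "proportion of white pixels in the ROI" reading.
#'
#' @param map A `perfusion_map` (normalized frame).
#' @param roi A `wedge_roi` whose `pixel_mask` matches the map shape.
#' @param include_large_vessel_area Keep large-vessel pixels in the
#'   denominator.
#' @return Fraction in \[0, 1\], or `NA_real_` (flagged missing) when the
#'   denominator is empty.
#' @export
focal_cd <- function(map, roi, include_large_vessel_area = FALSE) {
  stopifnot(inherits(map, "perfusion_map"), inherits(roi, "wedge_roi"))
  if (!all(dim(roi$pixel_mask) == dim(map$perfused)))
    stopf("ROI mask shape %s does not match map %s",
          paste(dim(roi$pixel_mask), collapse = "x"),
          paste(dim(map$perfused), collapse = "x"))
  denom_mask <- if (include_large_vessel_area) roi$pixel_mask
                else roi$pixel_mask & !map$large_vessel_mask
  denom <- sum(denom_mask)
  if (denom == 0L) return(NA_real_)      # flagged missing, never 0
  sum(map$perfused & denom_mask) / denom
}

#' Focal RNFL thickness over a ring arc
#'
#' Arithmetic mean of the thickness samples whose angle falls in the
#' half-open arc `[lo, hi)` (unwrapped across 0/360, so adjacent arcs
#' partition the circle).
#'
#' @param profile An [rnfl_profile].
#' @param arc Numeric length 2, `c(lo, hi)` in degrees with `hi > lo`
#'   (values outside \[0, 360) allowed; the arc may wrap).
#' @return Mean thickness in micrometres.
#' @export
focal_rnflt <- function(profile, arc) {
  stopifnot(inherits(profile, "rnfl_profile"))
  width <- arc[2] - arc[1]
  if (!is.finite(width) || width <= 0) stopf("arc width must be positive")
  if (width >= 360) return(mean(profile$thickness_um))
  rel <- wrap360(profile$angle_deg - arc[1])
  inarc <- rel < width
  if (!any(inarc))
    stopf("no profile samples in arc [%.2f, %.2f): arc narrower than the sampling step",
          arc[1], arc[2])
  mean(profile$thickness_um[inarc])
}

#' Global capillary density and RNFL thickness
#'
#' Global CD is the perfused fraction over the whole normalized frame,
#' excluding the large-vessel mask and (by default) a central disc mask;
#' global RNFL-T is the mean of the full circumpapillary profile.
#'
#' @param map A normalized `perfusion_map`.
#' @param profile An [rnfl_profile].
#' @param disc_mask Logical matrix marking the optic-disc region, or `NULL`
#'   to build a central disc of radius `disc_radius_mm`; set
#'   `disc_radius_mm = 0` to disable disc exclusion.
#' @param disc_radius_mm Radius of the default central disc mask.
#' @return `list(global_cd, global_rnflt)`.
#' @export
global_metrics <- function(map, profile, disc_mask = NULL, disc_radius_mm = 0.9) {
  stopifnot(inherits(map, "perfusion_map"))
  dims <- dim(map$perfused)
  if (is.null(disc_mask)) {
    if (disc_radius_mm > 0) {
      cx <- (dims[2] + 1) / 2; cy <- (dims[1] + 1) / 2
      r_px <- disc_radius_mm / map$mm_per_px
      disc_mask <- outer(seq_len(dims[1]), seq_len(dims[2]),
                         function(i, j) (i - cy)^2 + (j - cx)^2 <= r_px^2)
    } else disc_mask <- matrix(FALSE, dims[1], dims[2])
  }
  keep <- !disc_mask & !map$large_vessel_mask
  list(global_cd = sum(map$perfused & keep) / sum(keep),
       global_rnflt = if (is.null(profile)) NA_real_
                      else mean(profile$thickness_um))
}

#' Assemble the analysis table of focal records
#'
#' One row per (subject, analysis location) holding the three focal values:
#' fVFD (dB), fCD (fraction) and fRNFL-T (um).  Rows with any flagged
#' missing value are dropped and reported via the `"dropped"` attribute and
#' a message.
#'
#' @param exams Named list of [vf_exam] (names = subject ids).
#' @param maps Named list of normalized `perfusion_map`s.
#' @param profiles Named list of [rnfl_profile]s.
#' @param rois Named list (per subject) of wedge lists from
#'   [build_all_wedges()].
#' @param include_large_vessel_area Passed to [focal_cd()].
#' @return data.frame `subject_id, location_index, fVFD, fCD, fRNFLT`.
#' @export
assemble_records <- function(exams, maps, profiles, rois,
                             include_large_vessel_area = FALSE) {
  ids <- names(exams)
  mism <- c(setdiff(ids, names(maps)), setdiff(names(maps), ids),
            setdiff(ids, names(profiles)), setdiff(names(profiles), ids),
            setdiff(ids, names(rois)), setdiff(names(rois), ids))
  if (length(mism))
    stopf("subjects present in one input stream only: %s",
          paste(unique(mism), collapse = ", "))
  rows <- list(); dropped <- list()
  for (sid in ids) {
    exam <- exams[[sid]]
    for (w in rois[[sid]]) {
      li <- w$location_index
      fvfd <- unname(exam$td[as.character(li)])
      fcd <- focal_cd(maps[[sid]], w, include_large_vessel_area)
      frnflt <- tryCatch(focal_rnflt(profiles[[sid]], w$ring_arc),
                         error = function(e) NA_real_)
      row <- data.frame(subject_id = sid, location_index = li,
                        fVFD = if (is.null(fvfd)) NA_real_ else fvfd,
                        fCD = fcd, fRNFLT = frnflt)
      if (anyNA(row[, c("fVFD", "fCD", "fRNFLT")])) dropped[[length(dropped) + 1L]] <- row
      else rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), location_index = integer(0),
               fVFD = numeric(0), fCD = numeric(0), fRNFLT = numeric(0))
  rownames(out) <- NULL
  if (length(dropped)) {
    dr <- do.call(rbind, dropped)
    message(sprintf("assemble_records: dropped %d row(s) with missing focal values",
                    nrow(dr)))
    attr(out, "dropped") <- dr
  }
  out
}
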