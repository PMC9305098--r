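## OCT-A en-face slab preprocessing: binarization, Frangi-based large-vessel
## isolation, vessel removal, and normalization of the physical scale to the
## common analysis frame (4.11 mm over 960 pixels).

#' Construct an en-face OCT-A image
#'
#' @param pixels Numeric matrix (grayscale, values in \[0, 1\]).
#' @param mm_per_px Isotropic physical scale. If `NULL`, derived from
#'   `field_deg` via [mm_per_degree()] and the image width.
#' @param field_deg Angular field of view (degrees), used only when
#'   `mm_per_px` is missing.
#' @return Object of class `octa_image`.
#' @export
octa_image <- function(pixels, mm_per_px = NULL, field_deg = NULL) {
  if (!is.matrix(pixels) || !nrow(pixels) || !ncol(pixels))
    stopf("pixels must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  if (is.null(mm_per_px)) {
    if (is.null(field_deg))
      stopf("either mm_per_px or field_deg must be given")
    mm_per_px <- field_deg * mm_per_degree() / ncol(pixels)
  }
  if (!is_scalar_num(mm_per_px) || mm_per_px <= 0)
    stopf("mm_per_px must be a positive scalar")
  if (is.null(field_deg)) field_deg <- ncol(pixels) * mm_per_px / mm_per_degree()
  structure(list(pixels = pixels, mm_per_px = mm_per_px,
                 field_deg = field_deg), class = "octa_image")
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf("<octa_image> %d x %d px, %.4f mm/px (%.2f mm, %.1f deg field)\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_px,
              ncol(x$pixels) * x$mm_per_px, x$field_deg))
  invisible(x)
}

## Local mean over a w x w window via integral image; windows are clipped at
## the borders (true mean over the intersection).
local_mean <- function(mat, w) {
  h <- w %/% 2
  nr <- nrow(mat); nc <- ncol(mat)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(mat, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  sums <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / cnt
}

#' Binarize an OCT-A image
#'
#' Local adaptive thresholding: a pixel is perfused when it exceeds the mean
#' of its neighbourhood (default window 0.1 mm) by `offset` gray levels
#' (image scaled to \[0, 1\]).
#'
#' @param img An [octa_image].
#' @param window_mm Side of the averaging window in mm.
#' @param offset Threshold offset above the local mean.
#' @return Logical matrix (`TRUE` = perfused).
#' @export
octa_binarize <- function(img, window_mm = 0.1, offset = 0.02) {
  stopifnot(inherits(img, "octa_image"))
  px <- img$pixels
  if (max(px) == min(px)) {
    warnf("constant image: binarization returns all-background")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  w <- max(3L, as.integer(round(window_mm / img$mm_per_px)))
  if (w %% 2L == 0L) w <- w + 1L
  px > local_mean(px, w) + offset
}

## FFT Gaussian blur with replicate padding (no wrap-around artefacts).
gauss_blur <- function(mat, sigma_px) {
  pad <- ceiling(3 * sigma_px)
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- pmin(pmax(seq(1L - pad, nr + pad), 1L), nr)
  ci <- pmin(pmax(seq(1L - pad, nc + pad), 1L), nc)
  P <- mat[ri, ci]
  NR <- nrow(P); NC <- ncol(P)
  gr <- pmin(0:(NR - 1L), NR - 0:(NR - 1L))
  gc <- pmin(0:(NC - 1L), NC - 0:(NC - 1L))
  kr <- exp(-gr^2 / (2 * sigma_px^2)); kr <- kr / sum(kr)
  kc <- exp(-gc^2 / (2 * sigma_px^2)); kc <- kc / sum(kc)
  K <- outer(kr, kc)
  sm <- Re(stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE)) / (NR * NC)
  sm[pad + seq_len(nr), pad + seq_len(nc)]
}

## Scale-normalized Hessian of a smoothed image via central differences.
hessian_at_scale <- function(mat, sigma_px) {
  S <- gauss_blur(mat, sigma_px)
  nr <- nrow(S); nc <- ncol(S)
  up <- S[c(1L, seq_len(nr - 1L)), ]; dn <- S[c(seq_len(nr - 1L) + 1L, nr), ]
  lf <- S[, c(1L, seq_len(nc - 1L))]; rt <- S[, c(seq_len(nc - 1L) + 1L, nc)]
  Dyy <- up + dn - 2 * S
  Dxx <- lf + rt - 2 * S
  Dxy <- (S[c(seq_len(nr - 1L) + 1L, nr), c(seq_len(nc - 1L) + 1L, nc)] +
          S[c(1L, seq_len(nr - 1L)), c(1L, seq_len(nc - 1L))] -
          S[c(seq_len(nr - 1L) + 1L, nr), c(1L, seq_len(nc - 1L))] -
          S[c(1L, seq_len(nr - 1L)), c(seq_len(nc - 1L) + 1L, nc)]) / 4
  s2 <- sigma_px^2
  list(xx = Dxx * s2, yy = Dyy * s2, xy = Dxy * s2)
}

#' Frangi vesselness of a grayscale image
#'
#' Hessian-eigenvalue vesselness for bright tubular structures on a dark
#' background, maximized over scales and normalized to \[0, 1\] by the
#' per-image maximum.
#'
#' @param img An [octa_image].
#' @param scales_mm Gaussian scales (vessel radius, mm).
#' @param beta Blob-discrimination sensitivity.
#' @param c Structure-strength sensitivity; default half the maximum Frobenius
#'   norm of the Hessian at each scale.
#' @return Numeric matrix of vesselness in \[0, 1\].
#' @export
octa_frangi_vesselness <- function(img, scales_mm = c(0.03, 0.06, 0.09, 0.12),
                                   beta = 0.5, c = NULL) {
  stopifnot(inherits(img, "octa_image"))
  if (!length(scales_mm)) stopf("empty scale list")
  best <- matrix(0, nrow(img$pixels), ncol(img$pixels))
  for (s in scales_mm) {
    H <- hessian_at_scale(img$pixels, s / img$mm_per_px)
    d <- (H$xx - H$yy) / 2
    tmp <- sqrt(d^2 + H$xy^2)
    m <- (H$xx + H$yy) / 2
    e1 <- m + tmp; e2 <- m - tmp
    swap <- abs(e1) > abs(e2)          # order |l1| <= |l2|
    l1 <- ifelse(swap, e2, e1); l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    cs <- if (is.null(c)) max(sqrt(S2)) / 2 else c
    if (cs <= 0) next
    Rb2 <- (l1 / ifelse(l2 == 0, .Machine$double.eps, l2))^2
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cs^2)))
    v[l2 >= 0] <- 0                    # bright vessels: large negative l2
    ## suppress the border band where the padded Hessian is unreliable
    mar <- min(ceiling(2 * s / img$mm_per_px) + 2L, floor(min(dim(v)) / 4))
    v[c(seq_len(mar), nrow(v) - seq_len(mar) + 1L), ] <- 0
    v[, c(seq_len(mar), ncol(v) - seq_len(mar) + 1L)] <- 0
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best
}

#' Isolate large retinal vessels
#'
#' Thresholds the multi-scale Frangi vesselness (lightly smoothed so the
#' response does not dip where capillary texture crosses a vessel) and
#' gates the resulting region by the bright (binarized) pixels, so the mask
#' takes the vessel's true width rather than the broader vesselness
#' support.  The scale set (default 0.03-0.12 mm) targets the large arcade
#' vessels rather than the capillary texture.
#'
#' @inheritParams octa_frangi_vesselness
#' @param vesselness_threshold Threshold on the normalized vesselness.
#' @param smooth_mm Gaussian smoothing of the vesselness response before
#'   thresholding (0 disables).
#' @param gate_brightness Intersect the vesselness region with the
#'   binarized image.
#' @return Logical matrix (`TRUE` = large vessel).
#' @export
octa_isolate_large_vessels <- function(img,
                                       scales_mm = c(0.03, 0.06, 0.09, 0.12),
                                       vesselness_threshold = 0.5,
                                       beta = 0.5, c = NULL,
                                       smooth_mm = 0.03,
                                       gate_brightness = TRUE) {
  v <- octa_frangi_vesselness(img, scales_mm, beta = beta, c = c)
  if (smooth_mm > 0 && max(v) > 0) {
    v <- gauss_blur(v, smooth_mm / img$mm_per_px)
    v <- v / max(v)
  }
  mask <- v >= vesselness_threshold & v > 0
  if (gate_brightness && any(mask)) {
    bright <- suppressWarnings(octa_binarize(img))
    mask <- mask & bright
  }
  mask
}

#' Remove large vessels from a binarized map
#'
#' @param binary Logical matrix from [octa_binarize()].
#' @param mask Logical large-vessel mask of the same shape.
#' @param mm_per_px Physical scale of both.
#' @return A `perfusion_map`: `perfused` (= binary AND NOT mask),
#'   `large_vessel_mask` (retained so downstream density denominators can
#'   exclude it), `mm_per_px`.
#' @export
octa_remove_large_vessels <- function(binary, mask, mm_per_px) {
  if (!all(dim(binary) == dim(mask)))
    stopf("shape mismatch: binary %s vs mask %s",
          paste(dim(binary), collapse = "x"), paste(dim(mask), collapse = "x"))
  structure(list(perfused = binary & !mask, large_vessel_mask = mask,
                 mm_per_px = mm_per_px), class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  cat(sprintf("<perfusion_map> %d x %d px, %.5f mm/px, %.1f%% perfused, %.1f%% large vessel\n",
              nrow(x$perfused), ncol(x$perfused), x$mm_per_px,
              100 * mean(x$perfused), 100 * mean(x$large_vessel_mask)))
  invisible(x)
}

## Binary dilation by k pixels (8-neighbourhood, iterated).
dilate_mask <- function(mask, k) {
  for (i in seq_len(k)) mask <- local_mean(mask * 1, 3L) > 0
  mask
}

## Nearest-neighbour resample of a matrix to target_px covering target_mm,
## centred on the source centre.
resample_nn <- function(mat, src_mm_per_px, target_mm, target_px) {
  out_res <- target_mm / target_px
  idx <- function(n_src) {
    phys <- (seq_len(target_px) - (target_px + 1) / 2) * out_res
    i <- round(phys / src_mm_per_px + (n_src + 1) / 2)
    as.integer(pmin(pmax(i, 1L), n_src))
  }
  mat[idx(nrow(mat)), idx(ncol(mat)), drop = FALSE]
}

#' Normalize a perfusion map to the common analysis frame
#'
#' Rescales and crops (nearest neighbour, so no gray levels are
#' reintroduced) to exactly `target_px` x `target_px` covering `target_mm` x
#' `target_mm` centred on the input centre; by default 4.11 mm over 960
#' pixels.
#'
#' @param map A `perfusion_map` (or an [octa_image]).
#' @param target_mm,target_px Target physical extent and pixel count.
#' @return Same class as the input, normalized. Already-normalized input is
#'   returned bit-identically.
#' @export
octa_normalize <- function(map, target_mm = 4.11, target_px = 960L) {
  dims <- if (inherits(map, "perfusion_map")) dim(map$perfused)
          else dim(map$pixels)
  extent <- min(dims) * map$mm_per_px
  if (extent < target_mm - 1e-9)
    stopf("insufficient field: source covers %.3f mm < target %.2f mm",
          extent, target_mm)
  if (inherits(map, "perfusion_map")) {
    out <- map
    out$perfused <- resample_nn(map$perfused, map$mm_per_px, target_mm, target_px)
    out$large_vessel_mask <- resample_nn(map$large_vessel_mask, map$mm_per_px,
                                         target_mm, target_px)
    out$mm_per_px <- target_mm / target_px
    return(out)
  }
  if (inherits(map, "octa_image")) {
    px <- resample_nn(map$pixels, map$mm_per_px, target_mm, target_px)
    return(octa_image(px, mm_per_px = target_mm / target_px))
  }
  stopf("map must be a perfusion_map or octa_image")
}

#' Full OCT-A preprocessing chain
#'
#' binarize -> isolate large vessels -> remove -> normalize, mirroring the
#' processing order used for en-face superficial-slab angiograms.
#'
#' @param img An [octa_image].
#' @param window_mm,offset Binarization parameters.
#' @param scales_mm,vesselness_threshold Frangi parameters.
#' @param vessel_margin_px Safety margin: the detected vessel mask is
#'   dilated this many pixels before removal, so vessel borders missed by
#'   the detector do not leak into the capillary density.
#' @param target_mm,target_px Normalization target.
#' @return Normalized `perfusion_map` with a `params` attribute recording
#'   all parameters (provenance).
#' @export
preprocess_octa <- function(img, window_mm = 0.1, offset = 0.02,
                            scales_mm = c(0.03, 0.06, 0.09, 0.12),
                            vesselness_threshold = 0.5,
                            vessel_margin_px = 1L,
                            target_mm = 4.11, target_px = 960L) {
  bin <- octa_binarize(img, window_mm, offset)
  mask <- octa_isolate_large_vessels(img, scales_mm, vesselness_threshold)
  if (vessel_margin_px > 0L) mask <- dilate_mask(mask, vessel_margin_px)
  pm <- octa_remove_large_vessels(bin, mask, img$mm_per_px)
  out <- octa_normalize(pm, target_mm, target_px)
  attr(out, "params") <- list(window_mm = window_mm, offset = offset,
                              scales_mm = scales_mm,
                              vesselness_threshold = vesselness_threshold,
                              vessel_margin_px = vessel_margin_px,
                              target_mm = target_mm, target_px = target_px)
  out
}
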