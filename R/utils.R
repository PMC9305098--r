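## Internal helpers shared across modules.

## One constant ties the OCT-A physical frame to the trajectory model's
## angular frame: a 15 degree scan field corresponds to 4.11 mm on the
## retina, i.e. 0.274 mm per degree.
.FOCALSF <- new.env(parent = emptyenv())
.FOCALSF$target_mm <- 4.11
.FOCALSF$target_px <- 960L
.FOCALSF$field_deg <- 15

#' Millimetres per degree of visual angle
#'
#' The single conversion constant shared by the OCT-A preprocessing and the
#' trajectory model: a 15 degree scan field covers 4.11 mm of retina, so
#' 1 degree = 4.11/15 = 0.274 mm.
#'
#' @return Scalar, mm per degree.
#' @export
mm_per_degree <- function() .FOCALSF$target_mm / .FOCALSF$field_deg

## Wrap angle(s) into (-180, 180].
wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

## Wrap into [0, 360).
wrap360 <- function(a) a %% 360

## Signed angular difference a - b in (-180, 180].
ang_diff <- function(a, b) wrap180(a - b)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
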