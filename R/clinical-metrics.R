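# Clinical summary metrics: vertebral rotation from the dip shift, the
# normalised vertebral-body-to-skin distance profile, and severity
# classification from lateral deviation or Cobb angle.

#' Vertebral rotation angle from dip shift and body-to-skin distance
#'
#' Trigonometric estimate of the axial rotation of a vertebral body with
#' respect to its spinous process: with the vertebral body at P, the dip
#' at R on the contour, and PS the perpendicular distance from P to the
#' posterior contour, Q is the foot of that perpendicular (directly
#' posterior of P). The rotation is the angle at P in the triangle QPR:
#' `alpha = atan(QR / PS)`, signed positive when the body is rotated
#' toward the patient's right (body to the right of the dip).
#'
#' @param P vertebral body position, (x, y) mm.
#' @param R dip position on the contour, (x, y) mm.
#' @param PS perpendicular distance from P to the posterior contour (mm),
#'   > 0.
#' @return a `rotation_estimate`: list with `P`, `R`, `Q`, `PS`, `QR`
#'   (signed lateral dip shift, mm) and `alpha` (degrees).
#' @export
#' @examples
#' vertebral_rotation(P = c(25, 58.9), R = c(0, 0), PS = 58.9)$alpha # ~23
vertebral_rotation <- function(P, R, PS) {
  P <- as.numeric(P); R <- as.numeric(R)
  if (!is.numeric(PS) || length(PS) != 1L || PS <= 0)
    stop("PS must be a single positive distance (mm)")
  Q <- c(P[1L], P[2L] - PS)   # posterior foot of the perpendicular
  QR <- Q[1L] - R[1L]         # + when the body sits right of the dip
  alpha <- atan(QR / PS) * 180 / pi
  structure(list(P = P, R = R, Q = Q, PS = PS, QR = QR, alpha = alpha),
            class = "rotation_estimate")
}

#' @export
print.rotation_estimate <- function(x, ...) {
  cat(sprintf(paste0("<rotation_estimate> alpha %.1f deg ",
                     "(dip shift QR %.1f mm over PS %.1f mm)\n"),
              x$alpha, x$QR, x$PS))
  invisible(x)
}

#' Normalised vertebral-body-to-skin distance profile
#'
#' Normalises the per-level distances delta_i between vertebral body and
#' back skin by their mean: `delta_norm_i = (delta_i - mean) / mean`, a
#' dimensionless profile comparable across persons of different size.
#' Levels are mapped affinely to [0, 1] with 0 at the iliac crest and 1 at
#' the vertebra prominens.
#'
#' @param delta_i per-level distances (mm), all > 0, length >= 2.
#' @param levels corresponding levels z (mm), within
#'   `[iliac, prominens]`.
#' @param iliac,prominens landmark levels (mm), `iliac < prominens`.
#' @return a `delta_profile`: list with `delta_i`, `delta_bar` (mm),
#'   `delta_norm` (dimensionless, mean 0) and `levels_norm` (in [0, 1],
#'   increasing).
#' @export
delta_profile <- function(delta_i, levels, iliac, prominens) {
  delta_i <- as.numeric(delta_i); levels <- as.numeric(levels)
  if (length(delta_i) < 2L) stop("need at least 2 levels")
  if (length(delta_i) != length(levels))
    stop("delta_i and levels lengths differ")
  if (any(delta_i <= 0)) stop("all delta_i must be > 0")
  if (!(iliac < prominens)) stop("iliac level must be below the prominens")
  if (any(levels < iliac - 1e-9 | levels > prominens + 1e-9))
    stop("levels must lie between the iliac crest and vertebra prominens")
  o <- order(levels)
  delta_i <- delta_i[o]; levels <- levels[o]
  delta_bar <- mean(delta_i)
  structure(list(delta_i = delta_i, delta_bar = delta_bar,
                 delta_norm = (delta_i - delta_bar) / delta_bar,
                 levels_norm = (levels - iliac) / (prominens - iliac)),
            class = "delta_profile")
}

#' Severity classification of lateral deviation and Cobb angle
#'
#' `classify_deviation` bands the maximal lateral deviation of the spine:
#' mild when <= 10 mm, moderate between 10 and 20 mm, strong when
#' >= 20 mm. `classify_cobb` bands the radiographic Cobb angle: below 10
#' degrees there is no scoliosis; 10-20 is mild (physiotherapy), 20-40
#' moderate (bracing), above 40 severe (surgery often indicated). Band
#' edges at 20 and 40 degrees belong to the lower band.
#'
#' @param deviation_mm lateral deviation (mm), >= 0.
#' @param cobb_deg Cobb angle (degrees), >= 0.
#' @return a character vector of class labels.
#' @export
#' @examples
#' classify_deviation(c(10, 15, 20))  # mild, moderate, strong
#' classify_cobb(c(9, 10, 45))        # none, mild, severe
classify_deviation <- function(deviation_mm) {
  deviation_mm <- as.numeric(deviation_mm)
  if (any(!is.finite(deviation_mm)) || any(deviation_mm < 0))
    stop("deviation must be non-negative")
  ifelse(deviation_mm <= 10, "mild",
         ifelse(deviation_mm >= 20, "strong", "moderate"))
}

#' @rdname classify_deviation
#' @export
classify_cobb <- function(cobb_deg) {
  cobb_deg <- as.numeric(cobb_deg)
  if (any(!is.finite(cobb_deg)) || any(cobb_deg < 0))
    stop("Cobb angle must be non-negative")
  ifelse(cobb_deg < 10, "none",
         ifelse(cobb_deg <= 20, "mild",
                ifelse(cobb_deg <= 40, "moderate", "severe")))
}
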