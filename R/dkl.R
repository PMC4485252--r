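#' Monitor calibration
#'
#' CIE 1931 chromaticity coordinates and maximum luminances of the display
#' primaries, plus the mean (background) luminance. Defaults describe a
#' linearised LCD with sRGB-like primaries whose full-white luminance is
#' twice the 385 cd/m^2 mean, so that the mid-grey background sits at the
#' mean luminance.
#'
#' @param red,green,blue Length-3 vectors `c(x, y, Y)` per primary: CIE
#'   chromaticity (x, y) and maximum luminance Y in cd/m^2.
#' @param mean_luminance Background luminance, cd/m^2.
#' @param gamma Display gamma applied when decoding stored gun values; `1`
#'   for a linearised display.
#' @return A list of class `monitor_calibration`, including the derived
#'   3x3 `rgb_to_lms` matrix (columns = primaries at full drive) and the
#'   background LMS `lms_bg`.
#' @export
monitor_calibration <- function(red = c(0.64, 0.33, 0.2126 * 770),
                                green = c(0.30, 0.60, 0.7152 * 770),
                                blue = c(0.15, 0.06, 0.0722 * 770),
                                mean_luminance = 385,
                                gamma = 1) {
  prim <- rbind(red = red, green = green, blue = blue)
  colnames(prim) <- c("x", "y", "Y")
  if (any(prim[, "Y"] <= 0)) stop("primary luminances must be positive")

  # chromaticity + luminance -> XYZ tristimulus per primary
  xyz <- apply(prim, 1L, function(p) {
    x <- p[1L]; y <- p[2L]; Y <- p[3L]
    c(X = x / y * Y, Y = Y, Z = (1 - x - y) / y * Y)
  })                                    # 3x3, columns = R, G, B

  # Smith-Pokorny cone fundamentals (via Judd-modified XYZ)
  xyz_to_lms <- matrix(c(
     0.15514,  0.54312, -0.03286,
    -0.15514,  0.45684,  0.03286,
     0.0,      0.0,      0.01608
  ), 3, 3, byrow = TRUE, dimnames = list(c("L", "M", "S"), c("X", "Y", "Z")))

  rgb_to_lms <- xyz_to_lms %*% xyz
  lms_bg <- drop(rgb_to_lms %*% rep(0.5, 3))   # mid-grey background

  structure(list(primaries = prim, mean_luminance = mean_luminance,
                 gamma = gamma, xyz_to_lms = xyz_to_lms,
                 rgb_to_lms = rgb_to_lms, lms_bg = lms_bg),
            class = "monitor_calibration")
}

#' Transform an RGB patch into DKL space
#'
#' Linear gun values are mapped to cone excitations through the
#' calibration's RGB-to-LMS matrix, then expressed as cone-contrast
#' differential coordinates about the mid-grey background along the three
#' DKL mechanism axes: achromatic (luminance, L+M), the isoluminant L-M
#' axis, and the isoluminant S-(L+M) axis. The background pixel maps to
#' (0, 0, 0) and any modulation that scales all three guns about the
#' background equally has zero chromatic coordinates.
#'
#' @param patch An `image_patch` or a numeric H x W x 3 array of linear RGB
#'   in \[0, 1\] (out-of-range values are clipped with a warning).
#' @param cal A [monitor_calibration()].
#' @return A list of class `dkl_image` with channel matrices `lum`, `lm`,
#'   `s` (each H x W), `pix_per_deg`, and `n_clipped`.
#' @export
rgb_to_dkl <- function(patch, cal = monitor_calibration()) {
  stopifnot(inherits(cal, "monitor_calibration"))
  pix_per_deg <- NA_real_
  px <- patch
  if (inherits(patch, "image_patch")) {
    px <- patch$pixels
    pix_per_deg <- patch$pix_per_deg
  }
  stopifnot(length(dim(px)) == 3L, dim(px)[3L] == 3L)
  n_clipped <- sum(px < 0 | px > 1)
  if (n_clipped > 0L) {
    warning(n_clipped, " out-of-range pixel value(s) clipped to [0, 1]")
    px <- pmin(pmax(px, 0), 1)
  }
  h <- dim(px)[1L]; w <- dim(px)[2L]
  rgb <- matrix(px, ncol = 3L)                 # pixels x 3
  lms <- rgb %*% t(cal$rgb_to_lms)             # pixels x (L, M, S)
  bg <- cal$lms_bg
  dL <- lms[, 1L] - bg[1L]
  dM <- lms[, 2L] - bg[2L]
  dS <- lms[, 3L] - bg[3L]
  lum <- (dL + dM) / (bg[1L] + bg[2L])
  lm <- dL / bg[1L] - dM / bg[2L]
  s <- dS / bg[3L] - (dL + dM) / (bg[1L] + bg[2L])
  structure(list(lum = matrix(lum, h, w), lm = matrix(lm, h, w),
                 s = matrix(s, h, w), pix_per_deg = pix_per_deg,
                 n_clipped = n_clipped),
            class = "dkl_image")
}
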