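#' Extract square patches from the centres of the four image quadrants
#'
#' The input image is assumed gaze-centred: its centre corresponds to the
#' centre of the recording observer's gaze, so the top half is "above
#' fixation" and the bottom half "below fixation". One square patch is cut
#' from the centre of each quadrant.
#'
#' Pixel arrays are row-major with row 1 at the top; visual-field coordinates
#' have y upward, so small row indices are *above* fixation.
#'
#' @param image Numeric array, H x W (greyscale) or H x W x 3 (RGB), values
#'   in \[0, 1\].
#' @param patch_px Patch side length in pixels (default 128).
#' @param image_id Optional integer identifier carried on the patches.
#' @param pix_per_deg Pixels per degree of visual angle carried on the
#'   patches (default `NA`; set when known).
#' @return A list of four `image_patch` objects named `above_left`,
#'   `above_right`, `below_left`, `below_right`. Each is a list with elements
#'   `pixels` (patch_px x patch_px x 3), `image_id`, `source_v`
#'   (`"above"`/`"below"`), `source_h` (`"left"`/`"right"`) and
#'   `pix_per_deg`.
#' @export
extract_quadrant_patches <- function(image, patch_px = 128,
                                     image_id = NA_integer_,
                                     pix_per_deg = NA_real_) {
  if (length(dim(image)) == 2L) {
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  }
  stopifnot(length(dim(image)) == 3L)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (h < 2 * patch_px || w < 2 * patch_px) {
    stop("image (", h, "x", w, ") too small for two ", patch_px,
         "-px patches per dimension")
  }
  half <- patch_px %/% 2
  # quadrant centres in pixel units (top-left quadrant centre at h/4, w/4)
  centres <- list(
    above_left  = c(floor(h / 4), floor(w / 4)),
    above_right = c(floor(h / 4), floor(3 * w / 4)),
    below_left  = c(floor(3 * h / 4), floor(w / 4)),
    below_right = c(floor(3 * h / 4), floor(3 * w / 4))
  )
  out <- lapply(names(centres), function(nm) {
    ctr <- centres[[nm]]
    rows <- seq.int(ctr[1L] - half + 1L, ctr[1L] + (patch_px - half))
    cols <- seq.int(ctr[2L] - half + 1L, ctr[2L] + (patch_px - half))
    structure(list(
      pixels = image[rows, cols, , drop = FALSE],
      image_id = image_id,
      source_v = if (startsWith(nm, "above")) "above" else "below",
      source_h = if (endsWith(nm, "left")) "left" else "right",
      pix_per_deg = pix_per_deg
    ), class = "image_patch")
  })
  names(out) <- names(centres)
  out
}

#' Raised-cosine circular mask
#'
#' Mask value is 1 inside the plateau, falls along a half-cosine ramp of
#' width `transition_frac` times the patch radius, and reaches 0 at the patch
#' half-width.
#'
#' @param n Side length in pixels.
#' @param transition_frac Ramp width as a fraction of the patch radius, in
#'   \[0, 0.5).
#' @return An n x n matrix in \[0, 1\].
#' @export
raised_cosine_mask <- function(n, transition_frac = 0.1) {
  stopifnot(transition_frac >= 0, transition_frac < 0.5)
  ctr <- (n + 1) / 2
  radius <- n / 2
  ramp <- transition_frac * radius
  idx <- seq_len(n)
  r <- sqrt(outer((idx - ctr)^2, (idx - ctr)^2, "+"))
  m <- matrix(0, n, n)
  plateau <- r <= radius - ramp
  m[plateau] <- 1
  if (ramp > 0) {
    in_ramp <- r > radius - ramp & r < radius
    m[in_ramp] <- 0.5 * (1 + cos(pi * (r[in_ramp] - (radius - ramp)) / ramp))
  }
  m
}

#' Window a patch with a raised-cosine circular mask and upsample it
#'
#' Reproduces the display preparation of a patch: a circular raised-cosine
#' window is applied (pixels outside the circle blend to the mean-luminance
#' background), then the patch is resampled by `factor` using separable
#' linear interpolation.
#'
#' @param patch An `image_patch` (or bare numeric array).
#' @param factor Upsampling factor (> 0); the display pipeline uses 2.75.
#' @param transition_frac Raised-cosine ramp width as a fraction of the patch
#'   radius; see [raised_cosine_mask()].
#' @param background Background value blended in outside the circular window
#'   (default mid-grey 0.5, the mean-luminance background).
#' @param window Apply the circular window (default `TRUE`); set `FALSE` to
#'   resample only.
#' @return An `image_patch` with side length `round(n * factor)`.
#' @export
window_and_upsample <- function(patch, factor = 2.75, transition_frac = 0.1,
                                background = 0.5, window = TRUE) {
  stopifnot(factor > 0)
  px <- if (inherits(patch, "image_patch")) patch$pixels else patch
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
  n <- dim(px)[1L]
  stopifnot(n == dim(px)[2L])

  if (window) {
    m <- raised_cosine_mask(n, transition_frac)
    for (k in seq_len(dim(px)[3L])) {
      px[, , k] <- m * px[, , k] + (1 - m) * background
    }
  }

  m_out <- as.integer(round(n * factor))
  if (m_out != n) {
    # output pixel centres mapped back into input pixel-centre coordinates
    coord <- (seq_len(m_out) - 0.5) / factor + 0.5
    coord <- pmin(pmax(coord, 1), n)
    interp1 <- function(v, at) {
      lo <- pmin(floor(at), n - 1L)
      w <- at - lo
      v[lo] * (1 - w) + v[lo + 1L] * w
    }
    out <- array(0, dim = c(m_out, m_out, dim(px)[3L]))
    for (k in seq_len(dim(px)[3L])) {
      tmp <- apply(px[, , k], 2L, interp1, at = coord)        # rows
      out[, , k] <- t(apply(tmp, 1L, interp1, at = coord))    # cols
    }
    px <- out
  }

  if (inherits(patch, "image_patch")) {
    res <- patch
    res$pixels <- px
    if (!is.na(res$pix_per_deg)) res$pix_per_deg <- res$pix_per_deg * factor
    res
  } else {
    structure(list(pixels = px, image_id = NA_integer_,
                   source_v = NA_character_, source_h = NA_character_,
                   pix_per_deg = NA_real_),
              class = "image_patch")
  }
}

#' Aperture layout of the stimulus display
#'
#' The four stimulus apertures are centred at 5.37 degrees eccentricity on
#' the +/-45 degree diagonals, one per visual-field quadrant (away from both
#' meridians), and are 4.5 degrees in diameter. Coordinates are visual-field
#' degrees with x rightward, y upward and fixation at the origin.
#'
#' @param eccentricity_deg Radial distance of each aperture centre from
#'   fixation (default 5.37).
#' @param diameter_deg Aperture diameter (default 4.5).
#' @return A list of class `aperture_layout` with a `centers` data frame
#'   (columns `quadrant`, `x_deg`, `y_deg`), `diameter_deg` and
#'   `eccentricity_deg`.
#' @export
aperture_layout <- function(eccentricity_deg = 5.37, diameter_deg = 4.5) {
  d <- eccentricity_deg / sqrt(2)
  centers <- data.frame(
    quadrant = c("upper_left", "upper_right", "lower_left", "lower_right"),
    x_deg = c(-d, d, -d, d),
    y_deg = c(d, d, -d, -d),
    stringsAsFactors = FALSE
  )
  structure(list(centers = centers, diameter_deg = diameter_deg,
                 eccentricity_deg = eccentricity_deg),
            class = "aperture_layout")
}

#' Read an image from PNG, optionally linearising gun values
#'
#' @param path PNG file path.
#' @param gamma Display gamma used to linearise the stored 8-bit values;
#'   `1` (default) means the file already holds linear gun values, as on a
#'   gamma-corrected display.
#' @return Numeric H x W x 3 array in \[0, 1\].
#' @export
read_image_png <- function(path, gamma = 1) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]   # drop alpha if present
  if (gamma != 1) img <- img^gamma
  img
}

#' Write an image array to PNG
#'
#' @param image Numeric array in \[0, 1\] (clipped if slightly outside).
#' @param path Output path.
#' @param gamma Display gamma used to encode linear values for storage.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path, gamma = 1) {
  img <- pmin(pmax(image, 0), 1)
  if (gamma != 1) img <- img^(1 / gamma)
  png::writePNG(img, path)
  invisible(path)
}
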