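#' @title Gabor filter-bank characterisation of image patches
#' @name gabor-module
#' @description Odd-symmetric Gabor filters spanning 1-16 cycles per degree
#'   and four orientations, applied to the DKL channels of image patches;
#'   plus pixel statistics, marginals over spatial frequency/orientation and
#'   correlation-ready summaries.
NULL

#' Construct a Gabor filter kernel
#'
#' An isotropic Gaussian envelope multiplying a sinusoidal carrier
#' `cos(2 pi f x' - phase)`; at the default 90 degree phase the carrier is a
#' sine, making the kernel odd-symmetric with zero DC response. The envelope
#' standard deviation is set from the octave bandwidth `b` via
#' `sigma = (sqrt(ln 2 / 2) / (pi f)) * (2^b + 1) / (2^b - 1)` and the
#' kernel is truncated at +/- 3 sigma.
#'
#' @param sf Spatial frequency, cycles per degree; must be below the Nyquist
#'   limit `pix_per_deg / 2`.
#' @param orientation Carrier orientation in degrees (0 = modulation along
#'   x, i.e., vertically-oriented stripes; 90 = horizontal stripes).
#' @param phase Carrier phase in degrees (default 90: odd-symmetric).
#' @param bandwidth_octaves Spatial-frequency bandwidth in octaves
#'   (default 1).
#' @param pix_per_deg Pixels per degree of visual angle (default 78.7,
#'   a 1,920-px display spanning 24.4 degrees).
#' @return A square numeric matrix (odd side length).
#' @export
gabor_kernel <- function(sf, orientation, phase = 90,
                         bandwidth_octaves = 1, pix_per_deg = 78.7) {
  stopifnot(sf > 0)
  if (sf >= pix_per_deg / 2) {
    stop("spatial frequency ", sf, " cpd is at or above the Nyquist limit (",
         pix_per_deg / 2, " cpd at ", pix_per_deg, " px/deg)")
  }
  b <- bandwidth_octaves
  sigma_deg <- (sqrt(log(2) / 2) / (pi * sf)) * (2^b + 1) / (2^b - 1)
  sigma_px <- sigma_deg * pix_per_deg
  half <- ceiling(3 * sigma_px)
  d <- seq.int(-half, half) / pix_per_deg          # degrees
  th <- orientation * pi / 180
  ph <- phase * pi / 180
  # x' along the modulation direction; rows = y (downward), cols = x
  xp <- outer(-d, rep(1, length(d))) * sin(th) +
        outer(rep(1, length(d)), d) * cos(th)
  r2 <- outer(d^2, d^2, "+")
  exp(-r2 / (2 * sigma_deg^2)) * cos(2 * pi * sf * xp - ph)
}

# 2-D "valid" convolution via FFT. Returns the (nr-kr+1) x (nc-kc+1) region
# where the kernel lies fully inside the image.
conv2_valid <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  if (kr > nr || kc > nc) {
    stop("image (", nr, "x", nc, ") smaller than kernel support (",
         kr, "x", kc, ")")
  }
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- img
  B <- matrix(0, pr, pc); B[seq_len(kr), seq_len(kc)] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    (pr * pc)
  full[seq.int(kr, nr), seq.int(kc, nc), drop = FALSE]
}

#' Gabor filter-bank energies of a DKL image
#'
#' For every DKL channel, spatial frequency and orientation, the energy is
#' the square root of the sum over space of the squared valid-region
#' convolution of the channel with the corresponding odd-symmetric Gabor.
#' Per-channel pixel mean and standard deviation are attached.
#'
#' @param image A `dkl_image` from [rgb_to_dkl()] (or a plain matrix, taken
#'   as a single luminance channel).
#' @param sfs Spatial frequencies, cycles/degree (default 1, 2, 4, 8, 16).
#' @param orientations Orientations in degrees (default 0, 45, 90, 135).
#' @param pix_per_deg Pixels per degree; defaults to the image's value.
#' @param bandwidth_octaves Octave bandwidth of every filter (default 1).
#' @return A list of class `gabor_bank_response`: `energies` (3-d array
#'   channel x sf x orientation), `pixel_mean` and `pixel_sd` (per channel),
#'   `sfs`, `orientations`, `pix_per_deg`.
#' @export
bank_energy <- function(image, sfs = c(1, 2, 4, 8, 16),
                        orientations = c(0, 45, 90, 135),
                        pix_per_deg = NULL, bandwidth_octaves = 1) {
  if (is.matrix(image)) {
    image <- structure(list(lum = image, pix_per_deg = pix_per_deg %||% NA),
                       class = "dkl_image")
  }
  stopifnot(inherits(image, "dkl_image"))
  if (is.null(pix_per_deg)) pix_per_deg <- image$pix_per_deg
  if (is.na(pix_per_deg)) {
    stop("pix_per_deg must be supplied (not recorded on the image)")
  }
  channels <- intersect(c("lum", "lm", "s"), names(image))
  kerns <- lapply(sfs, function(f) lapply(orientations, function(o) {
    gabor_kernel(f, o, pix_per_deg = pix_per_deg,
                 bandwidth_octaves = bandwidth_octaves)
  }))
  en <- array(NA_real_,
              dim = c(length(channels), length(sfs), length(orientations)),
              dimnames = list(channel = channels, sf = as.character(sfs),
                              orientation = as.character(orientations)))
  for (ci in seq_along(channels)) {
    ch <- image[[channels[ci]]]
    for (fi in seq_along(sfs)) {
      for (oi in seq_along(orientations)) {
        conv <- conv2_valid(ch, kerns[[fi]][[oi]])
        en[ci, fi, oi] <- sqrt(sum(conv^2))
      }
    }
  }
  structure(list(
    energies = en,
    pixel_mean = vapply(channels, function(ch) mean(image[[ch]]), 0),
    pixel_sd = vapply(channels, function(ch) stats::sd(image[[ch]]), 0),
    sfs = sfs, orientations = orientations, pix_per_deg = pix_per_deg
  ), class = "gabor_bank_response")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average bank energies over orientation or spatial frequency
#'
#' @param resp A `gabor_bank_response`.
#' @param over `"orientation"` (returns per-sf marginals) or `"sf"` (returns
#'   per-orientation marginals).
#' @return Matrix channel x retained axis.
#' @export
marginalize <- function(resp, over = c("orientation", "sf")) {
  over <- match.arg(over)
  stopifnot(inherits(resp, "gabor_bank_response"))
  keep <- if (over == "orientation") c(1L, 2L) else c(1L, 3L)
  apply(resp$energies, keep, mean)
}

#' Characterise a set of image patches
#'
#' Each patch is transformed into DKL space and summarised by the pixel
#' mean, pixel SD, Gabor spatial-frequency marginals (averaged over
#' orientation) and orientation marginals (averaged over spatial frequency)
#' of every channel. Left/right patches of the same image and vertical
#' source are averaged after characterisation, giving one row per
#' (image, source, channel, statistic).
#'
#' @param patches List of `image_patch` objects (with `image_id`, `source_v`
#'   and `source_h` set).
#' @param cal A [monitor_calibration()].
#' @param sfs,orientations Filter-bank grid; see [bank_energy()].
#' @param pix_per_deg Pixels per degree of the patches (defaults to each
#'   patch's value).
#' @return Long data frame with columns `image`, `source`, `channel`,
#'   `statistic` (`mean`, `sd`, `sf_<f>`, `ori_<o>`), `value`.
#' @export
characterise_set <- function(patches, cal = monitor_calibration(),
                             sfs = c(1, 2, 4, 8, 16),
                             orientations = c(0, 45, 90, 135),
                             pix_per_deg = NULL) {
  rows <- lapply(patches, function(p) {
    stopifnot(inherits(p, "image_patch"))
    dkl <- rgb_to_dkl(p, cal)
    resp <- bank_energy(dkl, sfs = sfs, orientations = orientations,
                        pix_per_deg = pix_per_deg)
    sf_marg <- marginalize(resp, "orientation")
    ori_marg <- marginalize(resp, "sf")
    ch <- rownames(sf_marg)
    do.call(rbind, lapply(ch, function(cc) {
      data.frame(
        image = p$image_id, source = p$source_v, side = p$source_h,
        channel = cc,
        statistic = c("mean", "sd", paste0("sf_", sfs),
                      paste0("ori_", orientations)),
        value = c(resp$pixel_mean[[cc]], resp$pixel_sd[[cc]],
                  sf_marg[cc, ], ori_marg[cc, ]),
        stringsAsFactors = FALSE
      )
    }))
  })
  long <- do.call(rbind, rows)
  out <- stats::aggregate(value ~ image + source + channel + statistic,
                          long, mean)    # average left/right pairs
  out[order(out$image, out$source, out$channel, out$statistic), ,
      drop = FALSE]
}

#' Correlate image characteristics with response differences
#'
#' For every (statistic, channel) cell of a characterisation table, the
#' Spearman correlation between the characteristic and the per-entry
#' response differences (upper minus lower presentation) is computed over
#' the shared (image, source) index.
#'
#' @param characterisation Output of [characterise_set()].
#' @param diffs Data frame with columns `image`, `source`, `diff`.
#' @return Data frame with columns `channel`, `statistic`, `rho`, `p`, `n`.
#' @export
characterise_correlations <- function(characterisation, diffs) {
  key <- function(d) paste(d$image, d$source)
  missing_keys <- setdiff(unique(key(characterisation)), key(diffs))
  if (length(missing_keys) > 0L) {
    stop("response differences missing for entries: ",
         paste(utils::head(missing_keys, 5L), collapse = ", "),
         if (length(missing_keys) > 5L) ", ...")
  }
  cells <- unique(characterisation[, c("channel", "statistic")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- characterisation[
      characterisation$channel == cells$channel[i] &
        characterisation$statistic == cells$statistic[i], , drop = FALSE]
    d <- diffs$diff[match(key(sub), key(diffs))]
    ct <- spearman(sub$value, d)
    data.frame(channel = cells$channel[i], statistic = cells$statistic[i],
               rho = ct$rho, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
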