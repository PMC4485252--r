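#' @title Synthetic scenes and BOLD timeseries
#' @name synthetic-module
#' @description Generators for gaze-centred sky/ground images and for voxel
#'   BOLD timeseries with the statistical structure the analysis assumes
#'   (HRF-convolved condition responses, per-run polynomial drift,
#'   ARMA(1,1) noise), so every pipeline stage can be exercised without
#'   external recordings.
NULL

# 1/f^alpha ("fractal") texture, standardised to mean 0, sd 1.
spectral_texture <- function(nrow, ncol, alpha) {
  fr <- matrix(rep(c(0:(floor(nrow / 2)), -((ceiling(nrow / 2) - 1):1)) / nrow,
                   ncol), nrow, ncol)
  fc <- matrix(rep(c(0:(floor(ncol / 2)), -((ceiling(ncol / 2) - 1):1)) / ncol,
                   each = nrow), nrow, ncol)
  f <- sqrt(fr^2 + fc^2)
  filt <- ifelse(f == 0, 0, f^(-alpha))
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  tex <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (nrow * ncol)
  (tex - mean(tex)) / stats::sd(tex)
}

#' Default scene model for synthetic gaze-centred images
#'
#' The upper image half emulates sky (bright, low variance, slight blue
#' cast); the lower half emulates ground (darker, variegated, with more
#' low-spatial-frequency luminance structure and a warm cast). Both halves
#' are 1/f^alpha textures; the amplitude-spectrum exponent defaults to 1.2,
#' in the range reported for natural scenes.
#'
#' @param n_images Number of images (default 30).
#' @param sky_mean,ground_mean Mean luminance-channel values in \[0, 1\].
#' @param sky_sd,ground_sd Pixel standard deviations (sky < ground).
#' @param spectral_exponent Exponent alpha of the 1/f^alpha amplitude
#'   spectrum of the textures.
#' @param size Image side length in pixels.
#' @param seed Integer seed.
#' @return A list of class `scene_model`.
#' @export
scene_model <- function(n_images = 30, sky_mean = 0.75, ground_mean = 0.40,
                        sky_sd = 0.05, ground_sd = 0.15,
                        spectral_exponent = 1.2, size = 512, seed = 1) {
  stopifnot(sky_sd < ground_sd)
  structure(list(n_images = n_images, sky_mean = sky_mean,
                 ground_mean = ground_mean, sky_sd = sky_sd,
                 ground_sd = ground_sd,
                 spectral_exponent = spectral_exponent,
                 size = size, seed = seed),
            class = "scene_model")
}

#' Generate a set of synthetic gaze-centred images
#'
#' @param model A [scene_model()].
#' @return A list of `n_images` numeric `size x size x 3` arrays in
#'   \[0, 1\], upper half sky-like and lower half ground-like.
#' @export
synth_image_set <- function(model = scene_model()) {
  stopifnot(inherits(model, "scene_model"))
  n <- model$size
  half <- n %/% 2
  seeds <- derive_seeds(model$seed, model$n_images)
  lapply(seq_len(model$n_images), function(i) {
    with_seed(seeds[i], {
      sky <- model$sky_mean +
        model$sky_sd * spectral_texture(half, n, model$spectral_exponent)
      ground <- model$ground_mean +
        model$ground_sd * spectral_texture(n - half, n,
                                           model$spectral_exponent)
      lum <- rbind(sky, ground)
      # slight opposing chromatic casts, scaled down in the sky half
      cast <- c(rep(1, half), rep(-1, n - half)) *
        (0.03 + 0.02 * spectral_texture(n, n, model$spectral_exponent))
      img <- array(0, dim = c(n, n, 3))
      img[, , 1] <- lum - cast        # red: stronger on the ground
      img[, , 2] <- lum - 0.4 * cast
      img[, , 3] <- lum + cast        # blue: stronger in the sky
      pmin(pmax(img, 0), 1)
    })
  })
}

#' Simulate stationary ARMA(1,1) noise
#'
#' x_t = a x_(t-1) + e_t + b e_(t-1) with i.i.d. normal innovations of
#' standard deviation `sd`. A burn-in stretch is generated and discarded so
#' the returned series is (effectively) stationary.
#'
#' @param n Length of the returned series.
#' @param a AR parameter, |a| < 1.
#' @param b MA parameter.
#' @param sd Innovation standard deviation.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param burn_in Number of initial samples discarded (default 500).
#' @return Numeric vector of length `n`.
#' @export
arma11_noise <- function(n, a, b, sd = 1, seed = NULL, burn_in = 500) {
  if (abs(a) >= 1) stop("|a| must be < 1 for stationarity (got a = ", a, ")")
  gen <- function() {
    e <- stats::rnorm(n + burn_in + 1L, sd = sd)
    u <- e[-1L] + b * e[-length(e)]
    x <- stats::filter(u, a, method = "recursive")
    as.numeric(x[seq.int(burn_in + 1L, burn_in + n)])
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Default BOLD generative model
#'
#' Condition amplitudes default to the percent-signal-change pattern with a
#' built-in presentation x source interaction: responses in the lower visual
#' field favour below-fixation sources (0.80 vs 0.72 psc) while upper-field
#' responses are nearly equal (0.84 below, 0.85 above).
#'
#' @param amplitudes Named list of true percent-signal-change amplitudes by
#'   `presentation.source` (`upper.above`, `upper.below`, `lower.above`,
#'   `lower.below`).
#' @param baseline Baseline signal level (arbitrary scanner units).
#' @param drift_sd Standard deviation of per-run random Legendre drift
#'   coefficients, in signal units.
#' @param arma_a,arma_b ARMA(1,1) noise parameters.
#' @param noise_sd Innovation standard deviation (signal units).
#' @param tr Repetition time, seconds.
#' @param n_volumes_per_run Volumes per run (166 volumes = 332 s at TR 2 s).
#' @param amplitude_jitter_sd Between-participant (and between-area)
#'   amplitude jitter SD in psc units; see [simulate_session()].
#' @return A list of class `bold_model`.
#' @export
bold_model <- function(amplitudes = list(upper.above = 0.85,
                                         upper.below = 0.84,
                                         lower.above = 0.72,
                                         lower.below = 0.80),
                       baseline = 100, drift_sd = 1.5,
                       arma_a = 0.3, arma_b = 0.1, noise_sd = 1.5,
                       tr = 2, n_volumes_per_run = 166,
                       amplitude_jitter_sd = 0.05) {
  stopifnot(abs(arma_a) < 1)
  structure(list(amplitudes = amplitudes, baseline = baseline,
                 drift_sd = drift_sd, arma_a = arma_a, arma_b = arma_b,
                 noise_sd = noise_sd, tr = tr,
                 n_volumes_per_run = n_volumes_per_run,
                 amplitude_jitter_sd = amplitude_jitter_sd),
            class = "bold_model")
}

# Expand presentation-level amplitudes to a vector over the condition names
# of a design spec; `image_effects` is an optional named vector (same names
# as source_by_image conditions) added on top.
amplitudes_for <- function(model_amps, presentation, condition_spec,
                           n_images, image_effects = NULL) {
  cn <- condition_names_for(condition_spec, n_images)
  amp <- switch(condition_spec,
    single = mean(unlist(model_amps[paste0(presentation,
                                           c(".above", ".below"))])),
    source = unlist(model_amps[paste0(presentation, ".", cn)]),
    source_by_image = unlist(
      model_amps[paste0(presentation, ".", sub("_img.*$", "", cn))])
  )
  amp <- stats::setNames(as.numeric(amp), cn)
  if (!is.null(image_effects)) {
    common <- intersect(names(image_effects), cn)
    amp[common] <- amp[common] + image_effects[common]
  }
  amp
}

#' Simulate one voxel's BOLD timeseries for a set of runs
#'
#' Forward model:
#' `signal = baseline * (1 + sum_c amp_c/100 * regressor_c) + drift + noise`
#' sampled at the TR, where the condition regressors are the HRF-convolved
#' event onsets of the chosen presentation sequence, the drift is a per-run
#' random cubic polynomial and the noise is ARMA(1,1).
#'
#' @param runs List of `run_design`s (or a single one).
#' @param model A [bold_model()].
#' @param presentation `"upper"` or `"lower"`.
#' @param condition_spec Condition mapping, as in [condition_regressors()];
#'   amplitudes are taken from `model$amplitudes` (per-image effects can be
#'   planted via `image_effects`).
#' @param image_effects Optional named psc offsets per
#'   `source_by_image` condition.
#' @param seed Optional integer seed.
#' @param regressors Optional precomputed condition regressor matrix from
#'   [condition_regressors()] (avoids recomputing it when simulating many
#'   voxels over the same runs).
#' @return A list of class `voxel_timeseries`: `values` (full timeline),
#'   `tr`, `run_index`, `censored` (first 16 volumes of each run flagged),
#'   `truth` (the amplitude vector used).
#' @export
simulate_voxel <- function(runs, model = bold_model(),
                           presentation = "lower",
                           condition_spec = "source",
                           image_effects = NULL, seed = NULL,
                           regressors = NULL) {
  if (inherits(runs, "run_design")) runs <- list(runs)
  n_vol <- model$n_volumes_per_run
  if (abs(runs[[1L]]$duration - n_vol * model$tr) > model$tr) {
    stop("run duration (", runs[[1L]]$duration, " s) does not match ",
         n_vol, " volumes at TR ", model$tr, " s")
  }
  gen <- function() {
    seq_name <- paste0(presentation, "_seq")
    n_images <- max(1L, suppressWarnings(max(unlist(
      lapply(runs, function(r) r[[seq_name]]$image_id)), na.rm = TRUE)))
    amp <- amplitudes_for(model$amplitudes, presentation, condition_spec,
                          n_images, image_effects)
    C <- if (is.null(regressors)) {
      condition_regressors(runs, presentation, condition_spec,
                           tr = model$tr, n_volumes = n_vol)
    } else regressors
    amp <- amp[colnames(C)]
    sig <- model$baseline * (1 + drop(C %*% (amp / 100)))
    n_runs <- length(runs)
    drift <- unlist(lapply(seq_len(n_runs), function(r) {
      coef <- c(0, stats::rnorm(3, sd = model$drift_sd))
      drop(legendre_basis(n_vol, 3) %*% coef)
    }))
    noise <- arma11_noise(n_runs * n_vol, model$arma_a, model$arma_b,
                          sd = model$noise_sd)
    structure(list(
      values = sig + drift + noise,
      tr = model$tr,
      run_index = rep(seq_len(n_runs), each = n_vol),
      censored = rep(seq_len(n_vol) <= 16L, n_runs),
      truth = amp
    ), class = "voxel_timeseries")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a full multi-participant synthetic session set
#'
#' For each participant, `n_runs` run designs are generated, and voxel
#' timeseries are simulated for three "areas" (V1, V2, V3 stand-ins:
#' independent voxel pools sharing the condition amplitude map) and the two
#' presentation masks. True amplitudes receive normal jitter (SD
#' `model$amplitude_jitter_sd`) drawn independently per participant, area,
#' presentation and source, which makes the repeated-measures structure
#' non-degenerate.
#'
#' @param n_participants Number of participants (default 7).
#' @param n_runs Runs per participant (default 10).
#' @param model A [bold_model()].
#' @param n_voxels Voxels per (participant, area, presentation) pool.
#' @param condition_spec Condition mapping used for the generating
#'   amplitudes (default `"source"`).
#' @param image_effects Optional named psc offsets per `source_by_image`
#'   condition, applied to the *upper* presentation (an upper-preference
#'   plant); requires `condition_spec = "source_by_image"`.
#' @param design_pars List with `n_images`, `n_nulls`, `n_prepend`.
#' @param seed Integer master seed.
#' @return A list of class `synthetic_session_set`: `participants` (each
#'   with `runs` and `data[[area]][[presentation]]`, a voxels x time
#'   matrix), `truth` (data frame of generating amplitudes per cell),
#'   `model`, `seed`, plus the dimension constants.
#' @export
simulate_session <- function(n_participants = 7, n_runs = 10,
                             model = bold_model(), n_voxels = 50,
                             condition_spec = "source",
                             image_effects = NULL,
                             design_pars = list(n_images = 30, n_nulls = 15,
                                                n_prepend = 8),
                             seed = 1) {
  stopifnot(n_participants >= 1, n_runs >= 1)
  areas <- c("V1", "V2", "V3")
  presentations <- c("upper", "lower")
  p_seeds <- derive_seeds(seed, n_participants)
  truth <- list()

  participants <- lapply(seq_len(n_participants), function(p) {
    with_seed(p_seeds[p], {
      runs <- lapply(seq_len(n_runs), function(r) {
        build_run(design_pars$n_images, design_pars$n_nulls,
                  design_pars$n_prepend,
                  seed = sample.int(.Machine$integer.max, 1L))
      })
      regs <- lapply(presentations, function(pres) {
        condition_regressors(runs, pres, condition_spec, tr = model$tr,
                             n_volumes = model$n_volumes_per_run)
      })
      names(regs) <- presentations
      data <- lapply(areas, function(area) {
        per_pres <- lapply(presentations, function(pres) {
          amps <- model$amplitudes
          jit <- stats::rnorm(2, sd = model$amplitude_jitter_sd)
          keys <- paste0(pres, c(".above", ".below"))
          amps[keys] <- mapply(`+`, amps[keys], jit, SIMPLIFY = FALSE)
          truth[[length(truth) + 1L]] <<- data.frame(
            participant = p, area = area, presentation = pres,
            source = c("above", "below"),
            amplitude = unlist(amps[keys]), row.names = NULL)
          m <- model
          m$amplitudes <- amps
          plant <- if (pres == "upper") image_effects else NULL
          vox <- t(vapply(seq_len(n_voxels), function(v) {
            simulate_voxel(runs, m, pres, condition_spec,
                           image_effects = plant,
                           regressors = regs[[pres]])$values
          }, numeric(n_runs * model$n_volumes_per_run)))
          vox
        })
        names(per_pres) <- presentations
        per_pres
      })
      names(data) <- areas
      list(runs = runs, data = data)
    })
  })

  structure(list(
    participants = participants,
    truth = do.call(rbind, truth),
    model = model, n_participants = n_participants, n_runs = n_runs,
    n_voxels = n_voxels, condition_spec = condition_spec,
    image_effects = image_effects, design_pars = design_pars, seed = seed
  ), class = "synthetic_session_set")
}

#' Write / read the truth record of a synthetic session set
#'
#' The generating parameters (model constants and the per-cell true
#' amplitudes) are serialised as YAML so downstream recovery analyses can be
#' scored without carrying the full object.
#'
#' @param session A `synthetic_session_set`.
#' @param path Output path (`.yml`).
#' @return `path` ([write_truth()]) or the restored list ([read_truth()]).
#' @export
write_truth <- function(session, path) {
  stopifnot(inherits(session, "synthetic_session_set"))
  rec <- list(
    seed = session$seed,
    n_participants = session$n_participants,
    n_runs = session$n_runs,
    n_voxels = session$n_voxels,
    condition_spec = session$condition_spec,
    model = unclass(session$model),
    truth = lapply(seq_len(nrow(session$truth)), function(i)
      as.list(session$truth[i, ]))
  )
  yaml::write_yaml(rec, path, precision = 12)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  rec <- yaml::read_yaml(path)
  rec$truth <- do.call(rbind, lapply(rec$truth, as.data.frame))
  rec
}

#' Write / read a voxel-by-time array as delimited text
#'
#' Tab-separated, one row per voxel, one column per timepoint (named
#' `t<volume>`); a leading comment line records the TR so a table is
#' self-describing.
#'
#' @param voxels Numeric matrix, voxels x timepoints.
#' @param path Output path (`.tsv`).
#' @param tr Repetition time recorded in the header comment, seconds.
#' @return `path` ([write_voxels()]) or a list with `voxels` and `tr`
#'   ([read_voxels()]).
#' @export
write_voxels <- function(voxels, path, tr = 2) {
  stopifnot(is.matrix(voxels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_s=%s", format(tr)), con)
  writeLines(paste(paste0("t", seq_len(ncol(voxels))), collapse = "\t"), con)
  utils::write.table(format(voxels, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_voxels
#' @export
read_voxels <- function(path) {
  first <- readLines(path, n = 1L)
  tr <- if (startsWith(first, "# tr_s=")) {
    as.numeric(sub("# tr_s=", "", first))
  } else NA_real_
  skip <- if (startsWith(first, "#")) 1L else 0L
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                           check.names = FALSE)
  list(voxels = unname(as.matrix(tab)), tr = tr)
}
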