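#' @title GLM estimation for event-related timeseries
#' @name glm-module
#' @description Design-matrix construction (HRF-convolved condition
#'   regressors plus per-run Legendre drift), ordinary and ARMA(1,1)
#'   prewhitened least squares, localiser masks, ROI averaging and percent
#'   signal change.
NULL

# Map image events of a sequence to condition labels.
condition_labels <- function(seq_df, condition_spec) {
  img <- seq_df[seq_df$trial_type == "image", , drop = FALSE]
  lab <- switch(condition_spec,
    single = rep("image", nrow(img)),
    source = img$source,
    source_by_image = sprintf("%s_img%02d", img$source, img$image_id),
    stop("unknown condition_spec: ", condition_spec)
  )
  data.frame(onset = img$onset, duration = img$duration, condition = lab,
             stringsAsFactors = FALSE)
}

# All condition names implied by a spec, in stable order.
condition_names_for <- function(condition_spec, n_images) {
  switch(condition_spec,
    single = "image",
    source = c("above", "below"),
    source_by_image = as.vector(t(outer(c("above", "below"),
                                        seq_len(n_images),
                                        function(s, i) sprintf("%s_img%02d", s, i))))
  )
}

#' Build HRF-convolved condition regressors on the full run timeline
#'
#' Events are modelled as unit onset impulses (or optionally 1 s boxcars)
#' on a fine time grid, convolved with the HRF and sampled at the volume
#' acquisition times. No censoring is applied here; see
#' [build_design_matrix()].
#'
#' @param runs List of `run_design` objects (one per scanning run).
#' @param presentation `"upper"` or `"lower"`: which sequence of each run to
#'   model.
#' @param condition_spec `"single"` (one regressor for all image events, the
#'   localiser model), `"source"` (one per source location) or
#'   `"source_by_image"` (one per source x image combination).
#' @param tr Repetition time in seconds (default 2).
#' @param n_volumes Volumes per run (default `duration / tr`).
#' @param hrf HRF function of time in seconds.
#' @param boxcar If `TRUE`, model each event as a boxcar of its duration
#'   rather than an onset impulse.
#' @param dt Fine-grid step for the convolution, seconds.
#' @return Matrix (`n_runs * n_volumes`) x conditions, with condition
#'   column names.
#' @export
condition_regressors <- function(runs, presentation,
                                 condition_spec = "source",
                                 tr = 2, n_volumes = NULL,
                                 hrf = canonical_hrf, boxcar = FALSE,
                                 dt = 0.1) {
  if (inherits(runs, "run_design")) runs <- list(runs)
  if (is.null(n_volumes)) n_volumes <- round(runs[[1L]]$duration / tr)
  seq_name <- paste0(presentation, "_seq")
  n_images <- max(1L, suppressWarnings(
    max(unlist(lapply(runs, function(r) r[[seq_name]]$image_id)), na.rm = TRUE)))
  cond_names <- condition_names_for(condition_spec, n_images)

  hk <- hrf(seq(0, 32, by = dt))
  ngrid <- ceiling(n_volumes * tr / dt)
  vol_idx <- round((seq_len(n_volumes) - 1) * tr / dt) + 1L

  blocks <- lapply(runs, function(run) {
    ev <- condition_labels(run[[seq_name]], condition_spec)
    X <- matrix(0, n_volumes, length(cond_names),
                dimnames = list(NULL, cond_names))
    for (j in seq_along(cond_names)) {
      sel <- ev$condition == cond_names[j]
      if (!any(sel)) next
      u <- numeric(ngrid)
      if (boxcar) {
        for (i in which(sel)) {
          a <- round(ev$onset[i] / dt) + 1L
          b <- min(ngrid, a + max(1L, round(ev$duration[i] / dt)) - 1L)
          u[a:b] <- u[a:b] + 1
        }
      } else {
        at <- round(ev$onset[sel] / dt) + 1L
        at <- at[at <= ngrid]
        for (a in at) u[a] <- u[a] + 1
      }
      s <- stats::convolve(u, rev(hk), type = "open")[seq_len(ngrid)]
      X[, j] <- s[vol_idx]
    }
    X
  })
  do.call(rbind, blocks)
}

# Legendre polynomials P0..P3 (or up to `degree`) on [-1, 1], one block per run.
legendre_basis <- function(n, degree) {
  x <- seq(-1, 1, length.out = n)
  cols <- list(rep(1, n))
  if (degree >= 1) cols <- c(cols, list(x))
  if (degree >= 2) cols <- c(cols, list((3 * x^2 - 1) / 2))
  if (degree >= 3) cols <- c(cols, list((5 * x^3 - 3 * x) / 2))
  if (degree >= 4) {
    for (d in 4:degree) {
      p_nm1 <- cols[[d]]; p_nm2 <- cols[[d - 1L]]
      cols <- c(cols, list(((2 * d - 1) * x * p_nm1 - (d - 1) * p_nm2) / d))
    }
  }
  do.call(cbind, cols)
}

#' Build a censored GLM design matrix
#'
#' Condition regressors (see [condition_regressors()]) are combined with
#' per-run Legendre polynomial drift columns (degree 0..`poly_degree`,
#' block-diagonal by run), and the first `censor_n` volumes of each run are
#' dropped.
#'
#' @inheritParams condition_regressors
#' @param censor_n Number of initial volumes per run to censor (default 16,
#'   i.e., 32 s at a 2 s TR).
#' @param poly_degree Highest drift polynomial degree per run (default 3).
#' @return A list of class `design_matrix`: `X` (retained timepoints x
#'   columns), `condition_cols` and `drift_cols` (column indices),
#'   `run_index` (run of each retained row), `time_s` (acquisition time of
#'   each retained row on its run's clock), `tr`, `n_volumes`, `censor_n`,
#'   `condition_spec`, `presentation`.
#' @export
build_design_matrix <- function(runs, presentation,
                                condition_spec = "source",
                                tr = 2, n_volumes = NULL, censor_n = 16,
                                poly_degree = 3, hrf = canonical_hrf,
                                boxcar = FALSE, dt = 0.1) {
  if (inherits(runs, "run_design")) runs <- list(runs)
  if (is.null(n_volumes)) n_volumes <- round(runs[[1L]]$duration / tr)
  stopifnot(censor_n >= 0, censor_n < n_volumes)
  n_runs <- length(runs)

  C <- condition_regressors(runs, presentation, condition_spec, tr,
                            n_volumes, hrf, boxcar, dt)
  zero_cols <- colSums(abs(C)) == 0
  if (any(zero_cols)) {
    stop("condition(s) with no events: ",
         paste(colnames(C)[zero_cols], collapse = ", "))
  }

  drift_run <- legendre_basis(n_volumes, poly_degree)
  colnames(drift_run) <- paste0("poly", 0:poly_degree)
  D <- matrix(0, n_runs * n_volumes, n_runs * (poly_degree + 1L))
  dnames <- character(ncol(D))
  for (r in seq_len(n_runs)) {
    rows <- (r - 1L) * n_volumes + seq_len(n_volumes)
    cols <- (r - 1L) * (poly_degree + 1L) + seq_len(poly_degree + 1L)
    D[rows, cols] <- drift_run
    dnames[cols] <- paste0("run", r, "_", colnames(drift_run))
  }
  colnames(D) <- dnames

  keep_run <- seq_len(n_volumes) > censor_n
  keep <- rep(keep_run, n_runs)
  X <- cbind(C, D)[keep, , drop = FALSE]

  structure(list(
    X = X,
    condition_cols = seq_len(ncol(C)),
    drift_cols = ncol(C) + seq_len(ncol(D)),
    run_index = rep(seq_len(n_runs), each = n_volumes)[keep],
    time_s = rep((seq_len(n_volumes) - 1) * tr, n_runs)[keep],
    tr = tr, n_volumes = n_volumes, censor_n = censor_n,
    condition_spec = condition_spec, presentation = presentation
  ), class = "design_matrix")
}

# Autocorrelation sequence of a stationary ARMA(1,1) process at lags 0..n-1.
arma11_acf <- function(n, a, b) {
  stopifnot(abs(a) < 1)
  if (n == 1L) return(1)
  rho1 <- (1 + a * b) * (a + b) / (1 + 2 * a * b + b^2)
  c(1, rho1 * a^(0:(n - 2L)))
}

# Restricted (residual-contrast) -2 log likelihood of the data under
# ARMA(1,1) run-wise correlation, innovation variance profiled out.
# Terms constant in (a, b) are dropped.
arma11_negll <- function(par, y, X, run_index) {
  a <- par[1L]; b <- par[2L]
  if (abs(a) >= 0.97 || abs(b) >= 0.97) return(1e10)
  p <- ncol(X); N <- length(y)
  XtX <- matrix(0, p, p); Xty <- numeric(p); yty <- 0; logdet <- 0
  chol_cache <- list()
  for (r in unique(run_index)) {
    rows <- run_index == r
    n_r <- sum(rows)
    key <- as.character(n_r)
    if (is.null(chol_cache[[key]])) {
      C <- stats::toeplitz(arma11_acf(n_r, a, b))
      L <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(L)) return(1e10)
      chol_cache[[key]] <- L
    }
    L <- chol_cache[[key]]
    Xw <- backsolve(L, X[rows, , drop = FALSE], transpose = TRUE)
    yw <- backsolve(L, y[rows], transpose = TRUE)
    XtX <- XtX + crossprod(Xw)
    Xty <- Xty + crossprod(Xw, yw)
    yty <- yty + sum(yw^2)
    logdet <- logdet + 2 * sum(log(diag(L)))
  }
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  beta <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
  q <- yty - sum(Xty * beta)
  if (q <= 0) return(1e10)
  (N - p) * log(q / (N - p)) + logdet + 2 * sum(log(diag(R)))
}

#' Estimate ARMA(1,1) noise parameters (REML)
#'
#' Maximises the restricted (residual-contrast) Gaussian likelihood over
#' the AR parameter `a` and MA parameter `b`, using a coarse grid search
#' followed by local refinement; the innovation variance is profiled out.
#' The restricted likelihood accounts for the degrees of freedom absorbed
#' by the design matrix — a plain likelihood of OLS residuals would read
#' the projection-induced negative autocorrelation as real noise structure.
#' Because the ARMA(1,1) likelihood is nearly flat along the ridge of
#' near-cancelling (a, b) pairs, the white-noise model is retained unless
#' the 2-parameter model improves the deviance by a BIC-sized margin.
#'
#' @param y Signal vector (retained timepoints).
#' @param X Design matrix (same rows).
#' @param run_index Run membership of each timepoint; the stationary
#'   ARMA(1,1) correlation applies within runs, runs are independent.
#' @return Named vector `c(a = ..., b = ...)`.
#' @export
estimate_arma11 <- function(y, X, run_index) {
  val0 <- arma11_negll(c(0, 0), y, X, run_index)
  grid <- seq(-0.6, 0.6, by = 0.3)
  best <- c(0, 0); best_val <- val0
  for (a in grid) for (b in grid) {
    if (a == 0 && b == 0) next
    v <- arma11_negll(c(a, b), y, X, run_index)
    if (v < best_val) { best <- c(a, b); best_val <- v }
  }
  opt <- stats::optim(best, arma11_negll, y = y, X = X,
                      run_index = run_index, method = "Nelder-Mead",
                      control = list(maxit = 80, reltol = 1e-6))
  if (val0 - opt$value < 2 * log(length(y))) {
    return(c(a = 0, b = 0))
  }
  c(a = min(max(opt$par[1L], -0.94), 0.94),
    b = min(max(opt$par[2L], -0.94), 0.94))
}

#' Fit a GLM to a voxel (or ROI-averaged) timeseries
#'
#' With `whiten = "none"` this is ordinary least squares with classical t
#' statistics. With `whiten = "arma11"` the ARMA(1,1) noise parameters are
#' estimated from the OLS residuals (run-wise Gaussian likelihood), the
#' stationary ARMA(1,1) correlation matrix is built per run, and the model
#' is refit by generalised least squares in the whitened metric. With
#' a = b = 0 the two paths agree to numerical precision.
#'
#' @param y Signal: either a numeric vector over the *retained* timepoints
#'   (matching `nrow(dm$X)`), a full-timeline vector (censored volumes are
#'   dropped), or a `voxel_timeseries` from [simulate_voxel()].
#' @param dm A `design_matrix` from [build_design_matrix()].
#' @param whiten `"arma11"` (default) or `"none"`.
#' @param arma Optional fixed `c(a, b)` to use for whitening instead of
#'   estimating them (only with `whiten = "arma11"`).
#' @return A list of class `glm_result`: `betas`, `se`, `t` (condition
#'   columns), `residuals` (raw scale), `residuals_w` (whitened metric),
#'   `dof`, `arma` (`c(a, b)`), `sigma2`, `baseline` (temporal mean of the
#'   fitted drift timecourse), `design` (the `dm` used).
#' @export
fit_glm <- function(y, dm, whiten = c("arma11", "none"), arma = NULL) {
  whiten <- match.arg(whiten)
  stopifnot(inherits(dm, "design_matrix"))
  if (inherits(y, "voxel_timeseries")) y <- y$values
  X <- dm$X
  n <- nrow(X)
  if (length(y) != n) {
    full <- dm$n_volumes * length(unique(dm$run_index))
    if (length(y) == full) {
      keep <- rep(seq_len(dm$n_volumes) > dm$censor_n,
                  length(unique(dm$run_index)))
      y <- y[keep]
    } else {
      stop("length(y) = ", length(y), " matches neither the retained (", n,
           ") nor the full (", full, ") timepoint count")
    }
  }

  solve_ls <- function(Xw, yw) {
    qr_x <- qr(Xw)
    if (qr_x$rank < ncol(Xw)) {
      bad <- colnames(Xw)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(Xw))]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    beta <- qr.coef(qr_x, yw)
    resw <- yw - Xw %*% beta
    dof <- nrow(Xw) - ncol(Xw)
    sigma2 <- sum(resw^2) / dof
    XtXinv_p <- chol2inv(qr.R(qr_x))
    o <- order(qr_x$pivot)
    XtXinv <- XtXinv_p[o, o, drop = FALSE]
    list(beta = beta, resw = resw, dof = dof, sigma2 = sigma2,
         se = sqrt(sigma2 * diag(XtXinv)))
  }

  ols <- solve_ls(X, y)
  ab <- c(a = 0, b = 0)
  fit <- ols
  if (whiten == "arma11") {
    ab <- if (!is.null(arma)) {
      stats::setNames(as.numeric(arma), c("a", "b"))
    } else {
      estimate_arma11(y, X, dm$run_index)
    }
    if (!is.null(arma) || any(abs(ab) > 1e-8)) {
      Xw <- X; yw <- y
      for (r in unique(dm$run_index)) {
        rows <- dm$run_index == r
        L <- chol(stats::toeplitz(arma11_acf(sum(rows), ab["a"], ab["b"])))
        Xw[rows, ] <- backsolve(L, X[rows, , drop = FALSE], transpose = TRUE)
        yw[rows] <- backsolve(L, y[rows], transpose = TRUE)
      }
      fit <- solve_ls(Xw, yw)
    }
  }

  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  resid_raw <- drop(y - X %*% fit$beta)
  baseline <- mean(X[, dm$drift_cols, drop = FALSE] %*%
                     fit$beta[dm$drift_cols])
  cond <- dm$condition_cols
  structure(list(
    betas = beta,
    se = stats::setNames(fit$se, colnames(X)),
    t = stats::setNames((beta / fit$se)[cond], colnames(X)[cond]),
    residuals = resid_raw,
    residuals_w = drop(fit$resw),
    dof = fit$dof,
    arma = ab,
    sigma2 = fit$sigma2,
    baseline = baseline,
    design = dm
  ), class = "glm_result")
}

#' Threshold a t map into a localiser mask
#'
#' @param t_values Vector of per-voxel t statistics.
#' @param dof Degrees of freedom of the t statistics.
#' @param alpha Two-sided significance level (default 0.01).
#' @return Logical vector: `TRUE` where two-sided p < alpha.
#' @export
localiser_mask <- function(t_values, dof, alpha = 0.01) {
  stopifnot(dof > 0)
  2 * stats::pt(abs(t_values), dof, lower.tail = FALSE) < alpha
}

#' Spatially average voxel timeseries over a mask
#'
#' @param voxels Matrix, voxels x timepoints.
#' @param mask Logical (or index) vector selecting voxels.
#' @return Numeric vector: the unweighted mean timeseries of the selected
#'   voxels.
#' @export
roi_average <- function(voxels, mask = rep(TRUE, nrow(voxels))) {
  stopifnot(is.matrix(voxels))
  sel <- voxels[mask, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("empty localiser mask: no voxels survive the threshold")
  }
  colMeans(sel)
}

#' Convert condition betas to percent signal change
#'
#' psc = 100 x beta / baseline, with the baseline the temporal average over
#' retained timepoints of the fitted polynomial (drift) regressor
#' timecourse.
#'
#' @param fit A `glm_result` from [fit_glm()].
#' @return Named vector of percent-signal-change values, one per condition
#'   column.
#' @export
to_psc <- function(fit) {
  stopifnot(inherits(fit, "glm_result"))
  if (!is.finite(fit$baseline) || fit$baseline <= 0) {
    stop("non-positive baseline (", format(fit$baseline),
         "): percent signal change is undefined")
  }
  100 * fit$betas[fit$design$condition_cols] / fit$baseline
}

#' Mean squared residual as a function of time after trial onset
#'
#' A model-quality diagnostic: residuals are converted to percent-signal-
#' change units, squared, binned by TR lag after each image-event onset and
#' averaged. A mis-specified response model concentrates residual error at
#' early post-onset lags; white residuals give a flat curve.
#'
#' @param fit A `glm_result`.
#' @param runs The list of `run_design`s the fit used.
#' @param max_lag_s Largest post-onset lag to include, seconds (default 16).
#' @return Data frame with columns `lag_s`, `mean_sq_resid_psc`, `n`.
#' @export
residual_by_time_after_onset <- function(fit, runs, max_lag_s = 16) {
  stopifnot(inherits(fit, "glm_result"))
  if (inherits(runs, "run_design")) runs <- list(runs)
  dm <- fit$design
  res_psc <- 100 * fit$residuals / fit$baseline
  seq_name <- paste0(dm$presentation, "_seq")
  lag_bins <- seq(0, max_lag_s - dm$tr, by = dm$tr)
  tot <- stats::setNames(numeric(length(lag_bins)), lag_bins)
  cnt <- tot
  for (r in seq_along(runs)) {
    rows <- which(dm$run_index == r)
    times <- dm$time_s[rows]
    ev <- runs[[r]][[seq_name]]
    onsets <- ev$onset[ev$trial_type == "image"]
    for (o in onsets) {
      lag <- times - o
      ok <- lag >= 0 & lag < max_lag_s
      if (!any(ok)) next
      bin <- pmin(floor(lag[ok] / dm$tr) + 1L, length(lag_bins))
      sq <- res_psc[rows[ok]]^2
      for (i in seq_along(bin)) {
        tot[bin[i]] <- tot[bin[i]] + sq[i]
        cnt[bin[i]] <- cnt[bin[i]] + 1
      }
    }
  }
  data.frame(lag_s = lag_bins,
             mean_sq_resid_psc = ifelse(cnt > 0, tot / cnt, NA_real_),
             n = as.integer(cnt))
}
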