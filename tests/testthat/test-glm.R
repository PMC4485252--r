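test_that("canonical HRF has the expected shape", {
  tt <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tt)
  expect_equal(canonical_hrf(0), 0)
  expect_equal(max(h), 1, tolerance = 1e-4)
  peak <- tt[which.max(h)]
  expect_gt(peak, 4.5); expect_lt(peak, 5.5)
  # one sign change on (0, 32): positive lobe then undershoot
  inner <- h[tt > 0.02 & tt < 31]
  expect_equal(sum(diff(sign(inner)) != 0), 1)
  expect_equal(canonical_hrf(-1), 0)
})

test_that("design matrices have the protocol's row and column counts", {
  dm <- source_dm()
  expect_equal(nrow(dm$X), 1500)              # 150 retained x 10 runs
  expect_equal(length(dm$condition_cols), 2)
  expect_equal(length(dm$drift_cols), 40)     # 4 per run x 10 runs
  dml <- build_design_matrix(ten_runs(), "lower", "single")
  expect_equal(length(dml$condition_cols), 1)
  expect_equal(ncol(dml$X), 41)
  dmi <- build_design_matrix(ten_runs(), "upper", "source_by_image")
  expect_equal(length(dmi$condition_cols), 60)
})

test_that("a condition with no events is rejected by name", {
  run <- build_run(0, 10, 0, seed = 4)       # nulls only
  expect_error(build_design_matrix(list(run), "lower", "single"),
               "no events")
})

test_that("OLS betas match the hand-solved normal equations", {
  X <- cbind(cond = c(1, 2, 3, 4, 5), base = 1)
  y <- c(2, 4, 5, 4, 6)
  dm <- tiny_design(X, condition_cols = 1L, drift_cols = 2L)
  fit <- fit_glm(y, dm, whiten = "none")
  # solved by hand: [[55,15],[15,5]] beta = [71,21] -> beta = (0.8, 1.8)
  expect_equal(unname(fit$betas), c(0.8, 1.8), tolerance = 1e-10)
  expect_equal(unname(fit$baseline), 1.8)
  # residual orthogonality
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-6 * sqrt(sum(y^2)))
})

test_that("GLS with identity covariance reproduces OLS", {
  dm <- source_dm()
  v <- simulate_voxel(ten_runs(), bold_model(), "lower", "source", seed = 31)
  f_ols <- fit_glm(v, dm, whiten = "none")
  f_gls <- fit_glm(v, dm, whiten = "arma11", arma = c(0, 0))
  expect_equal(f_ols$betas, f_gls$betas, tolerance = 1e-10)
  expect_equal(f_ols$t, f_gls$t, tolerance = 1e-8)
})

test_that("ARMA estimates vanish on white noise and track true parameters", {
  dm <- source_dm()
  v <- simulate_voxel(ten_runs(), bold_model(arma_a = 0, arma_b = 0),
                      "lower", "source", seed = 9)
  f <- fit_glm(v, dm, whiten = "arma11")
  expect_lt(abs(f$arma["a"]), 0.05)
  expect_lt(abs(f$arma["b"]), 0.05)
  v2 <- simulate_voxel(ten_runs(), bold_model(arma_a = 0.5, arma_b = 0.3),
                       "lower", "source", seed = 9)
  f2 <- fit_glm(v2, dm, whiten = "arma11")
  expect_lt(abs(f2$arma["a"] - 0.5), 0.15)
  # whitened-metric residual orthogonality holds after GLS
  expect_lt(max(abs(crossprod(f2$design$X, f2$residuals_w))) /
              sqrt(sum(v2$values^2)), 1e-2)
})

test_that("rank-deficient designs name the collinear columns", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(0, 1, 0, 1))
  dm <- tiny_design(X, condition_cols = 1:2, drift_cols = 3L)
  expect_error(fit_glm(c(1, 2, 3, 4), dm, whiten = "none"),
               "rank deficient")
})

test_that("noiseless recovery through the full design is exact", {
  runs <- ten_runs()
  m0 <- bold_model(noise_sd = 0, drift_sd = 0)
  v <- simulate_voxel(runs, m0, "upper", "source", seed = 6)
  dm_up <- build_design_matrix(runs, "upper", "source")
  psc <- to_psc(fit_glm(v, dm_up, whiten = "none"))
  expect_equal(unname(psc), c(0.85, 0.84), tolerance = 1e-8)
})

test_that("localiser masks match a CDF-inversion threshold and nest in alpha", {
  dof <- 1456
  thr <- uniroot(function(t) pt(t, dof) - (1 - 0.01 / 2), c(0, 100),
                 tol = 1e-12)$root
  tv <- c(-4, -thr - 1e-6, -1, 0, 1, thr - 1e-3, thr + 1e-3, 5)
  m <- localiser_mask(tv, dof, 0.01)
  expect_equal(m, abs(tv) > thr)
  expect_false(localiser_mask(0, dof, 0.999))
  m05 <- localiser_mask(tv, dof, 0.05)
  expect_true(all(m05[m]))               # mask(0.01) subset of mask(0.05)
})

test_that("ROI averaging behaves as an unweighted spatial mean", {
  v <- matrix(rnorm(50), 5, 10)
  expect_equal(roi_average(v, c(TRUE, rep(FALSE, 4))), v[1, ])
  two <- rbind(v[1, ], -v[1, ])
  expect_equal(roi_average(two), rep(0, 10))
  expect_error(roi_average(v, rep(FALSE, 5)), "empty")
  # averaging 100 noisy copies tracks the shared signal better than any one
  set.seed(77)
  for (rep in 1:5) {
    s <- rnorm(200)
    vox <- matrix(rep(s, each = 100), 100) + matrix(rnorm(100 * 200), 100)
    avg <- roi_average(vox)
    cors <- apply(vox, 1, cor, y = s)
    expect_gt(cor(avg, s), max(cors))
  }
})

test_that("percent signal change follows its definition and guards baseline", {
  X <- cbind(cond = c(0, 1, 0, 1), base = 1)
  dm <- tiny_design(X, condition_cols = 1L, drift_cols = 2L)
  y <- 100 + 0.8 * X[, 1]
  fit <- fit_glm(y, dm, whiten = "none")
  expect_equal(unname(to_psc(fit)), 0.8, tolerance = 1e-10)
  y0 <- rep(100, 4)
  expect_equal(unname(to_psc(fit_glm(y0, dm, whiten = "none"))), 0)
  yneg <- -100 + 0.8 * X[, 1]
  expect_error(to_psc(fit_glm(yneg, dm, whiten = "none")), "baseline")
})

test_that("residual-by-lag diagnostics separate good and bad HRF models", {
  runs <- ten_runs()[1:4]
  dm <- build_design_matrix(runs, "lower", "source")
  m0 <- bold_model(noise_sd = 0, drift_sd = 0)
  v0 <- simulate_voxel(runs, m0, "lower", "source", seed = 3)
  fit0 <- fit_glm(v0, dm, whiten = "none")
  curve0 <- residual_by_time_after_onset(fit0, runs)
  expect_true(all(curve0$mean_sq_resid_psc < 1e-12))

  # white noise only: flat curve within Monte-Carlo error
  mw <- bold_model(amplitudes = list(upper.above = 0, upper.below = 0,
                                     lower.above = 0, lower.below = 0),
                   noise_sd = 1, drift_sd = 0, arma_a = 0, arma_b = 0)
  vw <- simulate_voxel(runs, mw, "lower", "source", seed = 4)
  cw <- residual_by_time_after_onset(fit_glm(vw, dm, whiten = "none"), runs)
  expect_lt(max(cw$mean_sq_resid_psc) / min(cw$mean_sq_resid_psc), 1.6)

  # mis-specified response shape: excess residual error after onset
  bad_hrf <- function(t) canonical_hrf(pmax(t - 4, 0))
  vm <- simulate_voxel(runs, bold_model(noise_sd = 0.05, drift_sd = 0),
                       "lower", "source", seed = 5)
  dm_bad <- build_design_matrix(runs, "lower", "source", hrf = bad_hrf)
  cb <- residual_by_time_after_onset(fit_glm(vm, dm_bad, whiten = "none"),
                                     runs)
  # strongly structured over post-onset lags, unlike the white-noise curve
  expect_gt(max(cb$mean_sq_resid_psc), 3 * min(cb$mean_sq_resid_psc))
})
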