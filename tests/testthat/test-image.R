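test_that("DKL conversion maps background to zero and is linear", {
  cal <- monitor_calibration()
  bg <- array(0.5, c(2, 2, 3))
  d <- rgb_to_dkl(bg, cal)
  expect_equal(max(abs(c(d$lum, d$lm, d$s))), 0)

  # pure luminance modulation: all guns scaled equally about the background
  lum_mod <- array(rep(c(0.7, 0.3, 0.55, 0.5), each = 1), c(2, 2, 1))
  lum_mod <- array(rep(lum_mod, 3), c(2, 2, 3))
  dl <- rgb_to_dkl(lum_mod, cal)
  expect_lt(max(abs(dl$lm)), 1e-12)
  expect_lt(max(abs(dl$s)), 1e-12)
  expect_gt(max(abs(dl$lum)), 0.1)

  # linearity over affine pixel combinations
  set.seed(1)
  p <- array(runif(12), c(2, 2, 3)); q <- array(runif(12), c(2, 2, 3))
  al <- 0.3
  mix <- rgb_to_dkl(al * p + (1 - al) * q, cal)
  dp <- rgb_to_dkl(p, cal); dq <- rgb_to_dkl(q, cal)
  for (ch in c("lum", "lm", "s")) {
    expect_equal(mix[[ch]], al * dp[[ch]] + (1 - al) * dq[[ch]],
                 tolerance = 1e-10)
  }
})

test_that("DKL conversion equals a hand-multiplied matrix chain", {
  cal <- monitor_calibration(red = c(0.62, 0.34, 150),
                             green = c(0.29, 0.61, 320),
                             blue = c(0.15, 0.07, 60))
  px <- array(c(0.8, 0.2, 0.4, 0.9, 0.1, 0.6), c(2, 1, 3))
  got <- rgb_to_dkl(px, cal)
  # independent scalar arithmetic, pixel by pixel
  xyz_of <- function(x, y, Y) c(x / y * Y, Y, (1 - x - y) / y * Y)
  prim <- cbind(xyz_of(0.62, 0.34, 150), xyz_of(0.29, 0.61, 320),
                xyz_of(0.15, 0.07, 60))
  sp <- rbind(c(0.15514, 0.54312, -0.03286),
              c(-0.15514, 0.45684, 0.03286),
              c(0, 0, 0.01608))
  lms_of <- function(rgb) drop(sp %*% (prim %*% rgb))
  bg <- lms_of(c(0.5, 0.5, 0.5))
  for (i in 1:2) {
    rgb <- c(px[i, 1, 1], px[i, 1, 2], px[i, 1, 3])
    lms <- lms_of(rgb)
    dL <- lms[1] - bg[1]; dM <- lms[2] - bg[2]; dS <- lms[3] - bg[3]
    expect_equal(got$lum[i, 1], (dL + dM) / (bg[1] + bg[2]),
                 tolerance = 1e-10)
    expect_equal(got$lm[i, 1], dL / bg[1] - dM / bg[2], tolerance = 1e-10)
    expect_equal(got$s[i, 1], dS / bg[3] - (dL + dM) / (bg[1] + bg[2]),
                 tolerance = 1e-10)
  }
})

test_that("out-of-range pixels are clipped with a warning", {
  px <- array(c(1.2, -0.1, rep(0.5, 10)), c(2, 2, 3))
  expect_warning(d <- rgb_to_dkl(px, monitor_calibration()), "clipped")
  expect_equal(d$n_clipped, 2)
})

test_that("Gabor kernels are odd-symmetric with the stated envelope width", {
  k <- gabor_kernel(1, 0, pix_per_deg = 39.1)
  expect_lt(abs(sum(k)), 1e-3 * sum(abs(k)))          # zero DC
  expect_equal(k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))], -k,
               tolerance = 1e-12)                     # 180 deg rotation negates
  # sigma from the one-octave bandwidth formula: 3 sigma support
  sigma_deg <- (sqrt(log(2) / 2) / pi) * 3
  expect_equal(sigma_deg, 0.5621719, tolerance = 1e-6)
  expect_equal(nrow(k), 2 * ceiling(3 * sigma_deg * 39.1) + 1)
  expect_error(gabor_kernel(16, 0, pix_per_deg = 30), "Nyquist")
})

test_that("bank energies respond to the matching grating cell", {
  ppd <- 39.1; n <- 176
  row_deg <- outer((1:n) / ppd, rep(1, n))            # varies down rows
  g90 <- sin(2 * pi * 4 * row_deg)                    # horizontal stripes
  resp <- bank_energy(g90, pix_per_deg = ppd)
  e <- resp$energies[1, , ]
  idx <- which(e == max(e), arr.ind = TRUE)
  expect_equal(rownames(e)[idx[1]], "4")
  expect_equal(colnames(e)[idx[2]], "90")

  # uniform patches produce (numerically) zero energy
  u <- bank_energy(matrix(0.7, n, n), pix_per_deg = ppd)
  expect_lt(max(u$energies), 1e-6 * n)

  # doubling contrast doubles every energy
  resp2 <- bank_energy(2 * g90, pix_per_deg = ppd)
  expect_equal(resp2$energies, 2 * resp$energies, tolerance = 1e-10)
})

test_that("energies are stable under translation and permute under rotation", {
  set.seed(8)
  big <- vfasym:::spectral_texture(200, 200, 1.2)
  a <- bank_energy(big[1:176, 1:176], pix_per_deg = 39.1,
                   sfs = c(2, 4), orientations = c(0, 45, 90, 135))
  b <- bank_energy(big[2:177, 2:177], pix_per_deg = 39.1,
                   sfs = c(2, 4), orientations = c(0, 45, 90, 135))
  expect_lt(max(abs(b$energies - a$energies) / a$energies), 0.02)

  rot <- t(big[1:176, 1:176])[176:1, ]               # 90 degree rotation
  r <- bank_energy(rot, pix_per_deg = 39.1,
                   sfs = c(2, 4), orientations = c(0, 45, 90, 135))
  perm <- a$energies[, , c("90", "135", "0", "45"), drop = FALSE]
  expect_lt(max(abs(r$energies - perm) / perm), 0.02)
})

test_that("marginals average the named axis and preserve the grand mean", {
  ppd <- 39.1
  g <- sin(2 * pi * 4 * outer(rep(1, 176), (1:176) / ppd))
  resp <- bank_energy(g, pix_per_deg = ppd)
  sf_m <- marginalize(resp, "orientation")
  ori_m <- marginalize(resp, "sf")
  expect_equal(unname(sf_m["lum", ]),
               unname(apply(resp$energies[1, , ], 1, mean)))
  expect_equal(which.max(sf_m["lum", ]), c(`4` = 3))
  expect_equal(mean(sf_m), mean(resp$energies), tolerance = 1e-12)
  expect_equal(mean(ori_m), mean(resp$energies), tolerance = 1e-12)

  flat <- resp
  flat$energies[] <- 3
  expect_true(all(marginalize(flat, "sf") == 3))
})

test_that("characterisation averages left/right pairs and plants recover", {
  set.seed(15)
  mk_patch <- function(val, id, sv, sh) {
    structure(list(pixels = array(val + 0.02 * runif(32 * 32 * 3),
                                  c(32, 32, 3)),
                   image_id = id, source_v = sv, source_h = sh,
                   pix_per_deg = 16),
              class = "image_patch")
  }
  lums <- seq(0.3, 0.7, length.out = 6)
  patches <- list()
  for (i in 1:6) {
    patches <- c(patches,
                 list(mk_patch(lums[i], i, "above", "left"),
                      mk_patch(lums[i], i, "above", "right")))
  }
  char <- characterise_set(patches, sfs = c(2, 4), orientations = c(0, 90))
  lum_mean <- char[char$channel == "lum" & char$statistic == "mean", ]
  expect_equal(nrow(lum_mean), 6)           # one row per image after pairing

  # response differences a monotone function of luminance: rho = 1
  diffs <- data.frame(image = 1:6, source = "above",
                      diff = (lum_mean$value[order(lum_mean$image)])^3)
  cors <- characterise_correlations(char, diffs)
  expect_equal(cors$rho[cors$channel == "lum" & cors$statistic == "mean"], 1)
  expect_error(characterise_correlations(char, diffs[-2, ]), "missing")
})

test_that("permuted responses give null-consistent correlation magnitudes", {
  set.seed(22)
  x <- rnorm(60)
  q95 <- quantile(replicate(200, abs(spearman(x, sample(x))$rho)), 0.95)
  # large-sample null: |rho| ~ 1.96 / sqrt(n - 1)
  expect_gt(q95, 0.15); expect_lt(q95, 0.35)
})
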