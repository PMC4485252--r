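test_that("repeated-measures ANOVA matches aov() on a balanced table", {
  tab <- toy_response_table(seed = 42)
  an <- rm_anova_3way(tab)
  tab$participant <- factor(tab$participant)
  tab$area <- factor(tab$area)
  tab$presentation <- factor(tab$presentation)
  tab$source <- factor(tab$source)
  av <- summary(aov(psc ~ area * presentation * source +
                      Error(participant / (area * presentation * source)),
                    data = tab))
  for (stratum in av) {
    t <- stratum[[1]]
    eff <- trimws(rownames(t)[1])
    if (eff == "Residuals") next
    row <- an[an$effect == eff, ]
    expect_equal(row$F, t[1, "F value"], tolerance = 1e-8)
    expect_equal(row$df1, t[1, "Df"])
    expect_equal(row$df2, t[2, "Df"])
    expect_equal(row$ss, t[1, "Sum Sq"], tolerance = 1e-8)
    expect_equal(row$ss_error, t[2, "Sum Sq"], tolerance = 1e-8)
  }
})

test_that("ANOVA sums of squares are additive on balanced data", {
  an <- rm_anova_3way(toy_response_table(seed = 7))
  total <- attr(an, "ss_total")
  parts <- attr(an, "ss_subject") + sum(an$ss) + sum(an$ss_error)
  expect_lt(abs(total - parts) / total, 1e-10)
})

test_that("1-df within effects reduce to squared paired t statistics", {
  tab <- toy_response_table(seed = 3)
  an <- rm_anova_3way(tab)
  # per-participant cell means over areas
  cm <- aggregate(psc ~ participant + presentation + source, tab, mean)
  # interaction contrast: double difference per participant
  ab <- cm[cm$source == "above", ]
  be <- cm[cm$source == "below", ]
  key <- function(d) paste(d$participant, d$presentation)
  d_ab <- ab$psc[order(ab$participant, ab$presentation)]
  d_be <- be$psc[order(be$participant, be$presentation)]
  m <- matrix(d_ab - d_be, nrow = 2)        # presentation x participant
  contrast <- m[1, ] - m[2, ]
  t_c <- mean(contrast) / (sd(contrast) / sqrt(length(contrast)))
  expect_equal(an$F[an$effect == "presentation:source"], t_c^2,
               tolerance = 1e-8)
  expect_equal(an$epsilon[an$effect == "presentation:source"], 1)
})

test_that("ANOVA rejects incomplete tables naming the missing cell", {
  tab <- toy_response_table()
  expect_error(rm_anova_3way(tab[-5, ]), "participant=")
})

test_that("image-level tables are averaged before the ANOVA", {
  tab <- toy_response_table(seed = 9)
  tab_img <- do.call(rbind, lapply(1:3, function(i) {
    t2 <- tab; t2$image <- i
    t2$psc <- t2$psc + rnorm(nrow(t2), sd = 0.1)
    t2
  }))
  avg <- aggregate(psc ~ participant + area + presentation + source,
                   tab_img, mean)
  expect_equal(rm_anova_3way(tab_img)$F, rm_anova_3way(avg)$F,
               tolerance = 1e-10)
})

test_that("Huynh-Feldt epsilon is exact for k = 2 and matches a brute-force GG", {
  set.seed(10)
  expect_equal(huynh_feldt_epsilon(matrix(rnorm(20), 10, 2))$epsilon_hf, 1)

  mat <- matrix(rnorm(30), 10, 3)
  mat[, 2] <- mat[, 2] * 2 + mat[, 1]       # break sphericity
  got <- huynh_feldt_epsilon(mat)
  # independent route: eigenvalues of the contrast covariance
  C <- contr.helmert(3)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  lam <- eigen(t(C) %*% cov(mat) %*% C, symmetric = TRUE)$values
  gg <- sum(lam)^2 / (2 * sum(lam^2))
  n <- 10; q <- 2
  hf <- (n * q * gg - 2) / (q * (n - 1 - q * gg))
  expect_equal(got$epsilon_gg, gg, tolerance = 1e-10)
  expect_equal(got$epsilon_hf, min(hf, 1), tolerance = 1e-10)
})

test_that("degenerate contrast covariance falls back to the lower bound", {
  mat <- matrix(rep(c(1, 2, 5), each = 4), 4, 3) + rnorm(4)  # equal columns
  expect_warning(eps <- huynh_feldt_epsilon(mat), "degenerate")
  expect_equal(eps$epsilon_hf, 0.5)
})

test_that("epsilon approaches 1 under compound symmetry", {
  set.seed(11)
  n <- 400
  subj <- rnorm(n, sd = 2)
  mat <- matrix(rnorm(n * 4), n, 4) + subj     # exchangeable columns
  expect_gt(huynh_feldt_epsilon(mat)$epsilon_hf, 0.95)
})

test_that("paired t follows the hand-computed value and its symmetries", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)            # differences 1, 2, 3
  res <- paired_t(x, y)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$dof, 2)
  swapped <- paired_t(y, x)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  expect_equal(paired_t(rnorm(7), rnorm(7))$dof, 6)
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("Spearman matches brute-force mid-ranks on tied data", {
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(2, 1, 3, 3, 5, 4)
  res <- spearman(x, y)
  midrank <- function(v) {
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rx <- midrank(x); ry <- midrank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho, rho, tolerance = 1e-12)
  tstat <- rho * sqrt((6 - 2) / (1 - rho^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)

  expect_equal(spearman(1:10, exp(1:10))$rho, 1)       # monotone invariance
  expect_equal(spearman(1:10, rev(1:10))$rho, -1)
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman(a, b)$rho, spearman(exp(a), b^3)$rho)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("preference ranking orders, breaks ties stably and is antisymmetric", {
  d <- data.frame(image = rep(1:30, 2),
                  source = rep(c("above", "below"), each = 30),
                  diff = 0)
  d$diff <- seq(-0.3, 0.29, by = 0.01)
  d$diff[10] <- 5                                # extreme positive entry
  r <- rank_preference(d, k = 5)
  expect_equal(r$upper_preferred$image[1], 10)
  neg <- d; neg$diff <- -neg$diff
  rn <- rank_preference(neg, k = 5)
  expect_equal(rn$lower_preferred, transform(r$upper_preferred,
                                             diff = -diff))
  # ties broken by image order
  tied <- data.frame(image = c(3, 1, 2), source = "above", diff = 1)
  expect_equal(rank_preference(tied, k = 3)$upper_preferred$image, 1:3)
  expect_error(rank_preference(d, k = 61), "exceeds")
})

test_that("display normalisation removes participant offsets only", {
  tab <- toy_response_table(seed = 13)
  shifted <- tab
  shifted$psc[shifted$participant == 3] <-
    shifted$psc[shifted$participant == 3] + 5
  norm1 <- normalize_for_display(tab)
  norm2 <- normalize_for_display(shifted)
  # the participant offset is removed up to its share of the grand mean
  expect_equal(norm2$psc, norm1$psc + 5 / 7, tolerance = 1e-12)
  # within-participant cell differences are untouched
  p3 <- tab$participant == 3
  expect_equal(diff(norm1$psc[p3]), diff(tab$psc[p3]), tolerance = 1e-12)
  # group condition means unchanged
  m0 <- aggregate(psc ~ presentation + source, tab, mean)
  m1 <- aggregate(psc ~ presentation + source, norm1, mean)
  expect_equal(m0$psc, m1$psc, tolerance = 1e-12)
  # single participant: identity
  one <- tab[tab$participant == 1, ]
  expect_equal(normalize_for_display(one)$psc, one$psc)
})
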