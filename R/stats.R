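#' @title Inference on response tables
#' @name stats-module
#' @description Three-way repeated-measures ANOVA with Huynh-Feldt
#'   correction, paired comparisons, Spearman correlations, preference
#'   ranking and within-subject normalisation for display.
NULL

# Orthonormal contrast matrix (k x (k-1)) spanning the deviations-from-mean
# subspace.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Greenhouse-Geisser and Huynh-Feldt sphericity corrections
#'
#' Given a subject-by-condition matrix for one within-subject effect, the
#' Greenhouse-Geisser epsilon is computed from the covariance of orthonormal
#' condition contrasts, and the Huynh-Feldt correction
#' `eps_HF = (n q eps_GG - 2) / (q (n - 1 - q eps_GG))` (with `q = k - 1`)
#' is applied and clipped to \[1/q, 1\].
#'
#' @param mat Numeric matrix, subjects x conditions (k >= 2 conditions,
#'   n >= 2 subjects).
#' @return A list with `epsilon_gg`, `epsilon_hf`, `k`, `n`. For k = 2 both
#'   epsilons are exactly 1 (sphericity is vacuous).
#' @export
huynh_feldt_epsilon <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 2, k >= 2)
  if (k == 2L) {
    return(list(epsilon_gg = 1, epsilon_hf = 1, k = k, n = n))
  }
  eps <- epsilon_from_contrast_scores(mat %*% orthonormal_contrasts(k))
  c(eps, list(k = k, n = n))
}

# Epsilons from subject scores on q orthonormal effect contrasts (n x q).
epsilon_from_contrast_scores <- function(D) {
  n <- nrow(D); q <- ncol(D)
  if (q == 1L) return(list(epsilon_gg = 1, epsilon_hf = 1))
  S <- stats::cov(D)
  tr <- sum(diag(S))
  tr2 <- sum(S * S)           # trace(S %*% S) for symmetric S
  if (tr2 <= .Machine$double.eps * max(tr^2, 1)) {
    warning("degenerate contrast covariance; returning the lower-bound epsilon")
    return(list(epsilon_gg = 1 / q, epsilon_hf = 1 / q))
  }
  eps_gg <- tr^2 / (q * tr2)
  eps_hf <- (n * q * eps_gg - 2) / (q * (n - 1 - q * eps_gg))
  clip <- function(e) min(max(e, 1 / q), 1)
  list(epsilon_gg = clip(eps_gg), epsilon_hf = clip(eps_hf))
}

# Mean of a named-dimension array over all dimensions except `keep`.
marginal_mean <- function(arr, keep) {
  dn <- names(dimnames(arr))
  if (length(keep) == 0L) return(mean(arr))
  apply(arr, match(keep, dn), mean)
}

#' Three-way repeated-measures ANOVA on a response table
#'
#' Classical univariate repeated-measures ANOVA for a fully within-subject
#' area (3) x presentation (2) x source (2) design. Effect sums of squares
#' are computed by the balanced-design partition (inclusion-exclusion over
#' marginal means); the error term for each effect is its interaction with
#' subjects. Huynh-Feldt epsilons are reported for every effect and used to
#' correct the degrees of freedom of effects with more than one numerator
#' degree of freedom (for 2-level-only effects epsilon is exactly 1).
#'
#' @param table Data frame with columns `participant`, `area`,
#'   `presentation`, `source` and `psc`. If an `image` column is present the
#'   table is first averaged over images. Every participant must contribute
#'   every cell.
#' @return A data frame of class `anova_table`: one row per effect with `F`,
#'   `df1`, `df2`, `epsilon` (Huynh-Feldt), `df1_corr`, `df2_corr`, `p`
#'   (computed at the corrected dof) and `ss`, `ss_error`.
#' @export
rm_anova_3way <- function(table) {
  need <- c("participant", "area", "presentation", "source", "psc")
  stopifnot(all(need %in% names(table)))
  if ("image" %in% names(table)) {
    table <- stats::aggregate(
      psc ~ participant + area + presentation + source, table, mean)
  }
  f <- list(
    subject = factor(table$participant),
    area = factor(table$area),
    presentation = factor(table$presentation),
    source = factor(table$source)
  )
  counts <- table(f$subject, f$area, f$presentation, f$source)
  if (any(counts != 1L)) {
    idx <- which(counts != 1L, arr.ind = TRUE)[1L, ]
    stop("incomplete or unbalanced design at cell (participant=",
         dimnames(counts)[[1L]][idx[1L]], ", area=",
         dimnames(counts)[[2L]][idx[2L]], ", presentation=",
         dimnames(counts)[[3L]][idx[3L]], ", source=",
         dimnames(counts)[[4L]][idx[4L]], ")")
  }

  dims <- c(subject = nlevels(f$subject), area = nlevels(f$area),
            presentation = nlevels(f$presentation),
            source = nlevels(f$source))
  Y <- array(NA_real_, dim = dims,
             dimnames = list(subject = levels(f$subject),
                             area = levels(f$area),
                             presentation = levels(f$presentation),
                             source = levels(f$source)))
  Y[cbind(as.integer(f$subject), as.integer(f$area),
          as.integer(f$presentation), as.integer(f$source))] <- table$psc

  all_factors <- names(dims)
  grand <- mean(Y)
  n_cells <- prod(dims)

  # pure (inclusion-exclusion) effect SS for any subset of factors
  effect_ss <- function(fac) {
    subs <- unlist(lapply(0:length(fac), function(m)
      utils::combn(fac, m, simplify = FALSE)), recursive = FALSE)
    acc <- array(0, dim = dims[fac], dimnames = dimnames(Y)[fac])
    if (length(fac) == 0L) return(0)
    for (s in subs) {
      term <- if (length(s) == 0L) grand else marginal_mean(Y, s)
      sgn <- (-1)^(length(fac) - length(s))
      if (length(s) == 0L) {
        acc <- acc + sgn * term
      } else {
        # broadcast the |s|-dim marginal over the dims of `fac`
        perm <- match(fac, c(s, setdiff(fac, s)))
        expanded <- aperm(array(term, dim = dims[c(s, setdiff(fac, s))]),
                          perm)
        acc <- acc + sgn * expanded
      }
    }
    (n_cells / prod(dims[fac])) * sum(acc^2)
  }

  within <- c("area", "presentation", "source")
  effects <- unlist(lapply(1:3, function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)

  rows <- lapply(effects, function(fac) {
    df1 <- prod(dims[fac] - 1L)
    df2 <- (dims[["subject"]] - 1L) * df1
    ss <- effect_ss(fac)
    ss_err <- effect_ss(c("subject", fac))
    Fv <- (ss / df1) / (ss_err / df2)

    # effect-specific orthonormal contrasts over the full within-cell grid:
    # Kronecker over factors (slowest factor first so cell flattening, with
    # the first within factor varying fastest, lines up)
    M <- matrix(1, 1, 1)
    for (w in rev(within)) {
      Mw <- if (w %in% fac) orthonormal_contrasts(dims[[w]]) else
        matrix(1 / sqrt(dims[[w]]), dims[[w]], 1)
      M <- M %x% Mw
    }
    cellmat <- matrix(Y, nrow = dims[["subject"]])   # cells: area fastest
    eps <- epsilon_from_contrast_scores(cellmat %*% M)$epsilon_hf
    df1_c <- df1 * eps
    df2_c <- df2 * eps
    data.frame(
      effect = paste(fac, collapse = ":"),
      F = Fv, df1 = df1, df2 = df2,
      epsilon = eps, df1_corr = df1_c, df2_corr = df2_c,
      p = stats::pf(Fv, df1_c, df2_c, lower.tail = FALSE),
      ss = ss, ss_error = ss_err,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "ss_subject") <- effect_ss("subject")
  attr(out, "ss_total") <- sum((Y - grand)^2)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Paired t test
#'
#' Classical paired t on the differences `x - y`, with `n - 1` degrees of
#' freedom and a two-sided p value.
#'
#' @param x,y Matched numeric vectors, length n >= 2.
#' @return A list with `t`, `dof`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("paired t requires at least 2 pairs")
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the two-sided
#' p value uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A list with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("spearman requires at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Rank image patch pairs by presentation preference
#'
#' Given per-entry response differences (upper minus lower visual field
#' presentation, one entry per image x source), returns the top-k
#' "upper-preferred" (largest differences) and "lower-preferred" (smallest)
#' entries. Ties are broken by stable image index order.
#'
#' @param diffs Data frame with columns `image`, `source` and `diff`
#'   (upper-minus-lower psc).
#' @param k Number of entries per list (default 5).
#' @return A list with data frames `upper_preferred` and `lower_preferred`,
#'   each of `k` rows ordered by preference strength.
#' @export
rank_preference <- function(diffs, k = 5) {
  stopifnot(all(c("image", "source", "diff") %in% names(diffs)))
  if (k > nrow(diffs)) {
    stop("k = ", k, " exceeds the number of entries (", nrow(diffs), ")")
  }
  up <- diffs[order(-diffs$diff, diffs$image), , drop = FALSE]
  lo <- diffs[order(diffs$diff, diffs$image), , drop = FALSE]
  rownames(up) <- rownames(lo) <- NULL
  list(upper_preferred = utils::head(up, k),
       lower_preferred = utils::head(lo, k))
}

#' Remove per-participant overall activation for display
#'
#' Within-subject normalisation for error bars: each participant's grand
#' mean is subtracted from their cells and the group grand mean added back.
#' Condition means and all within-participant differences are unchanged.
#'
#' @param table Data frame with columns `participant` and `psc` (any other
#'   index columns are preserved).
#' @return The table with `psc` normalised.
#' @export
normalize_for_display <- function(table) {
  stopifnot(all(c("participant", "psc") %in% names(table)))
  pm <- tapply(table$psc, table$participant, mean)
  table$psc <- as.numeric(table$psc - pm[as.character(table$participant)] +
                            mean(table$psc))
  rownames(table) <- NULL
  table
}
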