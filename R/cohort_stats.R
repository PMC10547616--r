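# Nonparametric statistical toolkit for the cohort-level validation:
# Spearman rank correlation, Wilcoxon rank-sum, Jonckheere-Terpstra ordered
# trend, and ROC analysis with a sensitivity+specificity-optimal cut point.
#
# Conventions, fixed a priori and exercised by the type-I-error suite:
# ties always take average ranks; rank tests switch to exact enumeration
# when the pooled sample size is <= 12 and otherwise use a normal
# approximation with tie-corrected variance; the Wilcoxon and
# Jonckheere-Terpstra normal approximations apply a 0.5 continuity
# correction (their statistics live on a unit lattice), Spearman uses the
# t approximation; all tests are two-sided unless stated.

EXACT_N_MAX <- 12L

#' Spearman rank correlation with t-approximation p value
#'
#' rho is the Pearson correlation of average ranks; the two-sided p value
#' uses the t approximation with n - 2 degrees of freedom. A constant input
#' leaves rho undefined: the result is flagged and carries NA, never a
#' silent zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `rho`, `p_value`, `n`, `undefined`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, undefined = FALSE)
}

# Mann-Whitney U (number of (a, b) pairs with a > b, ties counted 1/2),
# from the rank-sum of group a
.mann_whitney_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact permutation distribution of U by enumerating all C(n, na) group
# assignments of the pooled values
.u_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_obs <- .mann_whitney_u(a, b)
  combos <- utils::combn(n, na)
  r <- rank(pooled)
  us <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
  # two-sided by doubling the smaller tail (ties included in both tails)
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Average ranks for ties; exact enumeration of all group assignments when
#' the pooled size is <= 12, otherwise a two-sided normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param a,b numeric vectors, both nonempty.
#' @return list: `statistic` (Mann-Whitney U for `a`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  u <- .mann_whitney_u(a, b)
  if (n <= EXACT_N_MAX)
    return(list(statistic = u, p_value = .u_exact_p(a, b),
                method = "exact_permutation"))
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0)          # all values identical
    return(list(statistic = u, p_value = 1, method = "normal_approx"))
  mu <- na * nb / 2
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(statistic = u, p_value = 2 * stats::pnorm(-z),
       method = "normal_approx")
}

# JT statistic: sum over ordered group pairs i < j of
# #{u in G_i, v in G_j : u < v} + 1/2 #{u = v}
.jt_statistic <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      jt <- jt + .mann_whitney_u(groups[[j]], groups[[i]])
    }
  }
  jt
}

# enumerate JT over all distinct assignments of the pooled values to the
# ordered group sizes (multiset permutations via nested combinations).
# C[u, v] = (x_u < x_v) + (x_u == x_v)/2 is precomputed once so each
# arrangement costs a few submatrix sums.
.jt_exact_dist <- function(pooled, sizes) {
  n <- length(pooled)
  C <- outer(pooled, pooled, `<`) + 0.5 * outer(pooled, pooled, `==`)
  total <- factorial(n) / prod(factorial(sizes))
  res <- numeric(total)
  cnt <- 0L
  k <- length(sizes)
  recurse <- function(avail, gidx, chosen, acc) {
    if (gidx == k) {                 # last group takes the remainder
      cnt <<- cnt + 1L
      res[cnt] <<- acc + sum(vapply(seq_len(gidx - 1L), function(i)
        sum(C[chosen[[i]], avail]), 1.0))
      return(invisible())
    }
    ch <- utils::combn(length(avail), sizes[gidx])
    for (c_i in seq_len(ncol(ch))) {
      take <- avail[ch[, c_i]]
      rest <- avail[-ch[, c_i]]
      add <- sum(vapply(seq_len(gidx - 1L), function(i)
        sum(C[chosen[[i]], take]), 1.0))
      chosen[[gidx]] <- take
      recurse(rest, gidx + 1L, chosen, acc + add)
    }
  }
  recurse(seq_len(n), 1L, vector("list", k), 0)
  res[seq_len(cnt)]
}

#' Jonckheere-Terpstra test for an ordered trend
#'
#' Tests for a monotone trend in location across k >= 2 groups given in
#' their hypothesized order (for example visual groups A < B < C). The
#' statistic sums, over ordered group pairs, the Mann-Whitney counts of
#' pairs in the hypothesized direction, ties counting one half. Exact
#' permutation enumeration when the pooled size is <= 12; otherwise a
#' normal approximation with the tie-corrected variance.
#'
#' @param groups list of numeric vectors in increasing hypothesized order;
#'   all nonempty. Two groups reduce to a Mann-Whitney test.
#' @param alternative `"two_sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @param method `"auto"` (exact when pooled n <= 12), or force
#'   `"exact_permutation"` / `"normal_approx"`.
#' @return object of class `trend_test`: `jt_statistic`, `p_value`,
#'   `method`, `group_sizes`, `alternative`.
#' @export
jonckheere_terpstra <- function(groups, alternative = c("two_sided",
                                                        "increasing",
                                                        "decreasing"),
                                method = c("auto", "exact_permutation",
                                           "normal_approx")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of >= 2 samples in hypothesized order")
  if (any(!vapply(groups, length, 1L)))
    stop("every group must be nonempty")
  sizes <- vapply(groups, length, 1L)
  n <- sum(sizes)
  jt <- .jt_statistic(groups)

  exact <- switch(method, auto = n <= EXACT_N_MAX,
                  exact_permutation = TRUE, normal_approx = FALSE)
  if (exact) {
    dist <- .jt_exact_dist(unlist(groups), sizes)
    p <- switch(alternative,
                increasing = mean(dist >= jt - 1e-9),
                decreasing = mean(dist <= jt + 1e-9),
                two_sided = min(1, 2 * min(mean(dist >= jt - 1e-9),
                                           mean(dist <= jt + 1e-9))))
    method <- "exact_permutation"
  } else {
    pooled <- unlist(groups)
    mu <- (n^2 - sum(sizes^2)) / 4
    t_j <- table(pooled)
    s2_1 <- (n * (n - 1) * (2 * n + 5) -
               sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
               sum(t_j * (t_j - 1) * (2 * t_j + 5))) / 72
    s2_2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
      sum(t_j * (t_j - 1) * (t_j - 2)) / (36 * n * (n - 1) * (n - 2))
    s2_3 <- sum(sizes * (sizes - 1)) * sum(t_j * (t_j - 1)) /
      (8 * n * (n - 1))
    sigma2 <- s2_1 + s2_2 + s2_3
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      # 0.5 continuity correction: the JT lattice is coarse at small n
      p <- switch(alternative,
                  increasing = stats::pnorm((jt - 0.5 - mu) / sigma,
                                            lower.tail = FALSE),
                  decreasing = stats::pnorm((jt + 0.5 - mu) / sigma),
                  two_sided = min(1, 2 * stats::pnorm(
                    -max(abs(jt - mu) - 0.5, 0) / sigma)))
    }
    method <- "normal_approx"
  }
  structure(list(jt_statistic = jt, p_value = p, method = method,
                 group_sizes = sizes, alternative = alternative),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Jonckheere-Terpstra trend test (%s, %s)\nJT = %.1f, p = %.4g, groups n = %s\n",
              x$method, x$alternative, x$jt_statistic, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' ROC analysis with optimal cut point
#'
#' Builds the empirical ROC of `scores` against binary `labels`, reports the
#' trapezoidal AUC (equal to the Mann-Whitney U probability with ties
#' counted one half), a stratified-bootstrap percentile 95% CI, a p value
#' for AUC = 0.5 from the rank-sum test, and the observed threshold
#' maximizing sensitivity + specificity (smallest threshold on ties;
#' prediction is positive when score >= threshold), with sensitivity,
#' specificity and accuracy at that cut point.
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector; both classes must be present.
#' @param boot number of bootstrap replicates for the CI (default 2000).
#' @param conf confidence level (default 0.95).
#' @return object of class `roc_result`.
#' @export
roc_analysis <- function(scores, labels, boot = 2000L, conf = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  pos <- scores[labels]; neg <- scores[!labels]
  n1 <- length(pos); n0 <- length(neg)

  # empirical ROC over observed thresholds, descending; trapezoidal AUC
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(t) mean(pos >= t), 1.0)
  fpr <- vapply(th, function(t) mean(neg >= t), 1.0)
  xs <- c(0, fpr, 1); ys <- c(0, sens, 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)

  wt <- wilcoxon_rank_sum(pos, neg)

  j <- sens + (1 - fpr)
  best <- which(j >= max(j) - 1e-12)
  cut <- min(th[best])
  s_at <- mean(pos >= cut)
  sp_at <- mean(neg < cut)
  acc <- (sum(pos >= cut) + sum(neg < cut)) / (n1 + n0)

  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    aucs <- numeric(boot)
    for (b in seq_len(boot)) {
      pb <- pos[sample.int(n1, n1, replace = TRUE)]
      nb <- neg[sample.int(n0, n0, replace = TRUE)]
      aucs[b] <- .mann_whitney_u(pb, nb) / (n1 * n0)
    }
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha)))
  }
  structure(list(auc = auc, ci_95 = ci, p_vs_half = wt$p_value,
                 cut_point = cut, sensitivity = s_at, specificity = sp_at,
                 accuracy = acc, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f), p(AUC=0.5) = %.4g\ncut point %.4g: sens %.2f, spec %.2f, acc %.2f (n+ = %d, n- = %d)\n",
    x$auc, x$ci_95[1], x$ci_95[2], x$p_vs_half, x$cut_point, x$sensitivity,
    x$specificity, x$accuracy, x$n_pos, x$n_neg))
  invisible(x)
}
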