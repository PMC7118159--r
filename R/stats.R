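## Statistical kernels shared by every analytic stage. Each wraps the
## canonical base-R / survival routine behind a stable interface and is
## cross-checked against an independent oracle in the test suite.

#' Pearson correlation with a two-sided t-based p-value
#'
#' Product-moment correlation between two numeric vectors, with the p-value
#' obtained from the exact transform `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`. Neither may be
#'   constant: the correlation is undefined at zero variance.
#' @return A list with components `r`, `p` and `n`.
#' @examples
#' pearson_correlation(1:10, (1:10)^2)
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  # guard |r| = 1: p underflows to 0 rather than dividing by zero
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Two-sample Student t-test (pooled variance)
#'
#' Pooled-variance two-sided Student test. A Welch test (unequal variances)
#' is available via `var_equal = FALSE`. Zero pooled variance is handled
#' explicitly: equal means give `t = 0, p = 1`; unequal means give `p = 0`
#' with `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors, each of length `>= 2`.
#' @param var_equal Pool the variances (Student, default) or not (Welch).
#' @return A list with `t`, `p`, `df`, means of both groups and a
#'   `degenerate` flag.
#' @export
two_sample_t_test <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 observations")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  ma <- mean(a)
  mb <- mean(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (ma == mb) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  mean_a = ma, mean_b = mb, degenerate = FALSE))
    }
    return(list(t = sign(ma - mb) * Inf, p = 0,
                df = length(a) + length(b) - 2,
                mean_a = ma, mean_b = mb, degenerate = TRUE))
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter), mean_a = ma, mean_b = mb,
       degenerate = FALSE)
}

#' Odds ratio and Fisher exact test for a 2x2 alteration table
#'
#' The sample odds ratio `(a * d) / (b * c)` for a contingency table of two
#' binary events (`a` = both, `b` = only first, `c` = only second, `d` =
#' neither), with a two-sided Fisher exact p-value. The direction call is
#' `co_occurring` for OR > 1 and `mutually_exclusive` for OR < 1. When the
#' ratio is 0/0 the OR is undefined (`NA`) but the Fisher p is still
#' reported, which happens whenever one margin is empty.
#'
#' @param a,b,c,d Non-negative integer cell counts; total must be positive.
#' @return A list with `or`, `log_or`, `p`, `call` and the input cells.
#' @export
odds_ratio_test <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("table total must be positive")
  num <- a * d
  den <- b * c
  if (num == 0 && den == 0) {
    or <- NA_real_
  } else if (den == 0) {
    or <- Inf
  } else {
    or <- num / den
  }
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
  call <- if (is.na(or) || or == 1) {
    NA_character_
  } else if (or > 1) "co_occurring" else "mutually_exclusive"
  list(or = or, log_or = log(or), p = p, call = call,
       a = a, b = b, c = c, d = d)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `k` shared members between two sets of
#' sizes `n_a` and `n_b` drawn without replacement from a universe of size
#' `n_universe`: `P(X >= k)` for X hypergeometric.
#'
#' @param n_universe Universe size.
#' @param n_a,n_b Set sizes, each `<= n_universe`.
#' @param k Observed overlap, `<= min(n_a, n_b)`.
#' @return The upper-tail p-value.
#' @export
hypergeometric_overlap <- function(n_universe, n_a, n_b, k) {
  if (n_a > n_universe || n_b > n_universe) stop("set larger than universe")
  if (k > min(n_a, n_b)) {
    stop("impossible overlap: k exceeds the smaller set")
  }
  if (k < 0) stop("k must be non-negative")
  stats::phyper(k - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival curves per group and the log-rank chi-square test
#' on `k - 1` degrees of freedom, via the survival package. Groups without
#' any event make the test unreliable; the curves are still reported and the
#' result is flagged.
#'
#' @param times Follow-up times (non-negative).
#' @param events Event indicators, 1 = event, 0 = censored.
#' @param groups Group labels (>= 2 distinct values).
#' @return An object of class `survival_comparison`: per-group curves
#'   (`time`, `n_risk`, `surv`), `chi2`, `df`, `p`, `unreliable`.
#' @export
km_logrank <- function(times, events, groups) {
  times <- as.numeric(times)
  events <- as.integer(events)
  groups <- as.factor(groups)
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (any(times < 0)) stop("negative follow-up time")
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")

  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata_id <- rep(names(fit$strata), fit$strata)
  curves <- lapply(split(seq_along(fit$time), strata_id), function(i) {
    data.frame(time = fit$time[i], n_risk = fit$n.risk[i],
               n_event = fit$n.event[i], surv = fit$surv[i])
  })
  names(curves) <- sub("^groups=", "", names(curves))

  ev_per_group <- tapply(events, groups, sum)
  unreliable <- any(ev_per_group == 0)
  if (sum(events) == 0) {
    chi2 <- NA_real_; p <- NA_real_; df <- length(levels(groups)) - 1L
  } else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    chi2 <- unname(sd$chisq)
    df <- length(levels(groups)) - 1L
    p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  }
  structure(list(curves = curves, chi2 = chi2, df = df, p = p,
                 events_per_group = ev_per_group, unreliable = unreliable),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("Log-rank comparison of", length(x$curves), "groups\n")
  cat(sprintf("  chi-square = %.4g on %d df, p = %.4g\n", x$chi2, x$df, x$p))
  if (x$unreliable) cat("  NOTE: at least one group has zero events; test unreliable\n")
  invisible(x)
}

#' Seeded k-means partition with multiple restarts
#'
#' Runs `stats::kmeans` with `n_restarts` random starts under a fixed seed
#' and keeps the lowest within-cluster sum of squares. Cluster labels are
#' canonicalised by lexicographic centroid order so the labelling does not
#' depend on the internal start that won.
#'
#' @param x Numeric matrix (rows are observations).
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 25).
#' @return A list with `labels`, `centroids` and `wcss`.
#' @export
kmeans_partition <- function(x, k, seed = 1L, n_restarts = 25L) {
  x <- as.matrix(x)
  if (k <= 0 || k > nrow(x)) stop("k must be in 1..nrow(x)")
  if (k == nrow(x)) {
    # every observation its own cluster: trivially optimal, WCSS = 0
    ord <- do.call(order, as.data.frame(x))
    labels <- integer(k)
    labels[ord] <- seq_len(k)
    names(labels) <- rownames(x)
    return(list(labels = labels, centroids = x[ord, , drop = FALSE],
                wcss = 0))
  }
  set.seed(seed)
  fit <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  )
  # canonical order: sort centroids lexicographically by coordinate
  ord <- do.call(order, as.data.frame(fit$centers))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[fit$cluster]
  names(labels) <- rownames(x)
  list(labels = labels,
       centroids = fit$centers[ord, , drop = FALSE],
       wcss = fit$tot.withinss)
}
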