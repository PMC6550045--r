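# Shared statistical primitives: BH adjustment, one-way ANOVA with Fisher's
# LSD, and the two-sample Kolmogorov-Smirnov machinery.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; order-preserving (the i-th output
#' corresponds to the i-th input) and names are retained.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, clamped to at most 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-way ANOVA with Fisher's LSD post hoc test
#'
#' Omnibus F test from the between/within sum-of-squares decomposition,
#' followed by Fisher's least-significant-difference procedure: unadjusted
#' pairwise t-tests using the pooled within-group mean square on the ANOVA
#' error degrees of freedom.
#'
#' When the within-group variance is exactly zero but group means differ, F
#' is infinite; the result is flagged `degenerate` and the p-value reported
#' as the machine-epsilon bound. Identical data in all groups gives F = 0,
#' p = 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   replicates).
#' @return List with `F`, `p`, `df` (c(between, within)), `ms_within`,
#'   `degenerate`, `group_means`, and `pairwise` (data frame `group1`,
#'   `group2`, `diff`, `p`).
#' @examples
#' anova_lsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
anova_lsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups")
  if (any(lengths(groups) < 2))
    stop("every group needs >= 2 replicates")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  all_v <- unlist(groups, use.names = FALSE)
  gm <- mean(all_v)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n * (means - gm)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1; df2 <- N - k
  ms_b <- ss_between / df1
  ms_w <- ss_within / df2
  degenerate <- ms_w == 0
  if (degenerate) {
    if (ss_between == 0) { Fv <- 0; pv <- 1 } else {
      Fv <- Inf; pv <- .Machine$double.eps
    }
  } else {
    Fv <- ms_b / ms_w
    pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  pairs <- utils::combn(names(groups), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   diff = NA_real_, p = NA_real_)
  for (r in seq_len(ncol(pairs))) {
    i <- pairs[1, r]; j <- pairs[2, r]
    dd <- means[[i]] - means[[j]]
    pw$diff[r] <- dd
    if (degenerate) {
      pw$p[r] <- if (dd == 0) 1 else .Machine$double.eps
    } else {
      se <- sqrt(ms_w * (1 / n[[i]] + 1 / n[[j]]))
      pw$p[r] <- 2 * stats::pt(-abs(dd / se), df2)
    }
  }
  list(F = Fv, p = pv, df = c(between = df1, within = df2), ms_within = ms_w,
       degenerate = degenerate, group_means = means, pairwise = pw)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D = sup over t of |ECDF1(t) - ECDF2(t)|, evaluated over the pooled sample
#' points (handles ties).
#'
#' @param x,y Numeric samples, each with >= 1 observation.
#' @return The D statistic in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  f1 <- stats::ecdf(x)(pts)
  f2 <- stats::ecdf(y)(pts)
  max(abs(f1 - f2))
}

#' P-value for the two-sample Kolmogorov-Smirnov statistic
#'
#' Exact small-sample p-value (via the Smirnov distribution, accounting for
#' ties) when `n1 * n2 <= 10^4`, otherwise the asymptotic Kolmogorov series
#' with effective sample size `n1 * n2 / (n1 + n2)`.
#'
#' @param d Observed D statistic.
#' @param n1,n2 Sample sizes.
#' @param exact `TRUE`, `FALSE`, or `NULL` (auto: exact when
#'   `n1 * n2 <= 10^4`).
#' @param pooled Optional pooled data vector; supply when ties are present so
#'   the exact distribution conditions on the tie pattern.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
ks_pvalue <- function(d, n1, n2, exact = NULL, pooled = NULL) {
  if (is.null(exact)) exact <- (n1 * n2 <= 1e4)
  if (exact) {
    p <- stats::psmirnov(d, sizes = c(n1, n2), z = pooled,
                         two.sided = TRUE, lower.tail = FALSE)
    return(min(max(p, 0), 1))
  }
  ne <- n1 * n2 / (n1 + n2)
  lambda <- sqrt(ne) * d
  if (lambda == 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}
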