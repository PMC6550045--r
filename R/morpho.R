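# Circularity distribution analysis and between-group comparison.

#' Circularity distribution and high-circularity fraction
#'
#' Histograms per-cell circularity values over (0, 1] with left-open,
#' right-closed bins, and reports the fraction of cells with high
#' circularity, C in (0.5, 1.0] — the rounded, M1-like morphology. Raw values
#' above 1 (possible for small rasterized shapes) are clamped to 1 and
#' counted.
#'
#' @param cells Data frame with a `circularity` column (e.g. from
#'   [segment_cells()]), or a bare numeric vector of circularity values.
#' @param bin_width Histogram bin width; must divide 1 evenly.
#' @return List with `breaks`, `fractions` (per bin, summing to 1),
#'   `counts`, `high_fraction` (C in (0.5, 1]), `n`, `n_clamped`, and `empty`.
#' @examples
#' circularity_distribution(c(0.4, 0.6, 0.9, 1.0))$high_fraction  # 0.75
#' @export
circularity_distribution <- function(cells, bin_width = 0.1) {
  cvals <- if (is.data.frame(cells)) cells$circularity else as.numeric(cells)
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 1 evenly")
  nb <- as.integer(round(nb))
  breaks <- seq(0, 1, length.out = nb + 1)
  n_clamped <- sum(cvals > 1)
  cvals <- pmin(cvals, 1)
  if (any(cvals <= 0)) stop("circularity values must be > 0")
  if (length(cvals) == 0)
    return(list(breaks = breaks, fractions = rep(NA_real_, nb),
                counts = rep(0L, nb), high_fraction = NA_real_, n = 0L,
                n_clamped = 0L, empty = TRUE))
  # left-open, right-closed bins over (0, 1]
  counts <- tabulate(pmax(1L, ceiling(cvals / bin_width - 1e-12)), nbins = nb)
  list(breaks = breaks, fractions = counts / length(cvals), counts = counts,
       high_fraction = mean(cvals > 0.5), n = length(cvals),
       n_clamped = n_clamped, empty = FALSE)
}

#' Compare two circularity distributions by the Kolmogorov-Smirnov test
#'
#' Two-sample KS test on unbinned circularity values: D is the supremum
#' distance between the two empirical CDFs; the p-value is exact for small
#' samples and asymptotic otherwise (see [ks_pvalue()]).
#'
#' @param group1,group2 Numeric vectors of circularity values (or any
#'   continuous measurements), each non-empty.
#' @param exact Passed to [ks_pvalue()].
#' @return List with `D`, `p`, `n1`, `n2`.
#' @export
ks_compare <- function(group1, group2, exact = NULL) {
  if (length(group1) < 1 || length(group2) < 1)
    stop("both groups must be non-empty")
  d <- ks_statistic(group1, group2)
  p <- ks_pvalue(d, length(group1), length(group2), exact = exact,
                 pooled = c(group1, group2))
  list(D = d, p = p, n1 = length(group1), n2 = length(group2))
}
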