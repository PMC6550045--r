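# Transcriptome arm: count container, low-count filtering, size factors,
# simplified paired NB Wald test, regulation sets, attenuation statistic,
# immune-gene export and delta-delta-Ct fold changes.

TREATMENTS <- c("control", "amp", "beclo", "amp_beclo")

#' Four-condition count matrix with paired sample metadata
#'
#' Light container for a genes x samples integer count matrix and its sample
#' metadata. Treatments are `control` (unamputated, vehicle), `amp`
#' (amputated), `beclo` (beclomethasone) and `amp_beclo` (combined);
#' replicate ids pair samples across treatments.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param meta Data frame with columns `sample`, `treatment`, `replicate`;
#'   one row per column of `counts`, in order.
#' @return Object of class `wound_counts`: list with `counts` and `meta`.
#' @export
wound_counts <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  req <- c("sample", "treatment", "replicate")
  if (!all(req %in% names(meta))) stop("meta needs sample, treatment, replicate")
  meta <- as.data.frame(meta)[, req]
  if (nrow(meta) != ncol(counts)) stop("one meta row per counts column")
  if (!all(meta$treatment %in% TREATMENTS))
    stop("treatments must be among: ", paste(TREATMENTS, collapse = ", "))
  tt <- table(meta$treatment)
  if (any(tt < 2)) stop("each treatment present needs >= 2 replicates")
  colnames(counts) <- meta$sample
  structure(list(counts = counts, meta = meta), class = "wound_counts")
}

#' @export
print.wound_counts <- function(x, ...) {
  cat("wound_counts:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", paste(unique(x$meta$treatment), collapse = ", "), ")\n")
  invisible(x)
}

#' Remove genes with low total counts in a contrast
#'
#' For a two-group contrast, keeps the genes whose total count over all
#' samples of the two groups is at least `min_total` (default 30): genes
#' whose sum across the three replicates of both analyzed groups is lower
#' than 30 are removed before testing.
#'
#' @param cm A [wound_counts()] object.
#' @param treatment Non-control treatment of the contrast.
#' @param control Reference treatment, default `"control"`.
#' @param min_total Minimum summed count (inclusive).
#' @return Character vector of retained gene ids.
#' @export
filter_low_counts <- function(cm, treatment, control = "control",
                              min_total = 30) {
  stopifnot(inherits(cm, "wound_counts"))
  for (tr in c(treatment, control))
    if (!tr %in% cm$meta$treatment) stop("treatment not in metadata: ", tr)
  sel <- cm$meta$treatment %in% c(treatment, control)
  tot <- rowSums(cm$counts[, sel, drop = FALSE])
  rownames(cm$counts)[tot >= min_total]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over genes with nonzero
#' counts in every sample, of the ratio of the sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts Integer matrix (genes x samples) or a [wound_counts()].
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "wound_counts")) counts <- counts$counts
  ok <- rowSums(counts == 0) == 0
  if (!any(ok))
    stop("no gene has nonzero counts in all samples; ",
         "consider filtering or a pseudo-reference")
  sub <- counts[ok, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2, function(s) stats::median(s / geo))
}

#' Simplified paired negative-binomial Wald test for one contrast
#'
#' A documented stand-in for a full differential-expression engine, testing
#' one treatment against control with replicate as a blocking (pairing)
#' covariate. Per gene: counts are normalized by median-of-ratios size
#' factors; log2 fold change is computed from normalized group means with a
#' pseudocount of 0.5; the NB dispersion is estimated by method of moments
#' within each group on normalized counts, averaged, and floored at the
#' across-gene median (and at 1e-8); the gene is then fit with a fixed-
#' dispersion NB GLM `count ~ treatment + replicate` with log size factors as
#' offset, and the treatment coefficient is Wald-tested. P-values are BH-
#' adjusted across the tested genes.
#'
#' @param cm A [wound_counts()].
#' @param treatment Treatment to contrast against `control`.
#' @param control Reference treatment.
#' @param genes Genes to test; defaults to [filter_low_counts()] with the
#'   standard total-count cutoff of 30.
#' @param sf Optional size factors for the contrast's samples; computed from
#'   those samples when NULL.
#' @return Data frame with one row per tested gene: `gene`, `base_mean`
#'   (mean normalized count), `log2fc`, `fold_change` (2^log2fc), `p`,
#'   `p_adj`.
#' @export
paired_nb_test <- function(cm, treatment, control = "control", genes = NULL,
                           sf = NULL) {
  stopifnot(inherits(cm, "wound_counts"))
  if (is.null(genes)) genes <- filter_low_counts(cm, treatment, control)
  if (length(genes) == 0) stop("no genes pass the low-count filter")
  sel <- cm$meta$treatment %in% c(treatment, control)
  meta <- cm$meta[sel, ]
  counts <- cm$counts[genes, sel, drop = FALSE]
  if (is.null(sf)) sf <- size_factors(cm$counts[, sel, drop = FALSE])
  grp <- factor(meta$treatment, levels = c(control, treatment))
  repl <- factor(meta$replicate)
  norm <- sweep(counts, 2, sf, "/")
  i_ctl <- which(grp == control); i_trt <- which(grp == treatment)
  m_ctl <- rowMeans(norm[, i_ctl, drop = FALSE])
  m_trt <- rowMeans(norm[, i_trt, drop = FALSE])
  l2fc <- log2((m_trt + 0.5) / (m_ctl + 0.5))
  v_ctl <- apply(norm[, i_ctl, drop = FALSE], 1, stats::var)
  v_trt <- apply(norm[, i_trt, drop = FALSE], 1, stats::var)
  a_mom <- ((v_ctl - m_ctl) / m_ctl^2 + (v_trt - m_trt) / m_trt^2) / 2
  a_floor <- max(stats::median(pmax(a_mom, 0), na.rm = TRUE), 1e-8)
  a_mom[!is.finite(a_mom)] <- a_floor
  a_use <- pmax(a_mom, a_floor, 1e-8)
  off <- log(sf)
  p <- vapply(seq_along(genes), function(g) {
    fit <- tryCatch(
      stats::glm(counts[g, ] ~ grp + repl, offset = off,
                 family = MASS::negative.binomial(theta = 1 / a_use[g])),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::glm(counts[g, ] ~ grp + repl, offset = off,
          family = MASS::negative.binomial(theta = 1 / a_use[g])))
      })
    if (is.null(fit)) return(1)
    co <- stats::coef(summary(fit, dispersion = 1))
    rn <- paste0("grp", treatment)
    if (!rn %in% rownames(co) || !is.finite(co[rn, "z value"])) return(1)
    2 * stats::pnorm(-abs(co[rn, "z value"]))
  }, numeric(1))
  data.frame(gene = genes, base_mean = (m_ctl + m_trt) / 2, log2fc = l2fc,
             fold_change = 2^l2fc, p = p, p_adj = bh_adjust(p),
             row.names = NULL)
}

#' Classify significant regulation and compute Venn overlaps
#'
#' Applies the significance cutoffs `p_adj < 0.05` and fold change above 2
#' (up) or below 1/2 (down) to one or more contrast results, and counts all
#' pairwise and triple intersections among the up-sets and among the
#' down-sets.
#'
#' @param results Named list of contrast result data frames from
#'   [paired_nb_test()]; names are the contrast labels.
#' @param alpha Adjusted-p cutoff.
#' @param fc_cutoff Fold-change cutoff (> 1).
#' @return List with `up` and `down` (named lists of gene-id vectors per
#'   contrast) and `venn`, a data frame of intersection sizes for every
#'   non-empty combination of contrasts, within up and down separately.
#' @export
classify_regulation <- function(results, alpha = 0.05, fc_cutoff = 2) {
  stopifnot(is.list(results), !is.null(names(results)))
  up <- lapply(results, function(r)
    r$gene[r$p_adj < alpha & r$fold_change > fc_cutoff])
  down <- lapply(results, function(r)
    r$gene[r$p_adj < alpha & r$fold_change < 1 / fc_cutoff])
  combos <- unlist(lapply(seq_along(results), function(k)
    utils::combn(names(results), k, simplify = FALSE)), recursive = FALSE)
  venn <- do.call(rbind, lapply(combos, function(cs) {
    data.frame(contrasts = paste(cs, collapse = "&"),
               n_up = length(Reduce(intersect, up[cs])),
               n_down = length(Reduce(intersect, down[cs])))
  }))
  list(up = up, down = down, venn = venn)
}

#' Attenuation of the amputation response under glucocorticoid treatment
#'
#' For every gene significantly regulated by amputation, compares the log2
#' fold change under the combined amputation + beclomethasone treatment with
#' the one under amputation alone. A gene is `attenuated` when its combined
#' response is closer to zero with the same sign (|lfc_combo| < |lfc_amp| -
#' tol), `enhanced` when farther from zero with the same sign, `sign_flipped`
#' when both are nonzero with opposite signs, `unchanged` otherwise. Genes
#' absent from the combined contrast are flagged and counted as unchanged.
#'
#' Because the identity-line reading of the attenuation scatter plot counts a
#' sign-flipped gene whose combined response is smaller in magnitude as
#' attenuated, both tallies are returned: `fraction_attenuated` (strict
#' same-sign definition) and `fraction_attenuated_incl_flipped`.
#'
#' @param amp Contrast result (amputation vs control) from
#'   [paired_nb_test()].
#' @param combo Contrast result (combined treatment vs control).
#' @param amp_significant Character vector: the amputation-significant gene
#'   set (e.g. union of up and down sets from [classify_regulation()]).
#' @param tol Attenuation tolerance in log2 units (default 0: strict
#'   inequality, the identity line).
#' @return List with `table` (per-gene classification), `counts` (class
#'   tally), `fraction_attenuated`, `fraction_attenuated_incl_flipped`, and
#'   `n`.
#' @export
attenuation_fraction <- function(amp, combo, amp_significant, tol = 0) {
  if (length(amp_significant) == 0) stop("empty amputation-significant set")
  la <- stats::setNames(amp$log2fc, amp$gene)[amp_significant]
  lc <- stats::setNames(combo$log2fc, combo$gene)[amp_significant]
  missing_combo <- is.na(lc)
  lc[missing_combo] <- 0
  if (any(is.na(la))) stop("amp results must cover the amp-significant set")
  same_sign <- sign(la) == sign(lc) & lc != 0
  cls <- rep("unchanged", length(la))
  cls[same_sign & abs(lc) < abs(la) - tol] <- "attenuated"
  cls[same_sign & abs(lc) > abs(la) + tol] <- "enhanced"
  cls[sign(la) != sign(lc) & la != 0 & lc != 0] <- "sign_flipped"
  cls[missing_combo] <- "unchanged"
  tab <- data.frame(gene = amp_significant, log2fc_amp = la,
                    log2fc_amp_beclo = lc, class = cls,
                    combo_missing = missing_combo, row.names = NULL)
  counts <- table(factor(cls, levels = c("attenuated", "enhanced",
                                         "unchanged", "sign_flipped")))
  n <- length(amp_significant)
  flipped_atten <- sum(cls == "sign_flipped" & abs(lc) < abs(la) - tol)
  list(table = tab, counts = counts,
       fraction_attenuated = as.numeric(counts["attenuated"]) / n,
       fraction_attenuated_incl_flipped =
         (as.numeric(counts["attenuated"]) + flipped_atten) / n,
       n = n)
}

#' Fold-change table for a gene list across contrasts
#'
#' Long-format export of the fold change of selected genes (e.g. immune
#' marker genes) in each contrast; genes absent from a contrast's results are
#' skipped with a warning.
#'
#' @param results Named list of contrast results from [paired_nb_test()].
#' @param genes Character vector of gene ids.
#' @return Data frame with columns `gene`, `contrast`, `log2fc`,
#'   `fold_change`.
#' @export
immune_gene_table <- function(results, genes) {
  stopifnot(is.list(results), !is.null(names(results)))
  out <- list()
  for (ct in names(results)) {
    r <- results[[ct]]
    found <- genes %in% r$gene
    if (any(!found))
      warning("genes absent from contrast ", ct, ": ",
              paste(genes[!found], collapse = ", "))
    sub <- r[match(genes[found], r$gene), ]
    if (nrow(sub) > 0)
      out[[length(out) + 1]] <- data.frame(gene = sub$gene, contrast = ct,
                                           log2fc = sub$log2fc,
                                           fold_change = sub$fold_change)
  }
  if (length(out) == 0)
    return(data.frame(gene = character(), contrast = character(),
                      log2fc = numeric(), fold_change = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Delta-delta-Ct fold changes from qPCR Ct values
#'
#' Standard relative quantification: per sample and gene, delta-Ct is the
#' target Ct minus the reference-gene Ct (e.g. ppiab); delta-delta-Ct
#' subtracts the mean delta-Ct of the control samples for that gene; the
#' fold change is 2^(-delta-delta-Ct).
#'
#' @param ct Data frame with columns `sample`, `gene`, `ct`, `ref_ct`
#'   (reference-gene Ct for the same sample).
#' @param control_samples Character vector naming the control samples.
#' @return `ct` with added columns `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(ct, control_samples) {
  req <- c("sample", "gene", "ct", "ref_ct")
  if (!all(req %in% names(ct))) stop("ct needs columns: ",
                                     paste(req, collapse = ", "))
  if (any(is.na(ct$ref_ct))) stop("missing reference-gene Ct")
  if (!any(ct$sample %in% control_samples))
    stop("no control samples present in the Ct table")
  ct$dct <- ct$ct - ct$ref_ct
  ctrl_mean <- tapply(ct$dct[ct$sample %in% control_samples],
                      ct$gene[ct$sample %in% control_samples], mean)
  if (!all(ct$gene %in% names(ctrl_mean)))
    stop("every gene needs at least one control sample")
  ct$ddct <- ct$dct - as.numeric(ctrl_mean[ct$gene])
  ct$fold_change <- 2^(-ct$ddct)
  ct
}
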