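#' Leave-one-out expression comparison
#'
#' Compares each sample's r.p.m. for each gene against the mean and
#' standard deviation (n-1 estimator) of all other samples of the same
#' tissue type: fold = sample r.p.m. / leave-one-out mean,
#' z = (sample r.p.m. - mean)/sd, p = two-sided normal tail of z. Tissue
#' groups need more than `min_group_others` other samples; genes whose
#' leave-one-out mean or sd is zero are skipped for the affected
#' statistic.
#'
#' @param expr An `expression_table` (see [compute_rpm()]).
#' @param genes Optional character vector restricting the genes compared.
#' @param samples Optional character vector restricting the focal samples.
#' @param ecfg An [expression_call_config()].
#' @return Data.frame: gene_id, sample_id, subject_id, tissue, rpm,
#'   loo_mean, loo_sd, n_others, fold, z, p.
#' @export
loo_compare <- function(expr, genes = NULL, samples = NULL,
                        ecfg = expression_call_config()) {
  rpm <- expr$rpm
  if (!is.null(genes)) rpm <- rpm[rownames(rpm) %in% genes, ,
                                  drop = FALSE]
  info <- expr$samples
  focal <- if (is.null(samples)) info$sample_id else
    intersect(info$sample_id, samples)
  out <- lapply(focal, function(s) {
    tis <- info$tissue[info$sample_id == s]
    others <- info$sample_id[info$tissue == tis & info$sample_id != s]
    n_others <- length(others)
    if (n_others <= ecfg$min_group_others) return(NULL)
    om <- rpm[, others, drop = FALSE]
    loo_mean <- rowMeans(om)
    loo_sd <- apply(om, 1, stats::sd)
    x <- rpm[, s]
    fold <- ifelse(loo_mean > 0, x / loo_mean, NA_real_)
    z <- ifelse(loo_sd > 0, (x - loo_mean) / loo_sd, NA_real_)
    data.frame(gene_id = rownames(rpm), sample_id = s,
               subject_id = info$subject_id[info$sample_id == s],
               tissue = tis, rpm = x, loo_mean = loo_mean,
               loo_sd = loo_sd, n_others = n_others, fold = fold,
               z = z, p = 2 * stats::pnorm(-abs(z)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Leave-one-out statistics from summary numbers
#'
#' The same fold/z/p computation applied to a single gene given its
#' sample r.p.m. and the comparison group's mean and sd (e.g. from a
#' published summary table).
#'
#' @param rpm Focal sample r.p.m.
#' @param loo_mean,loo_sd Leave-one-out mean and standard deviation.
#' @param n_others Number of other samples.
#' @return One-row data.frame with fold, z, p.
#' @export
expression_comparison <- function(rpm, loo_mean, loo_sd, n_others) {
  fold <- ifelse(loo_mean > 0, rpm / loo_mean, NA_real_)
  z <- ifelse(loo_sd > 0, (rpm - loo_mean) / loo_sd, NA_real_)
  data.frame(rpm = rpm, loo_mean = loo_mean, loo_sd = loo_sd,
             n_others = n_others, fold = fold, z = z,
             p = 2 * stats::pnorm(-abs(z)))
}

#' Sample-level expression QC
#'
#' A sample with an excessive number of highly significant expression
#' differences from its tissue group (> `sample_qc_max_diffs` genes at
#' fold < `sample_qc_down_fold` or fold > `sample_qc_up_fold`, each with
#' p < `sample_qc_p`) indicates degraded RNA or tissue heterogeneity and
#' is excluded.
#'
#' @param comparisons Output of [loo_compare()].
#' @param ecfg An [expression_call_config()].
#' @return Data.frame per sample: sample_id, n_extreme_diffs, keep.
#' @export
sample_expression_qc <- function(comparisons,
                                 ecfg = expression_call_config()) {
  sig <- !is.na(comparisons$fold) & !is.na(comparisons$p) &
    comparisons$p < ecfg$sample_qc_p &
    (comparisons$fold < ecfg$sample_qc_down_fold |
       comparisons$fold > ecfg$sample_qc_up_fold)
  n <- tapply(sig, comparisons$sample_id, sum)
  data.frame(sample_id = names(n), n_extreme_diffs = as.integer(n),
             keep = as.integer(n) <= ecfg$sample_qc_max_diffs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify expression of extreme-ASE genes
#'
#' Labels each extreme-ASE event as upregulated (fold > `ase_up_fold`,
#' p < `ase_p`), downregulated (fold < `ase_down_fold`, p < `ase_p`) or
#' unchanged, by joining the event to the leave-one-out comparison of the
#' same gene and sample.
#'
#' @param ase_calls Output of [call_extreme_ase()], extreme rows used.
#' @param comparisons Output of [loo_compare()].
#' @param ecfg An [expression_call_config()].
#' @return ASE events with fold, z, p and `expression_class`.
#' @export
integrate_ase_expression <- function(ase_calls, comparisons,
                                     ecfg = expression_call_config()) {
  ev <- ase_calls[ase_calls$is_extreme_ase, , drop = FALSE]
  comparisons$sample_key <- paste(comparisons$gene_id,
                                  comparisons$subject_id,
                                  comparisons$tissue)
  m <- match(paste(ev$gene_id, ev$subject_id, ev$tissue),
             comparisons$sample_key)
  ev$fold <- comparisons$fold[m]
  ev$z <- comparisons$z[m]
  ev$p <- comparisons$p[m]
  ev$expression_class <- ifelse(
    is.na(ev$fold) | is.na(ev$p), "unevaluable",
    ifelse(ev$fold > ecfg$ase_up_fold & ev$p < ecfg$ase_p, "upregulated",
           ifelse(ev$fold < ecfg$ase_down_fold & ev$p < ecfg$ase_p,
                  "downregulated", "unchanged")))
  ev
}

#' Call biallelic loss of expression
#'
#' LOE candidates are genes that are highly expressed (leave-one-out mean
#' in the upper quartile of expressed genes for the tissue group) and
#' tightly regulated (coefficient of variation of the leave-one-out group
#' at most `loe_cv_max`); a candidate is called when fold < `loe_fold`
#' and p < `loe_p` (two-sided tail at |z| = 3). Restricted to
#' polyadenylated transcripts when a `polyA` gene flag is supplied.
#'
#' @param comparisons Output of [loo_compare()].
#' @param ecfg An [expression_call_config()].
#' @param polyA_genes Optional character vector of polyadenylated gene
#'   ids; when given, other genes are not called.
#' @return `comparisons` rows annotated with `candidate` and `is_loe`.
#' @export
call_loe <- function(comparisons, ecfg = expression_call_config(),
                     polyA_genes = NULL) {
  cc <- comparisons
  cc$cv <- ifelse(cc$loo_mean > 0, cc$loo_sd / cc$loo_mean, NA_real_)
  cc$candidate <- !is.na(cc$cv) & cc$cv <= ecfg$loe_cv_max
  if (ecfg$loe_upper_quartile) {
    for (tis in unique(cc$tissue)) {
      i <- cc$tissue == tis
      expressed <- i & cc$loo_mean >= expressed_rpm_min()
      q3 <- stats::quantile(cc$loo_mean[expressed], 0.75, na.rm = TRUE)
      cc$candidate[i] <- cc$candidate[i] & cc$loo_mean[i] >= q3
    }
  }
  if (!is.null(polyA_genes))
    cc$candidate <- cc$candidate & cc$gene_id %in% polyA_genes
  cc$is_loe <- cc$candidate & !is.na(cc$fold) & !is.na(cc$p) &
    cc$fold < ecfg$loe_fold & cc$p < ecfg$loe_p
  cc
}

#' Case/control burden comparison
#'
#' Fisher exact test of hit counts against cohort sizes:
#' [[case_hits, case_n - case_hits], [control_hits,
#' control_n - control_hits]].
#'
#' @param case_hits,case_n Hits and total subjects, cases.
#' @param control_hits,control_n Same for controls.
#' @return A [fisher_exact_2x2()] result.
#' @export
burden_fisher <- function(case_hits, case_n, control_hits, control_n) {
  stopifnot(case_hits <= case_n, control_hits <= control_n)
  fisher_exact_2x2(case_hits, case_n - case_hits,
                   control_hits, control_n - control_hits)
}
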