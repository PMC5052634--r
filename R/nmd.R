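#' Call nonsense-mediated decay at loss-of-function heterozygous SNPs
#'
#' For each heterozygous loss-of-function (LOF) variant with adequate
#' coverage, tests whether the allele carrying the LOF base is
#' under-expressed: NMD is called when the normal/LOF read ratio exceeds 4
#' and the two-sided exact binomial P (null 0.5), Bonferroni-corrected by
#' the number of heterozygous LOF variants in the same subject, is below
#' `p_threshold`. Direction matters: strong bias with the LOF allele
#' higher is never NMD. The correction divisor is the per-subject LOF
#' count, not the per-sample gene count, so NMD calling is more sensitive
#' than the global ASE scan.
#'
#' @param lof_counts Measurements at LOF SNPs: subject_id, tissue,
#'   gene_id, site_id, ref_reads, alt_reads, effect_class, and
#'   `lof_allele` ("ref" or "alt"; normally "alt" since the annotated
#'   change is the alternate base). Rows whose `lof_allele` is missing are
#'   skipped with a warning.
#' @param p_threshold Corrected-P threshold (0.01).
#' @param min_bias Minimum normal/LOF ratio (4, strict).
#' @param cfg A [qc_config()] (coverage filter).
#' @return Data.frame per variant measurement with lof_reads,
#'   normal_reads, nmd_bias, k (correction divisor), p_value,
#'   corrected_p, is_nmd.
#' @export
call_nmd <- function(lof_counts, p_threshold = 0.01, min_bias = 4,
                     cfg = qc_config()) {
  lc <- lof_counts
  if (!"lof_allele" %in% names(lc))
    lc$lof_allele <- rep("alt", nrow(lc))
  bad <- is.na(lc$lof_allele) | !lc$lof_allele %in% c("ref", "alt")
  if (any(bad)) {
    warning("call_nmd: ", sum(bad),
            " variant(s) with unidentifiable LOF allele skipped")
    lc <- lc[!bad, , drop = FALSE]
  }
  lc <- lc[!filter_min_coverage(lc$ref_reads, lc$alt_reads, cfg), ,
           drop = FALSE]
  if (!nrow(lc))
    return(data.frame(subject_id = character(), tissue = character(),
                      gene_id = character(), site_id = character(),
                      lof_reads = numeric(), normal_reads = numeric(),
                      nmd_bias = numeric(), k = integer(),
                      p_value = numeric(), corrected_p = numeric(),
                      is_nmd = logical(), stringsAsFactors = FALSE))
  lc$lof_reads <- ifelse(lc$lof_allele == "alt", lc$alt_reads,
                         lc$ref_reads)
  lc$normal_reads <- ifelse(lc$lof_allele == "alt", lc$ref_reads,
                            lc$alt_reads)
  lc$nmd_bias <- ifelse(lc$lof_reads == 0,
                        ifelse(lc$normal_reads == 0, NA_real_, Inf),
                        lc$normal_reads / lc$lof_reads)
  ## k: heterozygous LOF variants per subject (unique sites, any tissue)
  k_tab <- tapply(lc$site_id, lc$subject_id,
                  function(s) length(unique(s)))
  lc$k <- as.integer(k_tab[lc$subject_id])
  hi <- pmax(lc$normal_reads, lc$lof_reads)
  n <- lc$normal_reads + lc$lof_reads
  lc$p_value <- pmin(1, 2 * stats::pbinom(hi - 1, n, 0.5,
                                          lower.tail = FALSE))
  lc$corrected_p <- pmin(1, lc$k * lc$p_value)
  lc$is_nmd <- !is.na(lc$nmd_bias) & lc$nmd_bias > min_bias &
    lc$corrected_p < p_threshold
  rownames(lc) <- NULL
  lc[c("subject_id", "tissue", "gene_id", "site_id", "lof_reads",
       "normal_reads", "nmd_bias", "k", "p_value", "corrected_p",
       "is_nmd")]
}

#' Fraction of evaluable LOF genes exhibiting NMD
#'
#' @param calls Output of [call_nmd()].
#' @return List with `n_nmd`, `n_evaluable` (unique gene x subject pairs)
#'   and `fraction`.
#' @export
nmd_fraction <- function(calls) {
  if (!nrow(calls)) stop("nmd_fraction: no evaluable LOF variants")
  key <- paste(calls$gene_id, calls$subject_id)
  per <- tapply(calls$is_nmd, key, any)
  list(n_nmd = sum(per), n_evaluable = length(per),
       fraction = sum(per) / length(per))
}
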