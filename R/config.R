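#' Expressed-gene threshold in reads per million
#'
#' A gene is considered expressed in a sample when it has at least this many
#' aligned reads per million (r.p.m.). Used both for the expressed-gene flag
#' and for the fetal-heart expression filter.
#' @return Numeric scalar, 2.
#' @export
expressed_rpm_min <- function() 2

#' Derived fold-change thresholds for ASE expression integration
#'
#' An allele that loses expression halves the transcript output, so the
#' expected fold is ~0.5; an allele with extreme gain mirrors the compound
#' allele-ratio operating point of 7.2. Both are relaxed by 30% to absorb
#' variability in sex, age and genotype across the comparison group:
#' downregulated 0.5 + 0.5 x 0.3 = 0.65; upregulated 7.2 - 7.2 x 0.3 = 5
#' (rounded to the integer threshold in use).
#' @return Numeric scalar threshold.
#' @export
ase_down_fold <- function() 0.5 + 0.5 * 0.3

#' @rdname ase_down_fold
#' @export
ase_up_fold <- function() round(7.2 - 7.2 * 0.3)

#' Two-sided normal tail probability at z = -3
#'
#' The loss-of-expression significance threshold: a sample more than three
#' standard deviations below its tissue group is significant at this level.
#' @return Numeric scalar, 2 * pnorm(-3) (~2.7e-3).
#' @export
loe_p_threshold <- function() 2 * stats::pnorm(-3)

#' Quality-control configuration
#'
#' Thresholds for the subject-, SNP- and gene-level filter cascade. Defaults
#' are the operating points used throughout the analysis.
#'
#' @param min_gq Minimum genotype quality (phred-like) for a heterozygous
#'   call from DNA sequencing.
#' @param ab_low,ab_high Inclusive bounds on the DNA allele balance
#'   ALT/(REF+ALT) for a credible heterozygote.
#' @param min_snp_reads Minimum RNA-seq reads at a SNP unless both alleles
#'   are expressed.
#' @param cluster_window_bp,cluster_min_neighbors A SNP fails as clustered
#'   when at least `cluster_min_neighbors` other het SNPs lie within
#'   `cluster_window_bp`.
#' @param indel_window_bp SNPs within this distance of an indel fail.
#' @param bias_ratio,bias_min_high_reads A SNP is "biased" when the
#'   higher/lower read ratio is at least `bias_ratio` with at least
#'   `bias_min_high_reads` reads on the higher allele.
#' @param common_bias_subject_fraction,common_bias_min_subjects A SNP biased
#'   in more than this fraction of informative subjects of either cohort
#'   (with at least this many biased subjects) is removed, except
#'   loss-of-function SNPs (possible nonsense-mediated decay).
#' @param single_snp_high_reads Genes with a single het SNP above this read
#'   count and 100% monoallelic expression are excluded (suspect genotype).
#' @param unexpressed_fraction A SNP's gene fails when more than this
#'   fraction of its other het SNPs are unexpressed.
#' @param fetal_rpm_min Genes below this fetal-heart r.p.m. are excluded.
#' @param common_ase_subject_fraction Genes with ASE in more than this
#'   fraction of all subjects (including at least one control) are excluded.
#' @param subject_biallelic_min Subjects whose biallelic fraction falls
#'   below this are excluded.
#' @param subject_biallelic_min_reads Minimum reads for a SNP to enter the
#'   subject biallelic fraction.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_gq = 50,
                      ab_low = 0.2, ab_high = 0.8,
                      min_snp_reads = 5,
                      cluster_window_bp = 30, cluster_min_neighbors = 2,
                      indel_window_bp = 30,
                      bias_ratio = 7.2, bias_min_high_reads = 5,
                      common_bias_subject_fraction = 0.40,
                      common_bias_min_subjects = 3,
                      single_snp_high_reads = 20,
                      unexpressed_fraction = 0.20,
                      fetal_rpm_min = expressed_rpm_min(),
                      common_ase_subject_fraction = 0.05,
                      subject_biallelic_min = 0.75,
                      subject_biallelic_min_reads = 10) {
  cfg <- list(min_gq = min_gq, ab_low = ab_low, ab_high = ab_high,
              min_snp_reads = min_snp_reads,
              cluster_window_bp = cluster_window_bp,
              cluster_min_neighbors = cluster_min_neighbors,
              indel_window_bp = indel_window_bp,
              bias_ratio = bias_ratio,
              bias_min_high_reads = bias_min_high_reads,
              common_bias_subject_fraction = common_bias_subject_fraction,
              common_bias_min_subjects = common_bias_min_subjects,
              single_snp_high_reads = single_snp_high_reads,
              unexpressed_fraction = unexpressed_fraction,
              fetal_rpm_min = fetal_rpm_min,
              common_ase_subject_fraction = common_ase_subject_fraction,
              subject_biallelic_min = subject_biallelic_min,
              subject_biallelic_min_reads = subject_biallelic_min_reads)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                       logical(1))))
  fr <- c("common_bias_subject_fraction", "unexpressed_fraction",
          "common_ase_subject_fraction", "subject_biallelic_min",
          "ab_low", "ab_high")
  bad <- fr[!(unlist(cfg[fr]) > 0 & unlist(cfg[fr]) < 1)]
  if (length(bad)) stop("qc_config: fractions must lie in (0,1): ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "qc_config")
}

#' ASE calling configuration
#'
#' @param bias_threshold Minimum compound allele ratio for an extreme ASE
#'   call (7.2, validated on fully phased F1-style data).
#' @param p_threshold Bonferroni-corrected binomial P threshold (0.01).
#' @param min_high_reads Minimum reads on the higher allele (5).
#' @return A list of class `ase_config`.
#' @export
ase_config <- function(bias_threshold = 7.2, p_threshold = 0.01,
                       min_high_reads = 5) {
  stopifnot(bias_threshold > 0, p_threshold > 0, p_threshold < 1,
            min_high_reads >= 1)
  structure(list(bias_threshold = bias_threshold, p_threshold = p_threshold,
                 min_high_reads = min_high_reads), class = "ase_config")
}

#' Expression-comparison calling configuration
#'
#' Thresholds for classifying expression of extreme-ASE genes, sample-level
#' expression quality control, and biallelic loss-of-expression (LOE).
#' `ase_down_fold`/`ase_up_fold`/`loe_p` are derived, not free parameters;
#' see [ase_down_fold()] and [loe_p_threshold()].
#'
#' @param ase_down_fold,ase_up_fold,ase_p Fold and P thresholds for calling
#'   an ASE gene's expression down-/upregulated.
#' @param loe_fold,loe_p Fold and P thresholds for biallelic LOE.
#' @param sample_qc_max_diffs Samples with more than this many highly
#'   significant expression differences are excluded.
#' @param sample_qc_down_fold,sample_qc_up_fold,sample_qc_p Definition of a
#'   highly significant difference for sample QC.
#' @param min_group_others Minimum number of other same-tissue samples for
#'   any leave-one-out call.
#' @param loe_upper_quartile Restrict LOE candidacy to the upper expression
#'   quartile of expressed genes in the tissue group.
#' @param loe_cv_max Maximum coefficient of variation (sd/mean) of the
#'   leave-one-out group for LOE candidacy ("tightly regulated").
#' @return A list of class `expression_call_config`.
#' @export
expression_call_config <- function(ase_down_fold = cardase::ase_down_fold(),
                                   ase_up_fold = cardase::ase_up_fold(),
                                   ase_p = 0.05,
                                   loe_fold = 0.1,
                                   loe_p = loe_p_threshold(),
                                   sample_qc_max_diffs = 100,
                                   sample_qc_down_fold = 0.2,
                                   sample_qc_up_fold = 5,
                                   sample_qc_p = 0.05,
                                   min_group_others = 4,
                                   loe_upper_quartile = TRUE,
                                   loe_cv_max = 0.5) {
  cfg <- list(ase_down_fold = ase_down_fold, ase_up_fold = ase_up_fold,
              ase_p = ase_p, loe_fold = loe_fold, loe_p = loe_p,
              sample_qc_max_diffs = sample_qc_max_diffs,
              sample_qc_down_fold = sample_qc_down_fold,
              sample_qc_up_fold = sample_qc_up_fold,
              sample_qc_p = sample_qc_p,
              min_group_others = min_group_others,
              loe_upper_quartile = loe_upper_quartile,
              loe_cv_max = loe_cv_max)
  num <- cfg[setdiff(names(cfg), "loe_upper_quartile")]
  stopifnot(all(vapply(num, function(x) is.numeric(x) && x > 0, logical(1))),
            is.logical(loe_upper_quartile))
  structure(cfg, class = "expression_call_config")
}

#' Loss-of-function effect classes
#'
#' Variant effect annotations treated as loss-of-function (LOF): premature
#' stop, frameshift and canonical splice-site changes. Used by the
#' nonsense-mediated decay analysis and the common-biased-SNP exemption.
#' @return Character vector of effect-class labels.
#' @export
lof_effect_classes <- function() {
  c("STOP_GAINED", "FRAME_SHIFT", "SPLICE_SITE_ACCEPTOR",
    "SPLICE_SITE_DONOR", "nonsense", "frameshift", "splice")
}

#' Coding effect classes
#'
#' Effect-class designations identifying a gene as protein coding; genes
#' whose SNPs carry none of these are treated as noncoding and excluded.
#' @return Character vector of effect-class labels.
#' @export
coding_effect_classes <- function() {
  c("CODON_CHANGE_PLUS_CODON_DELETION", "CODON_CHANGE_PLUS_CODON_INSERTION",
    "CODON_DELETION", "CODON_INSERTION", "FRAME_SHIFT",
    "NON_SYNONYMOUS_CODING", "START_GAINED", "STOP_GAINED",
    "SYNONYMOUS_CODING", "UTR_3_PRIME", "UTR_5_PRIME",
    "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR",
    "synonymous", "missense", "nonsense", "frameshift", "splice", "UTR")
}

#' Excluded HLA genes
#'
#' The HLA locus shows pervasive allelic mapping artefacts and is excluded
#' from ASE analysis wholesale.
#' @return Character vector of gene symbols.
#' @export
hla_gene_list <- function() {
  c("HLA-A", "HLA-B", "HLA-C", "HLA-DMA", "HLA-DMB", "HLA-DOA", "HLA-DOB",
    "HLA-DPA1", "HLA-DPB1", "HLA-DQA1", "HLA-DQA2", "HLA-DQB1", "HLA-DQB2",
    "HLA-DRA", "HLA-DRB1", "HLA-DRB5", "HLA-E", "HLA-F", "HLA-G", "HLA-J",
    "HLA-P", "HLA-T")
}
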