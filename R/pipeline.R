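#' Run the full ASE/LOE discovery pipeline on a cohort
#'
#' Orchestrates the stages end to end: SNP/subject quality control, per-
#' gene allele summaries and extreme-ASE calling, gene-category filtering
#' (including the cohort common-ASE pass), imprinted-gene assessment, NMD
#' calling at loss-of-function SNPs, leave-one-out expression comparison
#' with sample QC, ASE/expression integration, biallelic LOE calling and
#' the case/control burden tests. Cohort-level filters require statistics
#' over all subjects, so calling is two-pass: a first pass tallies
#' per-gene ASE frequencies, the second pass removes common-ASE genes.
#'
#' @param cohort A `synthetic_cohort` or an equivalent list (subjects,
#'   genes, genotypes, allele_counts, expression, fetal_reference).
#' @param cfg A [qc_config()].
#' @param acfg An [ase_config()].
#' @param ecfg An [expression_call_config()].
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV with a header recording package version and seed.
#' @return A list of class `ase_pipeline_result` with elements `qc`,
#'   `subject_qc`, `summaries`, `ase_calls`, `gene_filter`,
#'   `candidate_ase`, `imprinting`, `nmd`, `comparisons`, `sample_qc`,
#'   `ase_expression`, `loe`, `burden` and `summary` (named counts).
#' @export
run_pipeline <- function(cohort, cfg = qc_config(), acfg = ase_config(),
                         ecfg = expression_call_config(),
                         out_dir = NULL) {
  qc <- run_snp_qc(cohort, cfg)
  keep_subjects <- qc$subject_qc$subject_id[qc$subject_qc$keep]
  pass <- qc$pass[qc$pass$subject_id %in% keep_subjects, , drop = FALSE]
  m_tab <- bonferroni_m(qc$measurements)

  empty_summary <- data.frame(
    gene_id = character(), subject_id = character(), tissue = character(),
    mat_sum = numeric(), pat_sum = numeric(), higher_sum = numeric(),
    lower_sum = numeric(), n_snps_used = integer(), H = numeric(),
    L = numeric(), allele_bias = numeric(), m = integer(),
    binomial_p = numeric(), corrected_p = numeric(),
    is_extreme_ase = logical(), known_imprinted = logical(),
    candidate_call = logical(), stringsAsFactors = FALSE)

  if (nrow(pass)) {
    summaries <- gene_allele_summaries(pass, m_tab)
    calls <- call_extreme_ase(summaries, cohort$genes, acfg)
  } else {
    summaries <- calls <- empty_summary
  }

  ## pass 2: gene-category filters need the cohort-wide ASE tally
  tally <- ase_gene_tally(calls, cohort$subjects)
  gene_filter <- filter_gene_categories(cohort$genes,
                                        cohort$fetal_reference,
                                        ase_tally = tally, cfg = cfg)
  bad_genes <- gene_filter$gene_id[gene_filter$fail]
  candidate_ase <- calls[calls$candidate_call &
                           !calls$gene_id %in% bad_genes, , drop = FALSE]

  catalog <- cohort$genes[!is.na(cohort$genes$imprinted_parent),
                          c("gene_id", "imprinted_parent")]
  names(catalog)[2] <- "expressed_parent"
  imprinting <- assess_imprinted_genes(calls, cohort$subjects, catalog,
                                       cohort$fetal_reference,
                                       cohort$genotypes, cfg)

  lof <- qc$measurements[
    qc$measurements$effect_class %in% lof_effect_classes() &
      !grepl("genotype_quality|low_coverage",
             qc$measurements$failed_filters) &
      qc$measurements$subject_id %in% keep_subjects, , drop = FALSE]
  nmd <- if (nrow(lof)) call_nmd(lof, cfg = cfg) else
    call_nmd(lof[0, ], cfg = cfg)

  comparisons <- loo_compare(cohort$expression, ecfg = ecfg)
  sample_qc <- sample_expression_qc(comparisons, ecfg)
  keep_samples <- sample_qc$sample_id[sample_qc$keep]
  comp_kept <- comparisons[comparisons$sample_id %in% keep_samples, ,
                           drop = FALSE]
  ase_expression <- integrate_ase_expression(candidate_ase, comp_kept,
                                             ecfg)
  loe <- call_loe(comp_kept, ecfg)

  cohort_of <- stats::setNames(cohort$subjects$cohort,
                               cohort$subjects$subject_id)
  n_case <- sum(cohort$subjects$cohort == "case" &
                  cohort$subjects$subject_id %in% keep_subjects)
  n_ctrl <- sum(cohort$subjects$cohort == "control" &
                  cohort$subjects$subject_id %in% keep_subjects)
  changed <- ase_expression$expression_class %in%
    c("upregulated", "downregulated")
  ase_chg_subj <- unique(ase_expression$subject_id[changed])
  loe_subj <- unique(loe$subject_id[loe$is_loe])
  burden <- list()
  if (n_case > 0 && n_ctrl > 0) {
    burden$ase_expression_change <- burden_fisher(
      sum(cohort_of[ase_chg_subj] == "case"), n_case,
      sum(cohort_of[ase_chg_subj] == "control"), n_ctrl)
    burden$loe <- burden_fisher(
      sum(cohort_of[loe_subj] == "case"), n_case,
      sum(cohort_of[loe_subj] == "control"), n_ctrl)
  }

  result <- list(
    qc = qc, subject_qc = qc$subject_qc, summaries = summaries,
    ase_calls = calls, gene_filter = gene_filter,
    candidate_ase = candidate_ase, imprinting = imprinting, nmd = nmd,
    comparisons = comparisons, sample_qc = sample_qc,
    ase_expression = ase_expression, loe = loe, burden = burden,
    summary = c(
      n_subjects_kept = length(keep_subjects),
      n_samples_kept = length(keep_samples),
      n_extreme_ase = sum(calls$is_extreme_ase),
      n_candidate_ase = nrow(candidate_ase),
      n_imprinted_ase = sum(imprinting$imprinted_in_heart),
      n_nmd = if (nrow(nmd)) sum(nmd$is_nmd) else 0L,
      n_loe = sum(loe$is_loe),
      n_ase_expression_changed = sum(changed)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(paste0("cardase version ",
                    as.character(utils::packageVersion("cardase"))),
             paste0("seed=", if (!is.null(cohort$config$seed))
               cohort$config$seed else NA))
    wr <- function(df, name) if (!is.null(df) && nrow(df))
      write_tsv_commented(df, file.path(out_dir, paste0(name, ".tsv")),
                          hdr)
    wr(qc$attrition, "qc_attrition")
    wr(qc$subject_qc, "subject_qc")
    wr(calls, "ase_calls")
    wr(candidate_ase, "candidate_ase")
    wr(imprinting, "imprinting")
    wr(nmd, "nmd")
    wr(sample_qc, "sample_qc")
    wr(ase_expression, "ase_expression")
    wr(loe[loe$is_loe, , drop = FALSE], "loe_calls")
    wr(data.frame(metric = names(result$summary),
                  value = as.numeric(result$summary)), "summary")
  }
  structure(result, class = "ase_pipeline_result")
}

#' @export
print.ase_pipeline_result <- function(x, ...) {
  cat("ASE/LOE pipeline result\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-26s %s\n", nm, x$summary[[nm]]))
  invisible(x)
}
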