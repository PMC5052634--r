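#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional exact test: with margins fixed, the two-sided P value is the
#' sum of hypergeometric probabilities of all tables whose probability does
#' not exceed that of the observed table (with a small relative tolerance
#' against floating-point ties). The odds ratio is the sample odds ratio
#' (a*d)/(b*c), infinite on a zero denominator.
#'
#' @param a,b,c,d Cell counts of the table rbind(c(a, b), c(c, d)).
#' @return List with `p_value`, `odds_ratio` and `table`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("fisher_exact_2x2: cells must be non-negative integers")
  if (sum(cells) == 0)
    stop("fisher_exact_2x2: all-zero table")
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p_value = p, odds_ratio = or,
       table = matrix(cells, 2, byrow = TRUE))
}

#' Combined-cohort percent ASE
#'
#' Integer percentage of informative subjects (cases + controls pooled)
#' showing ASE: round(100 * (case_num + control_num) /
#' (case_den + control_den)).
#'
#' @param case_num,case_den ASE and informative subject counts, cases.
#' @param control_num,control_den Same for controls.
#' @return Integer percent (NA when no informative subjects).
#' @export
pct_ase <- function(case_num, case_den, control_num, control_den) {
  den <- case_den + control_den
  ifelse(den == 0, NA_integer_,
         as.integer(round(100 * (case_num + control_num) / den)))
}

#' Summarize ASE of a known imprinted gene across the cohort
#'
#' Counts informative subjects (heterozygous with QC-passing, covered
#' SNPs) and subjects with ASE per cohort, derives the combined percent
#' ASE, classifies the expressed parent by majority vote of phased
#' subjects, and applies the in-heart imprinting rule (ASE fraction >=
#' `min_ase_fraction` of subjects; combined cohorts by default, per-cohort
#' behind the switch).
#'
#' @param gene_id Gene identifier.
#' @param verdicts Data.frame, one row per informative subject, with
#'   subject_id, cohort ("case"/"control"), ase (logical) and
#'   expressed_parent per subject ("maternal"/"paternal"/NA, from phase).
#' @param min_ase_fraction Membership threshold (0.5).
#' @param per_cohort If TRUE, require the ASE fraction in each cohort with
#'   informative subjects to reach the threshold.
#' @return One-row data.frame: gene_id, case_ase, case_informative,
#'   control_ase, control_informative, pct_ase, expressed_parent,
#'   imprinted_in_heart.
#' @export
summarize_imprinted_gene <- function(gene_id, verdicts,
                                     min_ase_fraction = 0.5,
                                     per_cohort = FALSE) {
  cs <- verdicts[verdicts$cohort == "case", , drop = FALSE]
  ct <- verdicts[verdicts$cohort == "control", , drop = FALSE]
  case_num <- sum(cs$ase); case_den <- nrow(cs)
  ctrl_num <- sum(ct$ase); ctrl_den <- nrow(ct)
  pct <- pct_ase(case_num, case_den, ctrl_num, ctrl_den)
  ep <- verdicts$expressed_parent[!is.na(verdicts$expressed_parent)]
  parent <- if (!length(ep)) "indeterminate" else {
    tab <- table(ep)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      warning("summarize_imprinted_gene: conflicting expressed-parent ",
              "phases for ", gene_id)
      "indeterminate"
    } else names(which.max(tab))
  }
  frac_ok <- if (per_cohort) {
    all(c(if (case_den > 0) case_num / case_den >= min_ase_fraction,
          if (ctrl_den > 0) ctrl_num / ctrl_den >= min_ase_fraction))
  } else {
    (case_den + ctrl_den) > 0 &&
      (case_num + ctrl_num) / (case_den + ctrl_den) >= min_ase_fraction
  }
  data.frame(gene_id = gene_id,
             case_ase = case_num, case_informative = case_den,
             control_ase = ctrl_num, control_informative = ctrl_den,
             pct_ase = pct, expressed_parent = parent,
             imprinted_in_heart = (case_den + ctrl_den) > 0 && frac_ok,
             stringsAsFactors = FALSE)
}

#' Assess all catalog imprinted genes in a cohort
#'
#' Builds per-subject ASE verdicts for each catalog gene from extreme-ASE
#' calls (a subject shows ASE when any of its samples is called) and
#' summarizes each gene. Genes with fetal-heart expression below the QC
#' threshold are excluded from the catalog before assessment.
#'
#' @param calls Output of [call_extreme_ase()].
#' @param subjects Subject table with subject_id, cohort.
#' @param catalog Data.frame gene_id, expressed_parent (the known catalog
#'   label, used only for reporting alongside the observed parent).
#' @param fetal_reference Data.frame gene_id, fetal_rpm.
#' @param genotypes Genotype table with subject_id, gene_id,
#'   parent_of_alt (phase source for the expressed-parent vote).
#' @param cfg A [qc_config()] (fetal r.p.m. threshold).
#' @param ... Passed to [summarize_imprinted_gene()].
#' @return Data.frame, one row per assessable catalog gene, including the
#'   catalog's `known_parent`.
#' @export
assess_imprinted_genes <- function(calls, subjects, catalog,
                                   fetal_reference, genotypes,
                                   cfg = qc_config(), ...) {
  frpm <- fetal_reference$fetal_rpm[match(catalog$gene_id,
                                          fetal_reference$gene_id)]
  keep <- is.na(frpm) | frpm >= cfg$fetal_rpm_min
  catalog <- catalog[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    g <- catalog$gene_id[i]
    cg <- calls[calls$gene_id == g, , drop = FALSE]
    if (!nrow(cg)) return(NULL)
    per_subj <- tapply(cg$is_extreme_ase, cg$subject_id, any)
    verd <- data.frame(subject_id = names(per_subj),
                       ase = as.logical(per_subj),
                       stringsAsFactors = FALSE)
    verd$cohort <- subjects$cohort[match(verd$subject_id,
                                         subjects$subject_id)]
    ## expressed parent: for ASE subjects with phased SNPs, the dominant
    ## parental side of the gene summary
    ep <- rep(NA_character_, nrow(verd))
    phased <- cg[cg$mat_sum + cg$pat_sum > 0 & cg$is_extreme_ase, ,
                 drop = FALSE]
    if (nrow(phased)) {
      dir <- tapply(phased$mat_sum - phased$pat_sum, phased$subject_id,
                    sum)
      ep[match(names(dir), verd$subject_id)] <-
        ifelse(dir > 0, "maternal", ifelse(dir < 0, "paternal", NA))
    }
    verd$expressed_parent <- ep
    s <- summarize_imprinted_gene(g, verd, ...)
    s$known_parent <- catalog$expressed_parent[i]
    s
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), case_ase = integer(),
                      case_informative = integer(), control_ase = integer(),
                      control_informative = integer(), pct_ase = integer(),
                      expressed_parent = character(),
                      imprinted_in_heart = logical(),
                      known_parent = character(), stringsAsFactors = FALSE)
  out
}

#' Parental-origin bias among imprinted genes
#'
#' Two Fisher exact tests on the catalog of imprinted genes assessed in
#' heart: (i) maternally vs paternally expressed genes cross-classified by
#' ASE vs biallelic expression; (ii) the same comparison restricted to
#' genes inside imprinted clusters (when a `cluster` flag is available).
#'
#' @param summaries Output of [assess_imprinted_genes()]; needs
#'   `known_parent` and `imprinted_in_heart`.
#' @param clusters Optional character vector of gene_ids belonging to
#'   imprinted clusters for test (ii).
#' @return List with `maternal_vs_paternal` and (optionally) `clusters`,
#'   each a [fisher_exact_2x2()] result plus the underlying counts.
#' @export
parental_bias_tests <- function(summaries, clusters = NULL) {
  tab_for <- function(s) {
    mat <- s$known_parent == "maternal"
    a <- sum(mat & s$imprinted_in_heart)
    b <- sum(mat & !s$imprinted_in_heart)
    c2 <- sum(!mat & s$imprinted_in_heart)
    d <- sum(!mat & !s$imprinted_in_heart)
    ft <- fisher_exact_2x2(a, b, c2, d)
    ft$counts <- c(maternal_ase = a, maternal_biallelic = b,
                   paternal_ase = c2, paternal_biallelic = d)
    ft
  }
  out <- list(maternal_vs_paternal = tab_for(summaries))
  if (!is.null(clusters)) {
    s <- summaries[summaries$gene_id %in% clusters, , drop = FALSE]
    if (nrow(s)) out$clusters <- tab_for(s)
  }
  out
}
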