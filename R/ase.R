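#' Assign SNP reads to allele categories
#'
#' Each heterozygous SNP measurement contributes its reads to one of four
#' categories depending on inheritance and expression: phased SNPs (known
#' parental origin of the alternate allele) contribute maternal and
#' paternal reads; unphased SNPs contribute higher- and lower-allele reads
#' under the assumption that the more highly expressed base at every SNP
#' of a gene lies on the same haplotype. An unphased SNP with equal ref
#' and alt reads carries no direction and contributes to neither sum
#' (deterministically assigning ties, e.g. to the reference base, would
#' reintroduce reference bias), but still counts as a SNP used.
#'
#' @param counts Data.frame of QC-passed measurements with `ref_reads`,
#'   `alt_reads` and `parent_of_alt`.
#' @return `counts` with numeric columns `mat`, `pat`, `higher`, `lower`.
#' @export
assign_snp_reads <- function(counts) {
  phased <- counts$parent_of_alt %in% c("maternal", "paternal")
  alt_mat <- counts$parent_of_alt == "maternal"
  counts$mat <- ifelse(phased,
                       ifelse(alt_mat, counts$alt_reads, counts$ref_reads),
                       0)
  counts$pat <- ifelse(phased,
                       ifelse(alt_mat, counts$ref_reads, counts$alt_reads),
                       0)
  tie <- counts$ref_reads == counts$alt_reads
  counts$higher <- ifelse(!phased & !tie,
                          pmax(counts$ref_reads, counts$alt_reads), 0)
  counts$lower <- ifelse(!phased & !tie,
                         pmin(counts$ref_reads, counts$alt_reads), 0)
  counts
}

#' Compound allele bias
#'
#' Reduces the four per-gene read sums to a single allele ratio. When
#' inheritance is (partly) known and one parental sum dominates, the
#' unphased higher/lower sums are folded onto the dominant parent's side:
#' bias = (higher + mat)/(lower + pat) when mat > pat, and
#' (higher + pat)/(lower + mat) when pat > mat. With no phased signal
#' (mat = pat, including both zero) the ratio is higher/lower. A zero
#' denominator with a nonzero numerator gives an infinite bias.
#'
#' @param mat,pat,higher,lower Numeric vectors of per-gene read sums.
#' @return Data.frame with `H` (numerator reads), `L` (denominator reads)
#'   and `bias`.
#' @export
compound_allele_bias <- function(mat, pat, higher, lower) {
  H <- ifelse(mat > pat, higher + mat,
              ifelse(pat > mat, higher + pat, higher))
  L <- ifelse(mat > pat, lower + pat,
              ifelse(pat > mat, lower + mat, lower))
  bias <- ifelse(H + L == 0, NA_real_, ifelse(L == 0, Inf, H / L))
  data.frame(H = H, L = L, bias = bias)
}

#' Exact binomial ASE P value with Bonferroni correction
#'
#' Two-sided exact binomial probability of the observed allele split under
#' the null of balanced expression: p = min(1, 2 * P(X >= H)) with
#' X ~ Binomial(H + L, 0.5), Bonferroni-corrected by `m`, the number of
#' genes containing expressed heterozygous SNPs in the same sample.
#'
#' @param H,L Numerator- and denominator-side read sums (H >= L as
#'   assembled by [compound_allele_bias()]).
#' @param m Number of genes tested in the sample (>= 1).
#' @return Data.frame with `binomial_p` and `corrected_p`; NA when
#'   H + L = 0.
#' @export
binomial_ase_pvalue <- function(H, L, m) {
  stopifnot(all(m >= 1))
  n <- H + L
  p <- ifelse(n == 0, NA_real_,
              pmin(1, 2 * stats::pbinom(H - 1, n, 0.5,
                                        lower.tail = FALSE)))
  data.frame(binomial_p = p, corrected_p = pmin(1, m * p))
}

#' Per-sample Bonferroni divisor
#'
#' The number of genes with at least one heterozygous SNP passing the
#' genotype-quality and coverage filters in each sample, taken before any
#' gene-level category filter (the earlier, larger count is the
#' conservative correction).
#'
#' @param measurements The `measurements` data.frame from [run_snp_qc()].
#' @return Data.frame with subject_id, tissue, m.
#' @export
bonferroni_m <- function(measurements) {
  ok <- !grepl("genotype_quality|low_coverage",
               measurements$failed_filters)
  mm <- measurements[ok, , drop = FALSE]
  key <- paste(mm$subject_id, mm$tissue)
  m <- tapply(mm$gene_id, key, function(g) length(unique(g)))
  out <- unique(data.frame(subject_id = mm$subject_id, tissue = mm$tissue,
                           key = key, stringsAsFactors = FALSE))
  out$m <- as.integer(m[out$key])
  out$key <- NULL
  out
}

#' Per-gene allele summaries for every sample
#'
#' Sums assigned reads per gene x subject x tissue, computes the compound
#' allele bias and the Bonferroni-corrected binomial P value.
#'
#' @param counts QC-passed measurements (see [run_snp_qc()] `pass`).
#' @param m_table Data.frame subject_id, tissue, m from [bonferroni_m()];
#'   defaults to counting genes within `counts` itself.
#' @return Data.frame, one row per gene x sample, with the four category
#'   sums, n_snps_used, H, L, allele_bias, binomial_p, corrected_p.
#' @export
gene_allele_summaries <- function(counts, m_table = NULL) {
  counts <- assign_snp_reads(counts)
  key <- interaction(counts$gene_id, counts$subject_id, counts$tissue,
                     drop = TRUE)
  agg <- function(x, f = sum) as.numeric(tapply(x, key, f))
  first <- function(x) as.character(tapply(as.character(x), key,
                                           function(v) v[1]))
  out <- data.frame(
    gene_id = first(counts$gene_id),
    subject_id = first(counts$subject_id),
    tissue = first(counts$tissue),
    mat_sum = agg(counts$mat), pat_sum = agg(counts$pat),
    higher_sum = agg(counts$higher), lower_sum = agg(counts$lower),
    n_snps_used = as.integer(tapply(key, key, length)),
    stringsAsFactors = FALSE)
  cab <- compound_allele_bias(out$mat_sum, out$pat_sum,
                              out$higher_sum, out$lower_sum)
  out$H <- cab$H; out$L <- cab$L; out$allele_bias <- cab$bias
  if (is.null(m_table)) {
    m_table <- bonferroni_m(
      data.frame(subject_id = counts$subject_id, tissue = counts$tissue,
                 gene_id = counts$gene_id, failed_filters = "",
                 stringsAsFactors = FALSE))
  }
  m <- m_table$m[match(paste(out$subject_id, out$tissue),
                       paste(m_table$subject_id, m_table$tissue))]
  pv <- binomial_ase_pvalue(out$H, out$L, pmax(1, m))
  out$m <- m
  out$binomial_p <- pv$binomial_p
  out$corrected_p <- pv$corrected_p
  out[!is.na(out$binomial_p), , drop = FALSE]
}

#' Call extreme allele-specific expression
#'
#' A gene in a sample has extreme ASE when its compound allele ratio is at
#' least `bias_threshold` (7.2), its Bonferroni-corrected binomial P is
#' below `p_threshold` (0.01), and the higher allele has at least
#' `min_high_reads` reads. Events in known imprinted genes are flagged and
#' excluded from the non-imprinted call set (they are expected ASE, not
#' disease candidates).
#'
#' @param summaries From [gene_allele_summaries()].
#' @param genes Gene table with gene_id and imprinted_parent (NA when not
#'   in the imprinted catalog).
#' @param acfg An [ase_config()].
#' @return `summaries` with logical columns `is_extreme_ase`,
#'   `known_imprinted` and `candidate_call` (extreme ASE outside the
#'   imprinted catalog).
#' @export
call_extreme_ase <- function(summaries, genes = NULL,
                             acfg = ase_config()) {
  summaries$is_extreme_ase <-
    !is.na(summaries$allele_bias) &
    summaries$allele_bias >= acfg$bias_threshold &
    summaries$corrected_p < acfg$p_threshold &
    summaries$H >= acfg$min_high_reads
  imprinted <- rep(FALSE, nrow(summaries))
  if (!is.null(genes)) {
    ip <- genes$imprinted_parent[match(summaries$gene_id, genes$gene_id)]
    imprinted <- !is.na(ip)
  }
  summaries$known_imprinted <- imprinted
  summaries$candidate_call <- summaries$is_extreme_ase & !imprinted
  summaries
}

#' Tally ASE calls per gene across the cohort
#'
#' Counts subjects with at least one extreme-ASE sample per gene, for the
#' common-ASE gene filter.
#'
#' @param calls Output of [call_extreme_ase()].
#' @param subjects Subject table with subject_id and cohort.
#' @return Data.frame gene_id, n_ase_subjects, n_ase_controls,
#'   n_subjects_total.
#' @export
ase_gene_tally <- function(calls, subjects) {
  hit <- calls[calls$is_extreme_ase, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(gene_id = character(), n_ase_subjects = integer(),
                      n_ase_controls = integer(),
                      n_subjects_total = integer()))
  hit$cohort <- subjects$cohort[match(hit$subject_id,
                                      subjects$subject_id)]
  per <- unique(hit[c("gene_id", "subject_id", "cohort")])
  n <- tapply(per$subject_id, per$gene_id, length)
  nc <- tapply(per$cohort == "control", per$gene_id, sum)
  data.frame(gene_id = names(n), n_ase_subjects = as.integer(n),
             n_ase_controls = as.integer(nc),
             n_subjects_total = nrow(subjects),
             row.names = NULL, stringsAsFactors = FALSE)
}

phased_hap_sums <- function(counts, genotypes) {
  key_gt <- paste(genotypes$subject_id, genotypes$site_id)
  altA <- genotypes$alt_on_hapA[match(paste(counts$subject_id,
                                            counts$site_id), key_gt)]
  counts$hapA <- ifelse(altA, counts$alt_reads, counts$ref_reads)
  counts$hapB <- ifelse(altA, counts$ref_reads, counts$alt_reads)
  counts
}

#' False-assignment rate of the higher-allele phasing heuristic
#'
#' On a cohort whose true haplotypes are known, makes unphased extreme-ASE
#' calls (higher-allele assignment) over a grid of minimum allele bias and
#' minimum per-SNP read depth, and checks each call against the fully
#' phased computation. A call is false when the phased sums do not support
#' it: the truly over-expressed haplotype's compound ratio or corrected P
#' fails the same thresholds.
#'
#' @param cohort A `synthetic_cohort` (true haplotypes in
#'   `genotypes$alt_on_hapA`).
#' @param counts QC-passed measurements; defaults to all of
#'   `cohort$allele_counts` merged with genotype annotation.
#' @param bias_grid Minimum compound allele ratios to evaluate.
#' @param depth_grid Minimum per-SNP read depths to evaluate.
#' @param p_threshold Bonferroni-corrected P threshold for a call.
#' @return Data.frame: bias, depth, true_calls, false_calls, fp_rate.
#' @export
evaluate_phasing_grid <- function(cohort, counts = NULL,
                                  bias_grid = c(4, 5, 6, 7, 7.2),
                                  depth_grid = 4:10,
                                  p_threshold = 0.01) {
  if (is.null(counts)) {
    counts <- merge(cohort$allele_counts,
                    cohort$genotypes[c("subject_id", "site_id", "gene_id")],
                    by = c("subject_id", "site_id"), sort = FALSE)
  }
  counts <- phased_hap_sums(counts, cohort$genotypes)
  counts$parent_of_alt <- "unknown"  # heuristic mode
  grid <- expand.grid(bias = bias_grid, depth = depth_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    b <- grid$bias[i]; d <- grid$depth[i]
    cc <- counts[counts$ref_reads + counts$alt_reads >= d, , drop = FALSE]
    if (!nrow(cc))
      return(data.frame(bias = b, depth = d, true_calls = 0L,
                        false_calls = 0L, fp_rate = NA_real_))
    summ <- gene_allele_summaries(cc)
    key <- paste(cc$gene_id, cc$subject_id, cc$tissue)
    A <- tapply(cc$hapA, key, sum)
    B <- tapply(cc$hapB, key, sum)
    k2 <- paste(summ$gene_id, summ$subject_id, summ$tissue)
    A <- as.numeric(A[match(k2, names(A))])
    B <- as.numeric(B[match(k2, names(B))])
    called <- !is.na(summ$allele_bias) & summ$allele_bias >= b &
      summ$corrected_p < p_threshold & summ$H >= 5
    if (!any(called))
      return(data.frame(bias = b, depth = d, true_calls = 0L,
                        false_calls = 0L, fp_rate = NA_real_))
    hi <- pmax(A, B); lo <- pmin(A, B)
    ph_bias <- ifelse(lo == 0, Inf, hi / lo)
    ph_p <- binomial_ase_pvalue(hi, lo, pmax(1, summ$m))$corrected_p
    true_call <- called & ph_bias >= b & ph_p < p_threshold
    data.frame(bias = b, depth = d,
               true_calls = sum(true_call),
               false_calls = sum(called & !true_call),
               fp_rate = sum(called & !true_call) / sum(called))
  })
  do.call(rbind, res)
}

#' Concordance of phased and unphased ASE calls
#'
#' Calls extreme ASE twice on the same measurements — once using parental
#' phase where available, once ignoring it — and returns the two call sets
#' and their symmetric difference. Strong ASE events are expected to be
#' called identically either way.
#'
#' @param counts QC-passed measurements including `parent_of_alt`.
#' @param genes Gene table (for the imprinted flag), optional.
#' @param acfg An [ase_config()].
#' @return List with `phased`, `unphased` (character keys
#'   gene|subject|tissue) and `symmetric_difference`.
#' @export
phased_unphased_concordance <- function(counts, genes = NULL,
                                        acfg = ase_config()) {
  m_tab <- bonferroni_m(
    data.frame(subject_id = counts$subject_id, tissue = counts$tissue,
               gene_id = counts$gene_id, failed_filters = "",
               stringsAsFactors = FALSE))
  call_keys <- function(cc) {
    s <- call_extreme_ase(gene_allele_summaries(cc, m_tab), genes, acfg)
    s <- s[s$is_extreme_ase, , drop = FALSE]
    paste(s$gene_id, s$subject_id, s$tissue, sep = "|")
  }
  with_phase <- call_keys(counts)
  no_phase <- counts
  no_phase$parent_of_alt <- "unknown"
  without_phase <- call_keys(no_phase)
  list(phased = with_phase, unphased = without_phase,
       symmetric_difference = union(setdiff(with_phase, without_phase),
                                    setdiff(without_phase, with_phase)))
}
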