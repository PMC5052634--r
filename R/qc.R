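#' Genotype-quality filter
#'
#' A heterozygous call from DNA sequencing is credible when its genotype
#' quality is at least `min_gq` and its DNA allele balance lies inside
#' [`ab_low`, `ab_high`] (inclusive). SNPs with missing GQ/AB (for example
#' array-genotyped controls) are passed with a note rather than failed.
#'
#' @param snps Data.frame with `gq` and `dna_ab` columns.
#' @param cfg A [qc_config()].
#' @return Logical vector, TRUE = fail.
#' @export
filter_genotype_quality <- function(snps, cfg = qc_config()) {
  gq_fail <- !is.na(snps$gq) & snps$gq < cfg$min_gq
  ab_fail <- !is.na(snps$dna_ab) &
    (snps$dna_ab < cfg$ab_low | snps$dna_ab > cfg$ab_high)
  if (anyNA(snps$gq) || anyNA(snps$dna_ab))
    message("filter_genotype_quality: ",
            sum(is.na(snps$gq) | is.na(snps$dna_ab)),
            " SNP(s) without GQ/AB skipped (not failed)")
  gq_fail | ab_fail
}

#' Minimum-coverage filter
#'
#' A SNP measurement is analysable when it has at least `min_snp_reads`
#' RNA-seq reads, or when both alleles are expressed (>= 1 read each).
#'
#' @param ref_reads,alt_reads Integer vectors.
#' @param cfg A [qc_config()].
#' @return Logical vector, TRUE = fail.
#' @export
filter_min_coverage <- function(ref_reads, alt_reads, cfg = qc_config()) {
  !((ref_reads + alt_reads) >= cfg$min_snp_reads |
      (ref_reads >= 1 & alt_reads >= 1))
}

#' Count close neighbours per SNP
#'
#' For each position, the number of other positions (same subject, same
#' chromosome) within `window` bp. Used for the clustered-SNP and
#' near-indel filters: clustered reads misalign.
#'
#' @param subject_id,chrom,pos Parallel vectors describing SNPs.
#' @param window Window in bp.
#' @param targets Optional data.frame(subject_id, chrom, pos) of positions
#'   to count against (e.g. indels); defaults to the SNPs themselves
#'   (self excluded).
#' @return Integer vector of neighbour counts.
#' @export
count_neighbors <- function(subject_id, chrom, pos, window = 30,
                            targets = NULL) {
  key <- paste(subject_id, chrom)
  self <- is.null(targets)
  if (self) {
    tkey <- key; tpos <- pos
  } else {
    tkey <- paste(targets$subject_id, targets$chrom); tpos <- targets$pos
  }
  out <- integer(length(pos))
  for (k in unique(key)) {
    i <- which(key == k)
    tp <- sort(tpos[tkey == k])
    if (!length(tp)) next
    n <- findInterval(pos[i] + window, tp) -
      findInterval(pos[i] - window - 1e-9, tp)
    if (self) n <- n - 1L
    out[i] <- n
  }
  out
}

#' Positional artefact filters
#'
#' Fails SNPs whose reads are prone to misalignment: `clustered` (at least
#' `cluster_min_neighbors` other het SNPs within `cluster_window_bp`),
#' `near_indel` (an indel within `indel_window_bp`), and `repeat_region`
#' (precomputed flag from multi-locus alignment of the flanking sequence).
#'
#' @param snps Data.frame with subject_id, chrom, pos and optional logical
#'   `flag_clustered`, `flag_near_indel`, `flag_repeat` columns.
#' @param indels Optional data.frame(subject_id, chrom, pos) of indel
#'   positions.
#' @param cfg A [qc_config()].
#' @return Data.frame of logical columns clustered, near_indel,
#'   repeat_region.
#' @export
filter_positional <- function(snps, indels = NULL, cfg = qc_config()) {
  flag <- function(nm) if (nm %in% names(snps)) snps[[nm]] else
    rep(FALSE, nrow(snps))
  clustered <- flag("flag_clustered") |
    count_neighbors(snps$subject_id, snps$chrom, snps$pos,
                    cfg$cluster_window_bp) >= cfg$cluster_min_neighbors
  near_indel <- flag("flag_near_indel")
  if (!is.null(indels) && nrow(indels))
    near_indel <- near_indel |
      count_neighbors(snps$subject_id, snps$chrom, snps$pos,
                      cfg$indel_window_bp, targets = indels) >= 1
  data.frame(clustered = clustered, near_indel = near_indel,
             repeat_region = flag("flag_repeat"))
}

#' Biased-SNP flag
#'
#' A SNP measurement is "biased" (monoallelic-like) when the higher/lower
#' read ratio reaches `bias_ratio` with at least `bias_min_high_reads`
#' reads on the higher allele. A zero lower allele gives an infinite ratio,
#' which is biased provided the higher allele is covered.
#'
#' @param ref_reads,alt_reads Integer vectors.
#' @param cfg A [qc_config()].
#' @return Logical vector.
#' @export
flag_biased_snp <- function(ref_reads, alt_reads, cfg = qc_config()) {
  hi <- pmax(ref_reads, alt_reads)
  lo <- pmin(ref_reads, alt_reads)
  ratio <- ifelse(lo == 0, Inf, hi / lo)
  hi >= cfg$bias_min_high_reads & ratio >= cfg$bias_ratio
}

#' Cohort-level common-biased-SNP filter
#'
#' A SNP site biased in more than `common_bias_subject_fraction` of
#' informative subjects of either cohort (with at least
#' `common_bias_min_subjects` biased subjects) reflects a technical
#' artefact or a common regulatory polymorphism, not a disease-causing
#' event, and is removed. Loss-of-function SNPs are exempt: recurrent bias
#' there can be nonsense-mediated decay. Informative subjects are those
#' whose measurement at the site passes the coverage filter; a subject
#' counts as biased if biased in any tissue.
#'
#' Known imprinted genes are exempt as well: their recurrent monoallelic
#' expression is the expected biology the imprinting assessment measures,
#' not an artefact.
#'
#' @param counts Data.frame of coverage-passing measurements with
#'   subject_id, site_id (or chrom+pos), ref_reads, alt_reads,
#'   effect_class.
#' @param subjects Data.frame with subject_id and cohort
#'   ("case"/"control").
#' @param cfg A [qc_config()].
#' @param exempt_genes Character vector of gene_ids never failed by this
#'   filter (known imprinted genes); needs a `gene_id` column in `counts`.
#' @return Data.frame per site: site_id, n_informative/biased per cohort,
#'   fail (logical).
#' @export
filter_common_biased_snps <- function(counts, subjects,
                                      cfg = qc_config(),
                                      exempt_genes = NULL) {
  if (!"site_id" %in% names(counts))
    counts$site_id <- paste(counts$chrom, counts$pos, sep = ":")
  counts$biased <- flag_biased_snp(counts$ref_reads, counts$alt_reads, cfg)
  counts$cohort <- subjects$cohort[match(counts$subject_id,
                                         subjects$subject_id)]
  per_subj <- stats::aggregate(biased ~ site_id + subject_id + cohort,
                               counts, any)
  agg <- stats::aggregate(cbind(informative = rep(1, nrow(per_subj)),
                                biased = per_subj$biased) ~
                            site_id + cohort, per_subj, sum)
  wide <- merge(
    stats::reshape(agg, idvar = "site_id", timevar = "cohort",
                   direction = "wide"),
    data.frame(site_id = unique(counts$site_id)), all.y = TRUE)
  for (cc in c("informative.case", "biased.case", "informative.control",
               "biased.control"))
    if (!cc %in% names(wide)) wide[[cc]] <- 0
  wide[is.na(wide)] <- 0
  over <- function(b, n) n > 0 & b / pmax(n, 1) >
    cfg$common_bias_subject_fraction & b >= cfg$common_bias_min_subjects
  wide$fail <- over(wide$biased.case, wide$informative.case) |
    over(wide$biased.control, wide$informative.control)
  lof_sites <- unique(counts$site_id[counts$effect_class %in%
                                       lof_effect_classes()])
  if (!is.null(exempt_genes) && "gene_id" %in% names(counts))
    lof_sites <- union(lof_sites,
                       unique(counts$site_id[counts$gene_id %in%
                                               exempt_genes]))
  wide$fail[wide$site_id %in% lof_sites] <- FALSE
  wide
}

#' Gene-structure filters for one sample
#'
#' Two misalignment signatures at the gene level, evaluated per sample:
#' `single_snp_monoallelic` (a gene whose only het SNP is highly covered,
#' >`single_snp_high_reads` reads, and 100% monoallelic — a suspicious
#' genotype) and `misaligned` (more than `unexpressed_fraction` of the
#' gene's other het SNPs have zero reads, or a coding het SNP has zero
#' reads).
#'
#' @param counts Data.frame of one sample's measurements with gene_id,
#'   ref_reads, alt_reads, effect_class.
#' @param cfg A [qc_config()].
#' @return Data.frame per gene: gene_id, single_snp_monoallelic,
#'   misaligned, fail.
#' @export
filter_gene_structure <- function(counts, cfg = qc_config()) {
  tot <- counts$ref_reads + counts$alt_reads
  mono <- pmin(counts$ref_reads, counts$alt_reads) == 0 & tot > 0
  coding_classes <- setdiff(coding_effect_classes(),
                            c("UTR_3_PRIME", "UTR_5_PRIME", "UTR"))
  per_gene <- function(i) {
    n <- length(i)
    single <- n == 1 && tot[i] > cfg$single_snp_high_reads && mono[i]
    z <- sum(tot[i] == 0)
    frac_other <- if (n > 1) z / (n - 1) else 0
    coding_zero <- any(tot[i] == 0 &
                         counts$effect_class[i] %in% coding_classes)
    mis <- (n > 1 && frac_other > cfg$unexpressed_fraction) || coding_zero
    c(single = single, misaligned = mis)
  }
  idx <- split(seq_len(nrow(counts)), counts$gene_id)
  res <- t(vapply(idx, per_gene, c(single = FALSE, misaligned = FALSE)))
  data.frame(gene_id = names(idx),
             single_snp_monoallelic = res[, "single"],
             misaligned = res[, "misaligned"],
             fail = res[, "single"] | res[, "misaligned"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-category filters
#'
#' Excludes genes that cannot carry an informative extreme-ASE call:
#' sex-chromosome genes (dosage compensation), the HLA locus, noncoding
#' genes, genes with low fetal-heart expression
#' (< `fetal_rpm_min` r.p.m.), and "common ASE" genes (ASE in more than
#' `common_ase_subject_fraction` of all subjects including at least one
#' control subject).
#'
#' @param genes Data.frame with gene_id, chrom, coding and optionally a
#'   gene symbol column `symbol` (checked against the HLA list along with
#'   gene_id).
#' @param fetal_reference Data.frame with gene_id, fetal_rpm.
#' @param ase_tally Optional data.frame with gene_id, n_ase_subjects,
#'   n_subjects_total, n_ase_controls (from a first calling pass).
#' @param cfg A [qc_config()].
#' @return Data.frame per gene with per-reason logical columns and `fail`.
#' @export
filter_gene_categories <- function(genes, fetal_reference,
                                   ase_tally = NULL, cfg = qc_config()) {
  chrom <- sub("^chr", "", genes$chrom)
  sex <- chrom %in% c("X", "Y")
  sym <- if ("symbol" %in% names(genes)) genes$symbol else genes$gene_id
  hla <- sym %in% hla_gene_list() | genes$gene_id %in% hla_gene_list()
  noncoding <- !genes$coding
  frpm <- fetal_reference$fetal_rpm[match(genes$gene_id,
                                          fetal_reference$gene_id)]
  low_fetal <- !is.na(frpm) & frpm < cfg$fetal_rpm_min
  common_ase <- rep(FALSE, nrow(genes))
  if (!is.null(ase_tally) && nrow(ase_tally)) {
    m <- match(genes$gene_id, ase_tally$gene_id)
    hit <- !is.na(m)
    common_ase[hit] <-
      ase_tally$n_ase_subjects[m[hit]] /
        ase_tally$n_subjects_total[m[hit]] >
        cfg$common_ase_subject_fraction &
      ase_tally$n_ase_controls[m[hit]] >= 1
  }
  data.frame(gene_id = genes$gene_id, sex_chromosome = sex, hla = hla,
             noncoding = noncoding, low_fetal_expression = low_fetal,
             common_ase = common_ase,
             fail = sex | hla | noncoding | low_fetal | common_ase,
             stringsAsFactors = FALSE)
}

#' Subject-level biallelic-expression QC
#'
#' In good RNA-seq data nearly all well-covered het SNPs outside loci with
#' expected ASE are expressed biallelically. Computes, per subject, the
#' fraction of qualifying SNP measurements (>= `subject_biallelic_min_reads`
#' reads; excluding chrX, known imprinted genes and alternatively spliced
#' exons) that are NOT biased, and excludes subjects below
#' `subject_biallelic_min`.
#'
#' @param counts Measurements with subject_id, gene_id, ref_reads,
#'   alt_reads and logical `flag_alt_spliced`.
#' @param genes Gene table with gene_id, chrom, imprinted_parent.
#' @param cfg A [qc_config()].
#' @return Data.frame per subject: subject_id, n_qualifying, fraction,
#'   keep.
#' @export
subject_biallelic_fraction <- function(counts, genes, cfg = qc_config()) {
  g <- match(counts$gene_id, genes$gene_id)
  excl <- sub("^chr", "", genes$chrom[g]) %in% c("X", "Y") |
    !is.na(genes$imprinted_parent[g])
  if ("flag_alt_spliced" %in% names(counts))
    excl <- excl | counts$flag_alt_spliced
  qual <- !excl &
    (counts$ref_reads + counts$alt_reads) >= cfg$subject_biallelic_min_reads
  cc <- counts[qual, , drop = FALSE]
  biased <- flag_biased_snp(cc$ref_reads, cc$alt_reads, cfg)
  n <- tapply(biased, cc$subject_id, length)
  b <- tapply(biased, cc$subject_id, sum)
  frac <- 1 - b / n
  data.frame(subject_id = names(n), n_qualifying = as.integer(n),
             fraction = as.numeric(frac),
             keep = as.numeric(frac) >= cfg$subject_biallelic_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Share of biased SNP measurements expressing the reference base
#'
#' Among measurements flagged biased (see [flag_biased_snp()]), the
#' fraction whose higher allele is the reference base. Without technical
#' reference bias this is ~0.5; values well above it indicate alignment
#' artefacts that QC should remove.
#'
#' @param counts Data.frame with ref_reads, alt_reads.
#' @param cfg A [qc_config()].
#' @return Numeric scalar in [0,1] (NaN when nothing is biased).
#' @export
ref_bias_share <- function(counts, cfg = qc_config()) {
  b <- flag_biased_snp(counts$ref_reads, counts$alt_reads, cfg)
  mean(counts$ref_reads[b] > counts$alt_reads[b])
}

#' Run the SNP-level QC cascade over a cohort
#'
#' Applies, in fixed order: genotype quality, coverage, positional
#' (clustered / near-indel / repeat), alternative splicing, complex
#' alleles, gene structure (single-SNP monoallelic, misaligned) and the
#' cohort common-biased-SNP filter. Filters never modify counts; each
#' measurement is annotated with every filter it failed.
#'
#' @param cohort A `synthetic_cohort`, or a list with `genotypes`,
#'   `allele_counts`, `subjects` and `genes` of the same shape.
#' @param cfg A [qc_config()].
#' @param indels Optional indel positions (subject_id, chrom, pos).
#' @return A list: `measurements` (all records with `failed_filters` and
#'   `pass`), `pass` (passing records only), `attrition` (records newly
#'   removed per filter, in order), `subject_qc` (from
#'   [subject_biallelic_fraction()], computed on records passing the
#'   per-SNP filters).
#' @export
run_snp_qc <- function(cohort, cfg = qc_config(), indels = NULL) {
  gt <- cohort$genotypes
  ac <- merge(cohort$allele_counts,
              gt[c("subject_id", "site_id", "gene_id", "gq", "dna_ab",
                   "effect_class", "parent_of_alt", "flag_clustered",
                   "flag_near_indel", "flag_repeat", "flag_alt_spliced",
                   "flag_complex")],
              by = c("subject_id", "site_id"), sort = FALSE)
  ac <- ac[order(ac$subject_id, ac$tissue, ac$pos), ]
  rownames(ac) <- NULL

  fails <- list()
  fails$genotype_quality <-
    suppressMessages(filter_genotype_quality(ac, cfg))
  fails$low_coverage <- filter_min_coverage(ac$ref_reads, ac$alt_reads, cfg)
  pos_f <- filter_positional(
    gt, indels, cfg)[match(paste(ac$subject_id, ac$site_id),
                           paste(gt$subject_id, gt$site_id)), ]
  fails$clustered <- pos_f$clustered
  fails$near_indel <- pos_f$near_indel
  fails$repeat_region <- pos_f$repeat_region
  fails$alt_spliced <- ac$flag_alt_spliced
  fails$complex_allele <- ac$flag_complex

  surv <- !Reduce(`|`, fails)
  gs_fail <- rep(FALSE, nrow(ac))
  for (samp in unique(paste(ac$subject_id, ac$tissue))) {
    i <- which(paste(ac$subject_id, ac$tissue) == samp & surv)
    if (!length(i)) next
    gs <- filter_gene_structure(ac[i, ], cfg)
    bad_genes <- gs$gene_id[gs$fail]
    gs_fail[i[ac$gene_id[i] %in% bad_genes]] <- TRUE
  }
  fails$gene_structure <- gs_fail

  surv <- surv & !gs_fail
  imprinted <- cohort$genes$gene_id[!is.na(cohort$genes$imprinted_parent)]
  cb <- filter_common_biased_snps(ac[surv, , drop = FALSE],
                                  cohort$subjects, cfg,
                                  exempt_genes = imprinted)
  fails$common_biased <- surv &
    ac$site_id %in% cb$site_id[cb$fail]

  fmat <- do.call(cbind, fails)
  ac$failed_filters <- apply(fmat, 1, function(r)
    paste(names(fails)[r], collapse = ";"))
  ac$pass <- !apply(fmat, 1, any)

  remaining <- rep(TRUE, nrow(ac))
  attr_rows <- lapply(names(fails), function(f) {
    removed <- sum(remaining & fails[[f]])
    remaining <<- remaining & !fails[[f]]
    data.frame(filter = f, removed = removed,
               remaining = sum(remaining), stringsAsFactors = FALSE)
  })
  attrition <- do.call(rbind, attr_rows)

  subject_qc <- subject_biallelic_fraction(
    ac[ac$pass | fails$common_biased, , drop = FALSE],
    cohort$genes, cfg)

  list(measurements = ac, pass = ac[ac$pass, , drop = FALSE],
       attrition = attrition, subject_qc = subject_qc)
}
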