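test_that("genotype-quality bounds are inclusive", {
  snps <- data.frame(gq = c(50, 49, 99, 99),
                     dna_ab = c(0.2, 0.5, 0.81, 0.8))
  expect_equal(filter_genotype_quality(snps),
               c(FALSE, TRUE, TRUE, FALSE))
  na_snps <- data.frame(gq = NA_real_, dna_ab = NA_real_)
  expect_message(res <- filter_genotype_quality(na_snps), "skipped")
  expect_false(res)
})

test_that("coverage filter admits five reads or both alleles expressed", {
  expect_equal(filter_min_coverage(c(5, 2, 3), c(0, 1, 0)),
               c(FALSE, FALSE, TRUE))
})

test_that("clustered, near-indel and repeat SNPs fail positionally", {
  snps <- data.frame(subject_id = "S1", chrom = "1",
                     pos = c(100, 110, 120, 1000))
  out <- filter_positional(snps)
  expect_equal(out$clustered, c(TRUE, TRUE, TRUE, FALSE))

  lone <- data.frame(subject_id = "S1", chrom = "1", pos = 500)
  ind31 <- data.frame(subject_id = "S1", chrom = "1", pos = 531)
  ind30 <- data.frame(subject_id = "S1", chrom = "1", pos = 530)
  expect_false(filter_positional(lone, indels = ind31)$near_indel)
  expect_true(filter_positional(lone, indels = ind30)$near_indel)

  flagged <- data.frame(subject_id = "S1", chrom = "1", pos = 500,
                        flag_repeat = TRUE)
  expect_true(filter_positional(flagged)$repeat_region)
})

test_that("the biased-SNP flag uses ratio 7.2 with five higher-allele reads", {
  expect_true(flag_biased_snp(36, 5))
  expect_false(flag_biased_snp(20, 20))
  expect_false(flag_biased_snp(4, 0))
  expect_true(flag_biased_snp(0, 12))  # allele-symmetric
})

test_that("common-biased SNPs fail per cohort, with the LOF exemption", {
  mk <- function(n_subj, n_biased, effect = "SYNONYMOUS_CODING") {
    data.frame(subject_id = sprintf("S%02d", seq_len(n_subj)),
               tissue = "T1", site_id = "s1",
               ref_reads = c(rep(50, n_biased), rep(20, n_subj - n_biased)),
               alt_reads = c(rep(0, n_biased), rep(20, n_subj - n_biased)),
               effect_class = effect, gene_id = "G1",
               stringsAsFactors = FALSE)
  }
  subjects <- data.frame(subject_id = sprintf("S%02d", 1:6),
                         cohort = "case")
  expect_true(filter_common_biased_snps(mk(6, 3), subjects)$fail)
  expect_false(filter_common_biased_snps(mk(4, 2), subjects)$fail)
  expect_false(
    filter_common_biased_snps(mk(6, 5, effect = "STOP_GAINED"),
                              subjects)$fail)
  expect_false(
    filter_common_biased_snps(mk(6, 5), subjects,
                              exempt_genes = "G1")$fail)
})

test_that("gene-structure filters catch suspect genotypes and misalignment", {
  one <- data.frame(gene_id = "G1", ref_reads = 25, alt_reads = 0,
                    effect_class = "SYNONYMOUS_CODING")
  expect_true(filter_gene_structure(one)$fail)
  low <- data.frame(gene_id = "G1", ref_reads = 10, alt_reads = 0,
                    effect_class = "SYNONYMOUS_CODING")
  expect_false(filter_gene_structure(low)$fail)  # <= 20 reads

  five <- data.frame(gene_id = "G2",
                     ref_reads = c(10, 12, 8, 0, 0),
                     alt_reads = c(9, 10, 11, 0, 0),
                     effect_class = "UTR_3_PRIME")
  expect_true(filter_gene_structure(five)$misaligned)

  ok <- data.frame(gene_id = "G3", ref_reads = c(10, 12),
                   alt_reads = c(9, 10), effect_class = "UTR_3_PRIME")
  expect_false(filter_gene_structure(ok)$fail)

  coding_zero <- data.frame(gene_id = "G4", ref_reads = c(10, 0),
                            alt_reads = c(9, 0),
                            effect_class = c("UTR_3_PRIME",
                                             "SYNONYMOUS_CODING"))
  expect_true(filter_gene_structure(coding_zero)$misaligned)
})

test_that("gene-category exclusions follow the quoted rules", {
  genes <- data.frame(gene_id = c("G1", "G2", "HLA-A", "G4", "G5", "G6"),
                      chrom = c("X", "1", "6", "1", "1", "1"),
                      coding = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                      stringsAsFactors = FALSE)
  fetal <- data.frame(gene_id = genes$gene_id,
                      fetal_rpm = c(10, 2.0, 10, 10, 1.9, 10))
  tally <- data.frame(gene_id = "G6", n_ase_subjects = 6,
                      n_subjects_total = 100, n_ase_controls = 0)
  out <- filter_gene_categories(genes, fetal, tally)
  expect_true(out$fail[out$gene_id == "G1"])    # chrX
  expect_false(out$fail[out$gene_id == "G2"])   # fetal 2.0 inclusive pass
  expect_true(out$fail[out$gene_id == "HLA-A"])
  expect_true(out$fail[out$gene_id == "G4"])    # noncoding
  expect_true(out$fail[out$gene_id == "G5"])    # fetal < 2
  expect_false(out$fail[out$gene_id == "G6"])   # 6% ASE but no control

  tally2 <- tally; tally2$n_ase_controls <- 1
  out2 <- filter_gene_categories(genes, fetal, tally2)
  expect_true(out2$fail[out2$gene_id == "G6"])
})

test_that("subjects with low biallelic fractions are excluded", {
  genes <- data.frame(gene_id = sprintf("G%d", 1:10), chrom = "1",
                      imprinted_parent = NA_character_,
                      stringsAsFactors = FALSE)
  counts <- data.frame(subject_id = "S1", gene_id = genes$gene_id,
                       ref_reads = c(rep(20, 7), rep(40, 3)),
                       alt_reads = c(rep(20, 7), rep(0, 3)),
                       flag_alt_spliced = FALSE, stringsAsFactors = FALSE)
  out <- subject_biallelic_fraction(counts, genes)
  expect_equal(out$fraction, 0.7)
  expect_false(out$keep)

  balanced <- counts
  balanced$alt_reads <- 20; balanced$ref_reads <- 20
  expect_true(subject_biallelic_fraction(balanced, genes)$keep)
})

test_that("a null synthetic subject has near-complete biallelic expression", {
  co <- generate_cohort(small_null_config(21))
  qc <- run_snp_qc(co)
  expect_true(all(qc$subject_qc$fraction >= 0.95))
})

test_that("the QC cascade annotates failures without modifying counts", {
  co <- generate_cohort(small_null_config(6, mapping_bias_fraction = 0.05))
  qc <- run_snp_qc(co)
  m <- qc$measurements
  orig <- co$allele_counts
  key <- paste(orig$subject_id, orig$tissue, orig$site_id)
  mkey <- paste(m$subject_id, m$tissue, m$site_id)
  expect_setequal(mkey, key)
  expect_equal(m$ref_reads[match(key, mkey)], orig$ref_reads)
  expect_equal(m$alt_reads[match(key, mkey)], orig$alt_reads)
  expect_true(all(m$pass == (m$failed_filters == "")))
  expect_equal(sum(qc$attrition$removed),
               nrow(m) - qc$attrition$remaining[nrow(qc$attrition)])
})
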