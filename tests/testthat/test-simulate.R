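test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(null_allele_fraction = 1.2),
               "null_allele_fraction")
  expect_error(simulation_config(trio_fraction = -0.1), "trio_fraction")
  expect_error(
    simulation_config(n_genes = 10,
                      ase_events = data.frame(gene = 11, subject = 1,
                                              allele_fraction = 0.9)),
    "ase_events\\$gene")
  expect_error(
    simulation_config(
      ase_events = data.frame(gene = 1, subject = 1,
                              allele_fraction = 0.9),
      loe_events = data.frame(gene = 1, subject = 1, fold = 0.1)),
    "both ASE and LOE")
})

test_that("null cohorts are allele-symmetric at high depth", {
  co <- generate_cohort(simulation_config(
    n_subjects = 4, n_controls = 0, n_genes = 100, tissues_per_subject = 1,
    read_depth_mean = 1000, trio_fraction = 0, seed = 42))
  ac <- co$allele_counts
  frac <- ac$ref_reads / (ac$ref_reads + ac$alt_reads)
  expect_gte(mean(abs(frac - 0.5) <= 0.05), 0.99)
})

test_that("an injected ASE event yields the binomially expected pooled ratio", {
  # oracle: at allele fraction 0.9 the pooled higher/lower ratio
  # concentrates near 0.9/0.1 = 9; (7, 12) covers binomial noise at n ~ 500+
  co <- generate_cohort(simulation_config(
    n_subjects = 4, n_controls = 0, n_genes = 20, tissues_per_subject = 1,
    read_depth_mean = 500, trio_fraction = 0, seed = 5,
    ase_events = data.frame(gene = 1, subject = 1, allele_fraction = 0.9,
                            expr_fold = NA)))
  ac <- co$allele_counts[co$allele_counts$subject_id == "S001", ]
  gt <- co$genotypes
  g1 <- gt$site_id[gt$gene_id == "G0001" & gt$subject_id == "S001"]
  ev <- ac[ac$site_id %in% g1, ]
  hi <- sum(pmax(ev$ref_reads, ev$alt_reads))
  lo <- sum(pmin(ev$ref_reads, ev$alt_reads))
  expect_gt(hi / lo, 7)
  expect_lt(hi / lo, 12)
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- small_null_config(9, ase_events = strong_ase_events(3, 8),
                           mapping_bias_fraction = 0.05)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("mapping-bias injection forces monoallelic reference expression", {
  co <- generate_cohort(small_null_config(3))
  expect_identical(inject_mapping_bias(co, 0), co)
  cob <- inject_mapping_bias(co, 0.1, bias_toward_ref = 1)
  bad_sites <- cob$truth$site_id[cob$truth$type == "mapping_bias"]
  expect_gt(length(bad_sites), 0)
  cc <- cob$allele_counts[cob$allele_counts$site_id %in% bad_sites, ]
  expect_true(all(cc$alt_reads == 0))
  expect_true(all(cc$ref_reads[cc$ref_reads + cc$alt_reads > 0] > 0))
})

test_that("overdispersed sampling still produces valid counts", {
  co <- generate_cohort(small_null_config(4, overdispersion = 0.1))
  ac <- co$allele_counts
  expect_true(all(ac$ref_reads >= 0 & ac$alt_reads >= 0))
})

test_that("stride subsampling keeps every n-th SNP per subject", {
  gt <- data.frame(subject_id = "S001", chrom = "1",
                   pos = sort(sample.int(1e6, 36)))
  expect_identical(subsample_snps(gt, 1), gt)
  expect_equal(nrow(subsample_snps(gt, 18)), 2)
  big <- data.frame(subject_id = "S001", chrom = "1", pos = seq_len(18500))
  expect_equal(nrow(subsample_snps(big, 18)), 1028)
  expect_error(subsample_snps(gt, 0), "stride")
})
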