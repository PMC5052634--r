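test_that("SNP reads are binned by inheritance and expression", {
  m <- make_measurements("G1", "S1", "T1",
                         ref = c(10, 30, 10), alt = c(30, 10, 10),
                         parent_of_alt = c("maternal", "unknown",
                                           "unknown"))
  out <- assign_snp_reads(m)
  expect_equal(out$mat, c(30, 0, 0))
  expect_equal(out$pat, c(10, 0, 0))
  expect_equal(out$higher, c(0, 30, 0))  # tie SNP contributes nothing
  expect_equal(out$lower, c(0, 10, 0))
})

test_that("the compound allele bias folds unphased sums onto the dominant parent", {
  expect_equal(compound_allele_bias(36, 5, 10, 2)$bias, 46 / 7)
  expect_equal(compound_allele_bias(5, 36, 10, 2)$bias, 46 / 7)
  expect_equal(compound_allele_bias(0, 0, 36, 5)$bias, 7.2)
  expect_equal(compound_allele_bias(50, 0, 0, 0)$bias, Inf)
  expect_equal(compound_allele_bias(3, 3, 36, 5)$bias, 36 / 5)  # tie rule
  expect_true(is.na(compound_allele_bias(0, 0, 0, 0)$bias))
})

test_that("binomial P values match brute-force enumeration", {
  # frozen values from the enumeration oracle
  expect_equal(binomial_ase_pvalue(36, 5, 1)$binomial_p,
               7.841572e-07, tolerance = 1e-6)
  expect_equal(binomial_ase_pvalue(5, 5, 1)$binomial_p, 1)
  pv <- binomial_ase_pvalue(10, 0, 100)
  expect_equal(pv$binomial_p, 2 / 2^10)
  expect_equal(pv$corrected_p, 100 * 2 / 2^10)

  set.seed(1)
  for (n in c(1, 2, 7, 33, 100, 200)) {
    for (H in unique(c(ceiling(n / 2), n, sample(ceiling(n / 2):n, 3,
                                                 replace = TRUE)))) {
      expect_equal(binomial_ase_pvalue(H, n - H, 1)$binomial_p,
                   binom_two_sided_oracle(H, n - H), tolerance = 1e-12)
    }
  }
})

test_that("binomial P is monotone in H and bias is monotone in H", {
  n <- 40
  H <- 20:40
  p <- binomial_ase_pvalue(H, n - H, 1)$binomial_p
  expect_true(all(diff(p) <= 1e-15))
  b <- compound_allele_bias(0, 0, H, n - H)$bias
  expect_true(all(diff(b) >= 0))
})

test_that("relabelling which base is reference leaves the statistic unchanged", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    m <- make_measurements(
      "G1", "S1", "T1",
      ref = rpois(n, 30), alt = rpois(n, 30),
      parent_of_alt = sample(c("maternal", "paternal", "unknown"), n,
                             replace = TRUE))
    flip <- runif(n) < 0.5
    m2 <- m
    m2$ref_reads[flip] <- m$alt_reads[flip]
    m2$alt_reads[flip] <- m$ref_reads[flip]
    swap <- c(maternal = "paternal", paternal = "maternal",
              unknown = "unknown")
    m2$parent_of_alt[flip] <- swap[m$parent_of_alt[flip]]
    s1 <- gene_allele_summaries(m)
    s2 <- gene_allele_summaries(m2)
    expect_equal(s1$allele_bias, s2$allele_bias)
    expect_equal(s1$binomial_p, s2$binomial_p)
  }
})

test_that("extreme-ASE calls require the joint bias, P and depth rule", {
  summ <- data.frame(gene_id = c("G1", "G2", "G3", "G4"),
                     subject_id = "S1", tissue = "T1",
                     allele_bias = c(7.2, 7.1, 20, Inf),
                     corrected_p = c(0.009, 1e-6, 0.02, 1e-6),
                     H = c(36, 40, 40, 4), stringsAsFactors = FALSE)
  out <- call_extreme_ase(summ)
  expect_equal(out$is_extreme_ase, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("known imprinted genes are excluded from the candidate call set", {
  summ <- data.frame(gene_id = c("G1", "G2"), subject_id = "S1",
                     tissue = "T1", allele_bias = c(50, 50),
                     corrected_p = c(1e-6, 1e-6), H = c(40, 40),
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("G1", "G2"),
                      imprinted_parent = c(NA, "paternal"),
                      stringsAsFactors = FALSE)
  out <- call_extreme_ase(summ, genes)
  expect_equal(out$is_extreme_ase, c(TRUE, TRUE))
  expect_equal(out$candidate_call, c(TRUE, FALSE))
})

test_that("the Bonferroni divisor counts covered genes per sample", {
  m <- data.frame(subject_id = c("S1", "S1", "S1", "S2"),
                  tissue = c("T1", "T1", "T2", "T1"),
                  gene_id = c("G1", "G2", "G1", "G3"),
                  failed_filters = c("", "low_coverage", "", ""),
                  stringsAsFactors = FALSE)
  mt <- bonferroni_m(m)
  expect_equal(mt$m[mt$subject_id == "S1" & mt$tissue == "T1"], 1)
  expect_equal(mt$m[mt$subject_id == "S1" & mt$tissue == "T2"], 1)
  expect_equal(mt$m[mt$subject_id == "S2"], 1)
})

test_that("phased and unphased calls agree on strong events and on nulls", {
  co <- generate_cohort(simulation_config(
    n_subjects = 8, n_controls = 0, n_genes = 60, read_depth_mean = 60,
    trio_fraction = 1, seed = 31,
    ase_events = strong_ase_events(10, 8, allele_fraction = 0.93)))
  qc <- run_snp_qc(co)
  conc <- phased_unphased_concordance(qc$pass)
  expect_gt(length(conc$phased), 0)
  expect_length(conc$symmetric_difference, 0)

  co0 <- generate_cohort(simulation_config(
    n_subjects = 4, n_controls = 0, n_genes = 40, trio_fraction = 1,
    seed = 32))
  conc0 <- phased_unphased_concordance(run_snp_qc(co0)$pass)
  expect_length(conc0$phased, 0)
  expect_length(conc0$unphased, 0)
})

test_that("the phasing grid includes the operating point and tightens with thresholds", {
  co <- generate_cohort(simulation_config(
    n_subjects = 8, n_controls = 0, n_genes = 50, read_depth_mean = 60,
    trio_fraction = 1, seed = 33,
    ase_events = strong_ase_events(12, 8, allele_fraction = 0.95)))
  qc <- run_snp_qc(co)
  grid <- evaluate_phasing_grid(co, counts = qc$pass,
                                bias_grid = c(4, 7.2), depth_grid = c(4, 5))
  expect_true(any(grid$bias == 7.2 & grid$depth == 5))
  op <- grid$fp_rate[grid$bias == 7.2 & grid$depth == 5]
  lax <- grid$fp_rate[grid$bias == 4 & grid$depth == 4]
  expect_lte(op, lax)
})
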