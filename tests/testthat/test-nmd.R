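lof_row <- function(ref, alt, subject = "S1", site = "v1", gene = "G1") {
  data.frame(subject_id = subject, tissue = "T1", gene_id = gene,
             site_id = site, ref_reads = ref, alt_reads = alt,
             effect_class = "STOP_GAINED", lof_allele = "alt",
             stringsAsFactors = FALSE)
}

test_that("NMD requires a >4 normal/LOF ratio in the right direction", {
  # 25 normal / 5 LOF: enumeration oracle gives the frozen P
  out <- call_nmd(lof_row(25, 5))
  expect_equal(out$nmd_bias, 5)
  expect_equal(out$p_value, binom_two_sided_oracle(25, 5),
               tolerance = 1e-12)
  expect_equal(out$p_value, 3.249142e-4, tolerance = 1e-4)
  expect_true(out$is_nmd)

  boundary <- call_nmd(lof_row(12, 3))
  expect_equal(boundary$nmd_bias, 4)
  expect_false(boundary$is_nmd)  # strict > 4

  wrong_dir <- call_nmd(lof_row(5, 25))
  expect_false(wrong_dir$is_nmd)
  expect_lt(wrong_dir$nmd_bias, 1)
})

test_that("the correction divisor is the per-subject LOF variant count", {
  two <- rbind(lof_row(25, 5, site = "v1", gene = "G1"),
               lof_row(30, 4, site = "v2", gene = "G2"))
  out <- call_nmd(two)
  expect_equal(out$k, c(2L, 2L))
  expect_equal(out$corrected_p, pmin(1, 2 * out$p_value))
})

test_that("unidentifiable LOF alleles are skipped with a warning", {
  x <- lof_row(25, 5)
  x$lof_allele <- NA_character_
  expect_warning(out <- call_nmd(x), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("the NMD fraction counts evaluable gene-subject pairs", {
  calls <- data.frame(gene_id = sprintf("G%02d", 1:78),
                      subject_id = "S1",
                      is_nmd = c(rep(TRUE, 14), rep(FALSE, 64)))
  nf <- nmd_fraction(calls)
  expect_equal(nf$n_nmd, 14)
  expect_equal(nf$n_evaluable, 78)
  expect_equal(round(nf$fraction, 2), 0.18)
  expect_equal(nmd_fraction(data.frame(gene_id = "G1", subject_id = "S1",
                                       is_nmd = FALSE))$fraction, 0)
  expect_error(nmd_fraction(calls[0, ]), "no evaluable")
})

test_that("injected NMD events are recovered at roughly their true rate", {
  # 6 decaying + 14 balanced LOF variants: true NMD fraction 0.3
  n_lof <- 20
  nmd_ev <- data.frame(gene = seq_len(n_lof),
                       subject = rep_len(1:10, n_lof),
                       lof_allele_fraction = c(rep(0.15, 6), rep(0.5, 14)))
  co <- generate_cohort(simulation_config(
    n_subjects = 10, n_controls = 0, n_genes = 40, read_depth_mean = 100,
    seed = 51, nmd_events = nmd_ev))
  res <- run_pipeline(co)
  ev_key <- paste(sprintf("G%04d", nmd_ev$gene),
                  sprintf("S%03d", nmd_ev$subject))
  calls <- res$nmd[paste(res$nmd$gene_id, res$nmd$subject_id) %in% ev_key, ]
  nf <- nmd_fraction(calls)
  expect_equal(nf$fraction, 0.3, tolerance = 0.34)  # within +/- 0.1

  # consistency: every NMD call also satisfies the relaxed ASE rule
  hit <- res$nmd[res$nmd$is_nmd, ]
  expect_true(all(hit$nmd_bias > 4))
})
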