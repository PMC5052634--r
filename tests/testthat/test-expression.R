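make_expr <- function(mat, tissues) {
  samples <- data.frame(sample_id = colnames(mat),
                        subject_id = colnames(mat), tissue = tissues,
                        total_reads = 1e6, stringsAsFactors = FALSE)
  compute_rpm(mat, setNames(rep(1e6, ncol(mat)), colnames(mat)),
              sample_info = samples)
}

test_that("leave-one-out statistics follow their definitions", {
  set.seed(1)
  vals <- c(100, 90, 110, 95, 105, 100)
  mat <- matrix(vals, 1, dimnames = list("G1", sprintf("s%d", 1:6)))
  expr <- make_expr(mat, rep("T1", 6))
  cmp <- loo_compare(expr)
  r1 <- cmp[cmp$sample_id == "s1", ]
  expect_equal(r1$loo_mean, mean(vals[-1]))
  expect_equal(r1$loo_sd, sd(vals[-1]))
  expect_equal(r1$fold, vals[1] / mean(vals[-1]))
  expect_equal(r1$z, (vals[1] - mean(vals[-1])) / sd(vals[-1]))
  expect_equal(r1$p, 2 * pnorm(-abs(r1$z)))
})

test_that("samples equal to the group mean have fold 1, z 0, p 1", {
  out <- expression_comparison(100, 100, 10, 10)
  expect_equal(out$fold, 1)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
})

test_that("adding a sample at the mean leaves the mean fixed and cannot raise the sd", {
  set.seed(4)
  for (i in 1:10) {
    x <- rlnorm(sample(5:12, 1), 3, 0.5)
    x2 <- c(x, mean(x))
    expect_equal(mean(x2), mean(x))
    expect_lte(sd(x2), sd(x))
  }
})

test_that("small tissue groups and degenerate groups are skipped", {
  mat <- matrix(rlnorm(40, 3, 0.2), 8, 5,
                dimnames = list(sprintf("G%d", 1:8), sprintf("s%d", 1:5)))
  expr <- make_expr(mat, rep("T1", 5))  # 4 others: not > 4
  expect_null(loo_compare(expr))

  mat2 <- matrix(10, 2, 6,
                 dimnames = list(c("G1", "G2"), sprintf("s%d", 1:6)))
  mat2[2, ] <- 0
  expr2 <- make_expr(mat2, rep("T1", 6))
  cmp2 <- loo_compare(expr2)
  expect_true(all(is.na(cmp2$z[cmp2$gene_id == "G1"])))    # sd 0
  expect_true(all(is.na(cmp2$fold[cmp2$gene_id == "G2"]))) # mean 0
})

test_that("sample QC excludes samples with more than 100 extreme differences", {
  mk <- function(n_sig) {
    data.frame(sample_id = "s1", gene_id = sprintf("G%d", 1:150),
               fold = c(rep(0.1, n_sig), rep(1, 150 - n_sig)),
               p = c(rep(0.001, n_sig), rep(0.8, 150 - n_sig)))
  }
  expect_false(sample_expression_qc(mk(101))$keep)
  expect_true(sample_expression_qc(mk(100))$keep)
})

test_that("extreme-ASE events are classified by the derived fold thresholds", {
  ev <- data.frame(gene_id = c("RBFOX2", "FGFBP2", "GX"),
                   subject_id = "S1", tissue = "T1",
                   is_extreme_ase = TRUE, stringsAsFactors = FALSE)
  cmp <- data.frame(gene_id = ev$gene_id, sample_id = "S1_T1",
                    subject_id = "S1", tissue = "T1",
                    fold = c(0.64, 5.48, 1.0),
                    z = c(-2.4, 2.7, 0),
                    p = c(0.016, 6.7e-3, 1), stringsAsFactors = FALSE)
  out <- integrate_ase_expression(ev, cmp)
  expect_equal(out$expression_class,
               c("downregulated", "upregulated", "unchanged"))
})

test_that("LOE calls require candidacy plus the joint fold and P rule", {
  cmp <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4"),
    sample_id = "s1", subject_id = "s1", tissue = "T1",
    rpm = c(1, 1, 1, 50),
    loo_mean = c(50, 50, 50, 50), loo_sd = c(5, 5, 40, 5),
    n_others = 10,
    fold = c(0.02, 0.09, 0.02, 1),
    z = c(-9.8, -8.2, -1.2, 0),
    stringsAsFactors = FALSE)
  cmp$p <- 2 * pnorm(-abs(cmp$z))
  cmp$p[2] <- 0.01  # fold passes but P fails
  ec <- expression_call_config(loe_upper_quartile = FALSE)
  out <- call_loe(cmp, ec)
  expect_true(out$is_loe[out$gene_id == "G1"])
  expect_false(out$is_loe[out$gene_id == "G2"])  # p 0.01 > 2.7e-3
  expect_false(out$is_loe[out$gene_id == "G3"])  # CV 0.8 not tight
  expect_false(out$is_loe[out$gene_id == "G4"])

  out2 <- call_loe(cmp, ec, polyA_genes = "G4")
  expect_false(any(out2$is_loe))
})

test_that("the burden test wraps the Fisher exact test on cohort totals", {
  b <- burden_fisher(9, 37, 0, 57)
  expect_equal(b$p_value, 1.17e-4, tolerance = 0.01)
  expect_equal(burden_fisher(5, 10, 5, 10)$p_value, 1)
  expect_error(burden_fisher(11, 10, 0, 5), "case_hits")
})

test_that("call thresholds derive from first principles", {
  expect_equal(ase_down_fold(), 0.5 + 0.5 * 0.3)
  expect_equal(ase_down_fold(), 0.65)
  expect_equal(ase_up_fold(), 5)
  expect_equal(loe_p_threshold(), 2 * pnorm(-3))
  expect_equal(loe_p_threshold(), 2.6998e-3, tolerance = 1e-4)
})

test_that("injected knockdowns are detected and null samples stay clean", {
  co <- generate_cohort(simulation_config(
    n_subjects = 10, n_controls = 4, n_genes = 80, seed = 61,
    loe_events = data.frame(gene = 1:8, subject = 1:8, fold = 0.08)))
  res <- run_pipeline(co)
  loe_hits <- res$loe[res$loe$is_loe, ]
  ev_key <- paste(sprintf("G%04d", 1:8), sprintf("S%03d", 1:8))
  recovered <- ev_key %in% paste(loe_hits$gene_id, loe_hits$subject_id)
  expect_gte(mean(recovered), 0.9)
  # no LOE calls outside the injected events
  expect_true(all(paste(loe_hits$gene_id, loe_hits$subject_id) %in% ev_key))
})
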