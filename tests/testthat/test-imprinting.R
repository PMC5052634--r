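test_that("the Fisher exact test matches the reference implementation on random tables", {
  set.seed(2)
  for (i in 1:60) {
    tab <- matrix(sample(0:20, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    mine <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_equal(fisher_exact_2x2(2, 4, 3, 5)$odds_ratio, (2 * 5) / (4 * 3))
  expect_equal(fisher_exact_2x2(2, 0, 3, 5)$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("percent ASE pools cohorts and rounds to integer percent", {
  expect_equal(pct_ase(4, 7, 15, 15), 86L)
  expect_equal(pct_ase(16, 16, 33, 34), 98L)
  expect_true(is.na(pct_ase(0, 0, 0, 0)))
})

test_that("imprinted-gene summaries count cohorts and vote the expressed parent", {
  verd <- data.frame(
    subject_id = sprintf("S%02d", 1:22),
    cohort = c(rep("case", 7), rep("control", 15)),
    ase = c(rep(TRUE, 4), rep(FALSE, 3), rep(TRUE, 15)),
    expressed_parent = c("paternal", "paternal", NA, NA, NA, NA, NA,
                         rep(NA, 15)),
    stringsAsFactors = FALSE)
  s <- summarize_imprinted_gene("GZ", verd)
  expect_equal(s$case_ase, 4); expect_equal(s$case_informative, 7)
  expect_equal(s$control_ase, 15)
  expect_equal(s$pct_ase, 86L)
  expect_equal(s$expressed_parent, "paternal")
  expect_true(s$imprinted_in_heart)

  none <- verd[0, ]
  s0 <- summarize_imprinted_gene("GZ", none)
  expect_equal(s0$expressed_parent, "indeterminate")
  expect_false(s0$imprinted_in_heart)
  expect_true(is.na(s0$pct_ase))

  conflict <- verd[1:2, ]
  conflict$expressed_parent <- c("maternal", "paternal")
  expect_warning(sc <- summarize_imprinted_gene("GZ", conflict),
                 "conflicting")
  expect_equal(sc$expressed_parent, "indeterminate")
})

test_that("per-cohort membership is stricter than the combined rule", {
  verd <- data.frame(subject_id = sprintf("S%02d", 1:12),
                     cohort = c(rep("case", 4), rep("control", 8)),
                     ase = c(rep(FALSE, 4), rep(TRUE, 8)),
                     expressed_parent = NA_character_,
                     stringsAsFactors = FALSE)
  expect_true(summarize_imprinted_gene("G", verd)$imprinted_in_heart)
  expect_false(summarize_imprinted_gene("G", verd,
                                        per_cohort = TRUE)$imprinted_in_heart)
})

test_that("parental-bias tests recover the expected association direction", {
  summaries <- data.frame(
    gene_id = sprintf("G%02d", 1:46),
    known_parent = c(rep("maternal", 21), rep("paternal", 25)),
    imprinted_in_heart = c(rep(TRUE, 1), rep(FALSE, 20),
                           rep(TRUE, 14), rep(FALSE, 11)),
    stringsAsFactors = FALSE)
  out <- parental_bias_tests(summaries)
  expect_equal(unname(out$maternal_vs_paternal$counts),
               c(1, 20, 14, 11))
  expect_equal(out$maternal_vs_paternal$p_value, 3.1e-4,
               tolerance = 0.02)

  flat <- summaries; flat$imprinted_in_heart <- FALSE
  expect_equal(parental_bias_tests(flat)$maternal_vs_paternal$p_value, 1)
})

test_that("injected paternal-only imprinting is detected as parental bias", {
  n_pat <- 12
  co <- generate_cohort(simulation_config(
    n_subjects = 12, n_controls = 6, n_genes = 60, read_depth_mean = 50,
    trio_fraction = 0.5, seed = 41,
    imprinting_events = data.frame(gene = seq_len(n_pat),
                                   expressed_parent = "paternal",
                                   penetrance = 0.9)))
  # extend the catalog with biallelically expressed maternal genes
  co$genes$imprinted_parent[13:24] <- "maternal"
  res <- run_pipeline(co)
  expect_gte(sum(res$imprinting$imprinted_in_heart &
                   res$imprinting$known_parent == "paternal"), 10)
  bias <- parental_bias_tests(res$imprinting)
  expect_lt(bias$maternal_vs_paternal$p_value, 0.05)
})
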