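#!/usr/bin/env Rscript

# Imprinting and NMD: assess the known-imprinted catalog genes for ASE,
# test parental-origin bias, and test whether loss-of-function alleles
# are under-expressed (nonsense-mediated decay).

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_cohort.R"))
dir.create("results", showWarnings = FALSE)

cohort <- study_cohort()
res <- run_pipeline(cohort)
seed_hdr <- paste0("seed=", cohort$config$seed)

cat("Imprinted-gene assessment (catalog genes with informative subjects):\n")
print(res$imprinting)
write_tsv_commented(res$imprinting, "results/imprinting.tsv", seed_hdr)

if (nrow(res$imprinting) > 1 &&
    length(unique(res$imprinting$known_parent)) > 1) {
  bias <- parental_bias_tests(res$imprinting)
  cat(sprintf("\nMaternal vs paternal ASE bias: P = %.3g (table: %s)\n",
              bias$maternal_vs_paternal$p_value,
              paste(bias$maternal_vs_paternal$counts, collapse = "/")))
}

nmd <- res$nmd
write_tsv_commented(nmd, "results/nmd_calls.tsv", seed_hdr)
truth <- cohort$truth[cohort$truth$type == "nmd", ]
decaying <- truth[truth$param <= 0.2, ]
if (nrow(nmd)) {
  nf <- nmd_fraction(nmd)
  cat(sprintf("\nNMD: %d/%d evaluable LOF gene-subject pairs called (fraction %.2f)\n",
              nf$n_nmd, nf$n_evaluable, nf$fraction))
  hit <- unique(paste(nmd$gene_id, nmd$subject_id)[nmd$is_nmd])
  cat(sprintf("Injected decaying variants recovered: %d/%d\n",
              sum(paste(decaying$gene_id, decaying$subject_id) %in% hit),
              nrow(decaying)))
}
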