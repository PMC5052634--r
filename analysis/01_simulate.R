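#!/usr/bin/env Rscript

# Build the study cohort: 16 case and 8 control subjects, two tissues
# each, 200 genes, with injected extreme-ASE, imprinting, NMD and LOE
# events plus reference mapping-bias contamination at 5% of SNP sites.
# Writes the cohort to results/cohort/ and prints the truth-label census.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_cohort.R"))
dir.create("results", showWarnings = FALSE)

cohort <- study_cohort()
write_cohort(cohort, "results/cohort")

cat("Cohort generated:\n")
print(cohort)
cat("\nTruth labels by type:\n")
print(table(cohort$truth$type))
cat("\nWritten to results/cohort/ (one VCF per subject + TSV tables).\n")
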