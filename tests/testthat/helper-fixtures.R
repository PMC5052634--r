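# Shared fixture builders. All cohorts are generated in code at test time;
# sizes are kept small so the whole suite runs in well under a minute per
# file.

small_null_config <- function(seed, ...) {
  simulation_config(n_subjects = 8, n_controls = 4, n_genes = 100,
                    tissues_per_subject = 2, read_depth_mean = 50,
                    seed = seed, ...)
}

# strong, easily recoverable ASE events spread over distinct gene/subject
# pairs
strong_ase_events <- function(n_events, n_subjects, allele_fraction = 0.92) {
  data.frame(gene = seq_len(n_events),
             subject = rep_len(seq_len(n_subjects), n_events),
             allele_fraction = allele_fraction,
             expr_fold = NA_real_)
}

# independent brute-force oracle for the two-sided binomial P value:
# direct enumeration of the binomial pmf, no pbinom
binom_two_sided_oracle <- function(H, L) {
  n <- H + L
  k <- 0:n
  pmf <- choose(n, k) / 2^n
  min(1, 2 * sum(pmf[k >= H]))
}

# measurement records shaped like run_snp_qc()$pass, built directly
make_measurements <- function(gene_id, subject_id, tissue, ref, alt,
                              parent_of_alt = "unknown") {
  data.frame(gene_id = gene_id, subject_id = subject_id, tissue = tissue,
             site_id = paste0("site", seq_along(ref)),
             ref_reads = ref, alt_reads = alt,
             parent_of_alt = parent_of_alt, stringsAsFactors = FALSE)
}
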