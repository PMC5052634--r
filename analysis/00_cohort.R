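# Shared study configuration for the analysis scripts. The cohort is a
# pure function of this config, so every script can rebuild it exactly
# rather than depending on execution order.

suppressMessages(library(cardase))

study_config <- function() {
  simulation_config(
    n_subjects = 16, n_controls = 8, tissues_per_subject = 2,
    n_genes = 200, read_depth_mean = 50, trio_fraction = 0.25,
    ase_events = data.frame(gene = 1:12, subject = rep_len(1:12, 12),
                            allele_fraction = 0.92,
                            expr_fold = c(rep(0.5, 4), rep(6, 2),
                                          rep(NA, 6))),
    imprinting_events = data.frame(gene = 21:24,
                                   expressed_parent = c("paternal",
                                                        "paternal",
                                                        "paternal",
                                                        "maternal"),
                                   penetrance = 0.9),
    nmd_events = data.frame(gene = 31:40, subject = rep_len(1:10, 10),
                            lof_allele_fraction = c(rep(0.15, 3),
                                                    rep(0.5, 7))),
    loe_events = data.frame(gene = 41:46, subject = 11:16, fold = 0.08),
    mapping_bias_fraction = 0.05,
    seed = 20160927)
}

study_cohort <- function() generate_cohort(study_config())
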