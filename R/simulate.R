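#' Simulation configuration for a synthetic ASE/LOE cohort
#'
#' Describes a cohort of case and control subjects, each sequenced in one or
#' more cardiovascular tissues, with heterozygous SNPs whose allele-specific
#' read counts are binomially sampled. Under the null every SNP expresses
#' both alleles at fraction `null_allele_fraction`; configured events inject
#' extreme allele-specific expression (ASE), imprinting, nonsense-mediated
#' decay (NMD) and biallelic loss of expression (LOE), each recorded as a
#' truth label.
#'
#' Event tables use 1-based gene and subject indices:
#' \describe{
#'   \item{ase_events}{`data.frame(gene, subject, allele_fraction,
#'     expr_fold)`; `allele_fraction` is the expression fraction of the
#'     over-expressed haplotype (>= 0.88 for extreme ASE); `expr_fold`
#'     optionally scales the gene's total expression in that subject
#'     (NA = unchanged).}
#'   \item{imprinting_events}{`data.frame(gene, expressed_parent,
#'     penetrance)`; `expressed_parent` is "maternal" or "paternal";
#'     each subject silences the other parent's allele with probability
#'     `penetrance`.}
#'   \item{nmd_events}{`data.frame(gene, subject, lof_allele_fraction)`;
#'     the gene gains a nonsense SNP whose allele is expressed at the given
#'     fraction (<= 0.2 for decay).}
#'   \item{loe_events}{`data.frame(gene, subject, fold)`; total expression
#'     (and SNP read depth) scaled by `fold` (<= 0.1 for LOE).}
#' }
#'
#' @param n_subjects Number of case subjects.
#' @param n_controls Number of control subjects.
#' @param tissues_per_subject Tissues sampled per subject.
#' @param n_genes Number of genes.
#' @param snps_per_gene_mean Mean heterozygous SNPs per gene per subject.
#' @param panel_sites_per_gene Candidate SNP sites per gene; subjects are
#'   heterozygous at each site independently, so sites recur across
#'   subjects (as real polymorphisms do).
#' @param read_depth_mean Mean RNA-seq reads per SNP per tissue.
#' @param null_allele_fraction Haplotype expression fraction under the null.
#' @param ase_events,imprinting_events,nmd_events,loe_events Event tables,
#'   see Details.
#' @param imprinting_fraction Expressed-parent allele fraction for
#'   imprinted expression.
#' @param mapping_bias_fraction Fraction of SNP sites to contaminate with
#'   artifactual reference bias (applied by [inject_mapping_bias()] when
#'   run through [generate_cohort()]).
#' @param trio_fraction Fraction of subjects with parental genotypes
#'   (phased SNPs).
#' @param overdispersion Beta-binomial overdispersion rho in [0,1);
#'   0 (default) gives pure binomial sampling, matching the assumption of
#'   the downstream binomial test.
#' @param total_reads_per_sample Aligned reads per RNA-seq sample.
#' @param expr_meanlog,expr_sdlog Log-normal parameters for gene baseline
#'   expression (r.p.m.).
#' @param expr_noise_sdlog Log-normal sd of per-sample expression noise;
#'   sets the within-tissue coefficient of variation.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 16, n_controls = 8,
                              tissues_per_subject = 2,
                              n_genes = 200,
                              snps_per_gene_mean = 3,
                              panel_sites_per_gene = 8,
                              read_depth_mean = 50,
                              null_allele_fraction = 0.5,
                              ase_events = NULL,
                              imprinting_events = NULL,
                              nmd_events = NULL,
                              loe_events = NULL,
                              imprinting_fraction = 0.95,
                              mapping_bias_fraction = 0,
                              trio_fraction = 0.25,
                              overdispersion = 0,
                              total_reads_per_sample = 2e6,
                              expr_meanlog = log(30), expr_sdlog = 1,
                              expr_noise_sdlog = 0.15,
                              seed = 1L) {
  empty_ev <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  if (is.null(ase_events))
    ase_events <- empty_ev(gene = integer(), subject = integer(),
                           allele_fraction = numeric(),
                           expr_fold = numeric())
  if (is.null(ase_events$expr_fold)) ase_events$expr_fold <- NA_real_
  if (is.null(imprinting_events))
    imprinting_events <- empty_ev(gene = integer(),
                                  expressed_parent = character(),
                                  penetrance = numeric())
  if (is.null(nmd_events))
    nmd_events <- empty_ev(gene = integer(), subject = integer(),
                           lof_allele_fraction = numeric())
  if (is.null(loe_events))
    loe_events <- empty_ev(gene = integer(), subject = integer(),
                           fold = numeric())

  cfg <- list(n_subjects = n_subjects, n_controls = n_controls,
              tissues_per_subject = tissues_per_subject, n_genes = n_genes,
              snps_per_gene_mean = snps_per_gene_mean,
              panel_sites_per_gene = panel_sites_per_gene,
              read_depth_mean = read_depth_mean,
              null_allele_fraction = null_allele_fraction,
              ase_events = ase_events,
              imprinting_events = imprinting_events,
              nmd_events = nmd_events, loe_events = loe_events,
              imprinting_fraction = imprinting_fraction,
              mapping_bias_fraction = mapping_bias_fraction,
              trio_fraction = trio_fraction,
              overdispersion = overdispersion,
              total_reads_per_sample = total_reads_per_sample,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              expr_noise_sdlog = expr_noise_sdlog,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_subjects", "tissues_per_subject", "n_genes",
              "panel_sites_per_gene")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("simulation_config: '", f, "' must be a positive integer")
  if (!is.numeric(cfg$n_controls) || cfg$n_controls < 0 ||
      cfg$n_controls != round(cfg$n_controls))
    stop("simulation_config: 'n_controls' must be a non-negative integer")
  pos <- c("snps_per_gene_mean", "read_depth_mean", "total_reads_per_sample",
           "expr_sdlog", "expr_noise_sdlog")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("simulation_config: '", f, "' must be positive")
  probs <- c("null_allele_fraction", "mapping_bias_fraction",
             "trio_fraction", "overdispersion", "imprinting_fraction")
  for (f in probs)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("simulation_config: '", f, "' must be a probability in [0,1]")
  n_total <- cfg$n_subjects + cfg$n_controls
  chk_idx <- function(ev, field, max, name) {
    if (nrow(ev) && (any(ev[[field]] < 1) || any(ev[[field]] > max)))
      stop("simulation_config: '", name, "$", field, "' out of range")
  }
  for (nm in c("ase_events", "nmd_events", "loe_events")) {
    chk_idx(cfg[[nm]], "gene", cfg$n_genes, nm)
    chk_idx(cfg[[nm]], "subject", n_total, nm)
  }
  chk_idx(cfg$imprinting_events, "gene", cfg$n_genes, "imprinting_events")
  if (nrow(cfg$ase_events) && any(cfg$ase_events$allele_fraction < 0 |
                                  cfg$ase_events$allele_fraction > 1))
    stop("simulation_config: 'ase_events$allele_fraction' must be in [0,1]")
  if (nrow(cfg$imprinting_events) &&
      !all(cfg$imprinting_events$expressed_parent %in%
           c("maternal", "paternal")))
    stop("simulation_config: 'imprinting_events$expressed_parent' must be ",
         "maternal or paternal")
  both <- merge(cfg$ase_events[c("gene", "subject")],
                cfg$loe_events[c("gene", "subject")])
  if (nrow(both))
    stop("simulation_config: 'ase_events'/'loe_events' overlap: gene ",
         both$gene[1], " subject ", both$subject[1],
         " cannot be both ASE and LOE")
  invisible(cfg)
}

#' Generate a synthetic cohort
#'
#' Produces genotypes, allele counts, an expression table, a fetal-heart
#' reference and truth labels from a [simulation_config()]. Null SNPs draw
#' reference reads as Binomial(depth, 0.5); event SNPs use the configured
#' allele fraction for every SNP of that gene in that subject, with the
#' over-expressed base consistently on one haplotype (the cis structure the
#' phasing heuristic exploits). Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort` with elements `subjects`,
#'   `genes`, `sites`, `genotypes`, `allele_counts`, `expression`
#'   (an `expression_table`), `fetal_reference`, `truth` and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  validate_simulation_config(config)
  set.seed(config$seed)
  n_total <- config$n_subjects + config$n_controls
  subj_ids <- sprintf("S%03d", seq_len(n_total))
  subjects <- data.frame(
    subject_id = subj_ids,
    cohort = rep(c("case", "control"),
                 c(config$n_subjects, config$n_controls)),
    trio = stats::runif(n_total) < config$trio_fraction,
    stringsAsFactors = FALSE)

  ## genes: baseline expression log-normal; LOE target genes are placed
  ## well inside the high-expression tier (LOE calling is defined for
  ## highly expressed, tightly regulated genes, so the injected events
  ## must sit safely above the upper-quartile candidacy gate even after
  ## tissue-level multipliers)
  gn <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(gn))
  expr_mean <- stats::rlnorm(gn, config$expr_meanlog, config$expr_sdlog)
  if (nrow(config$loe_events)) {
    hi <- stats::quantile(expr_mean, 0.95)
    idx <- unique(config$loe_events$gene)
    expr_mean[idx] <- pmax(expr_mean[idx], hi)
  }
  imprint_parent <- rep(NA_character_, gn)
  if (nrow(config$imprinting_events))
    imprint_parent[config$imprinting_events$gene] <-
      config$imprinting_events$expressed_parent
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(((seq_len(gn) - 1) %% 22) + 1),
    strand = sample(c("+", "-"), gn, replace = TRUE),
    coding = TRUE,
    is_hla = FALSE,
    imprinted_parent = imprint_parent,
    expr_mean = expr_mean,
    stringsAsFactors = FALSE)

  ## SNP site panel: shared polymorphic sites, spaced widely so positional
  ## filters are quiet unless contamination sets flags
  P <- config$panel_sites_per_gene
  bases <- c("A", "C", "G", "T")
  site_gene <- rep(seq_len(gn), each = P)
  sites <- data.frame(
    site_id = sprintf("%s_s%d", gene_ids[site_gene],
                      rep(seq_len(P), times = gn)),
    gene_id = gene_ids[site_gene],
    chrom = genes$chrom[site_gene],
    pos = (site_gene - 1L) * 1000000L + 10000L +
      rep(seq_len(P) - 1L, times = gn) * 400L,
    ref = sample(bases, gn * P, replace = TRUE),
    effect_class = sample(c("SYNONYMOUS_CODING", "NON_SYNONYMOUS_CODING",
                            "UTR_3_PRIME", "UTR_5_PRIME"),
                          gn * P, replace = TRUE,
                          prob = c(0.3, 0.3, 0.25, 0.15)),
    population_af = stats::runif(gn * P, 0.05, 0.5),
    stringsAsFactors = FALSE)
  sites$alt <- vapply(sites$ref,
                      function(r) sample(setdiff(bases, r), 1), "")
  ## genes carrying an NMD event get a designated nonsense site (panel slot 1)
  if (nrow(config$nmd_events)) {
    lof_sites <- (unique(config$nmd_events$gene) - 1L) * P + 1L
    sites$effect_class[lof_sites] <- "STOP_GAINED"
    sites$population_af[lof_sites] <- 1e-4
  }

  ## heterozygosity: subject x site Bernoulli; event subjects forced het at
  ## the event gene (first sites of the panel) so events are observable
  het_prob <- min(1, config$snps_per_gene_mean / P)
  het <- matrix(stats::runif(n_total * nrow(sites)) < het_prob,
                nrow = n_total)
  force_het <- function(het, gene, subject, k, P) {
    for (i in seq_along(gene)) {
      slots <- (gene[i] - 1L) * P + seq_len(min(k, P))
      het[subject[i], slots] <- TRUE
    }
    het
  }
  if (nrow(config$ase_events))
    het <- force_het(het, config$ase_events$gene,
                     config$ase_events$subject, 3L, P)
  if (nrow(config$loe_events))
    het <- force_het(het, config$loe_events$gene,
                     config$loe_events$subject, 3L, P)
  if (nrow(config$nmd_events))
    het <- force_het(het, config$nmd_events$gene,
                     config$nmd_events$subject, 1L, P)

  ## long genotype table for het (subject, site) pairs
  idx <- which(het, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  si <- idx[, 2]
  gt <- data.frame(
    subject_id = subj_ids[idx[, 1]],
    site_id = sites$site_id[si],
    gene_id = sites$gene_id[si],
    chrom = sites$chrom[si],
    pos = sites$pos[si],
    ref = sites$ref[si],
    alt = sites$alt[si],
    gq = 99L,
    dna_ab = round(stats::rbeta(nrow(idx), 30, 30), 3),
    effect_class = sites$effect_class[si],
    population_af = sites$population_af[si],
    flag_clustered = FALSE, flag_near_indel = FALSE,
    flag_repeat = FALSE, flag_alt_spliced = FALSE,
    flag_complex = FALSE,
    stringsAsFactors = FALSE)
  ## haplotype A is the maternal haplotype by convention; the alt base sits
  ## on A or B at random per subject x site
  gt$alt_on_hapA <- stats::runif(nrow(gt)) < 0.5
  gt$parent_of_alt_true <- ifelse(gt$alt_on_hapA, "maternal", "paternal")
  trio_of <- stats::setNames(subjects$trio, subjects$subject_id)
  gt$parent_of_alt <- ifelse(trio_of[gt$subject_id],
                             gt$parent_of_alt_true, "unknown")

  ## per subject x gene haplotype-A expression fraction and depth scale
  fracA <- matrix(config$null_allele_fraction, n_total, gn)
  depth_scale <- matrix(1, n_total, gn)
  expr_scale <- matrix(1, n_total, gn)
  truth <- list()
  ev <- config$ase_events
  if (nrow(ev)) {
    fracA[cbind(ev$subject, ev$gene)] <- ev$allele_fraction
    esc <- ifelse(is.na(ev$expr_fold), 1, ev$expr_fold)
    expr_scale[cbind(ev$subject, ev$gene)] <- esc
    truth[["ase"]] <- data.frame(
      type = "ase", gene_id = gene_ids[ev$gene],
      subject_id = subj_ids[ev$subject], site_id = NA_character_,
      param = ev$allele_fraction, overexpressed_hap = "A",
      stringsAsFactors = FALSE)
  }
  ev <- config$imprinting_events
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      on <- stats::runif(n_total) < ev$penetrance[i]
      hapA_expr <- ev$expressed_parent[i] == "maternal"
      fracA[on, ev$gene[i]] <- if (hapA_expr) config$imprinting_fraction
                               else 1 - config$imprinting_fraction
      truth[[paste0("imp", i)]] <- data.frame(
        type = "imprinting", gene_id = gene_ids[ev$gene[i]],
        subject_id = subj_ids[on], site_id = NA_character_,
        param = ev$penetrance[i],
        overexpressed_hap = if (hapA_expr) "A" else "B",
        stringsAsFactors = FALSE)
    }
  }
  ev <- config$nmd_events
  if (nrow(ev)) {
    ## LOF alt allele placed on haplotype B; B expressed at lof fraction
    for (i in seq_len(nrow(ev))) {
      lof_site <- sites$site_id[(ev$gene[i] - 1L) * P + 1L]
      sel <- gt$subject_id == subj_ids[ev$subject[i]] &
        gt$site_id == lof_site
      gt$alt_on_hapA[sel] <- FALSE
      gt$parent_of_alt_true[sel] <- "paternal"
      gt$parent_of_alt[sel] <- ifelse(trio_of[gt$subject_id[sel]],
                                      "paternal", "unknown")
      fracA[ev$subject[i], ev$gene[i]] <- 1 - ev$lof_allele_fraction[i]
    }
    truth[["nmd"]] <- data.frame(
      type = "nmd", gene_id = gene_ids[ev$gene],
      subject_id = subj_ids[ev$subject],
      site_id = sites$site_id[(ev$gene - 1L) * P + 1L],
      param = ev$lof_allele_fraction, overexpressed_hap = "A",
      stringsAsFactors = FALSE)
  }
  ev <- config$loe_events
  if (nrow(ev)) {
    depth_scale[cbind(ev$subject, ev$gene)] <- ev$fold
    expr_scale[cbind(ev$subject, ev$gene)] <- ev$fold
    truth[["loe"]] <- data.frame(
      type = "loe", gene_id = gene_ids[ev$gene],
      subject_id = subj_ids[ev$subject], site_id = NA_character_,
      param = ev$fold, overexpressed_hap = NA_character_,
      stringsAsFactors = FALSE)
  }

  ## allele counts per subject x tissue x het SNP
  tissues <- sprintf("T%d", seq_len(config$tissues_per_subject))
  srow <- match(gt$subject_id, subj_ids)
  grow <- match(gt$gene_id, gene_ids)
  counts <- do.call(rbind, lapply(tissues, function(tis) {
    depth <- stats::rpois(nrow(gt), config$read_depth_mean *
                            depth_scale[cbind(srow, grow)])
    pA <- fracA[cbind(srow, grow)]
    p_alt <- ifelse(gt$alt_on_hapA, pA, 1 - pA)
    if (config$overdispersion > 0) {
      rho <- config$overdispersion
      conc <- (1 - rho) / rho
      p_alt <- stats::rbeta(nrow(gt), p_alt * conc, (1 - p_alt) * conc)
    }
    alt_reads <- stats::rbinom(nrow(gt), depth, p_alt)
    data.frame(subject_id = gt$subject_id, tissue = tis,
               site_id = gt$site_id, chrom = gt$chrom, pos = gt$pos,
               ref = gt$ref, alt = gt$alt,
               ref_reads = depth - alt_reads, alt_reads = alt_reads,
               stringsAsFactors = FALSE)
  }))
  counts <- counts[order(counts$subject_id, counts$tissue, counts$pos), ]
  rownames(counts) <- NULL

  ## expression matrix: log-normal noise around gene x tissue means
  samples <- expand.grid(subject_id = subj_ids, tissue = tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[order(samples$subject_id, samples$tissue), ]
  samples$sample_id <- paste(samples$subject_id, samples$tissue, sep = "_")
  samples$total_reads <- config$total_reads_per_sample
  tissue_mult <- matrix(stats::rlnorm(gn * length(tissues), 0, 0.2),
                        gn, length(tissues),
                        dimnames = list(gene_ids, tissues))
  mu <- tissue_mult[, samples$tissue, drop = FALSE] * genes$expr_mean
  mu <- mu * t(expr_scale[match(samples$subject_id, subj_ids), ,
                          drop = FALSE])
  rpm_noise <- matrix(stats::rlnorm(length(mu), 0, config$expr_noise_sdlog),
                      nrow(mu))
  count_mat <- round(mu * rpm_noise * config$total_reads_per_sample / 1e6)
  dimnames(count_mat) <- list(gene_ids, samples$sample_id)
  expression <- compute_rpm(count_mat,
                            stats::setNames(samples$total_reads,
                                            samples$sample_id),
                            sample_info = samples)

  fetal_reference <- data.frame(
    gene_id = gene_ids,
    fetal_rpm = round(genes$expr_mean * stats::rlnorm(gn, 0, 0.1), 2),
    stringsAsFactors = FALSE)

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(), gene_id = character(),
               subject_id = character(), site_id = character(),
               param = numeric(), overexpressed_hap = character(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  cohort <- structure(list(subjects = subjects, genes = genes,
                           sites = sites, genotypes = gt,
                           allele_counts = counts, expression = expression,
                           fetal_reference = fetal_reference, truth = truth,
                           config = config),
                      class = "synthetic_cohort")
  if (config$mapping_bias_fraction > 0)
    cohort <- inject_mapping_bias(cohort, config$mapping_bias_fraction)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$cohort == "case"), "case /",
      sum(x$subjects$cohort == "control"), "control ),",
      nrow(x$genes), "genes,", nrow(x$genotypes), "het genotypes,",
      nrow(x$allele_counts), "allele-count records,",
      nrow(x$truth), "truth labels\n")
  invisible(x)
}

#' Inject artifactual reference mapping bias
#'
#' Contaminates a fraction of SNP sites with monoallelic expression of one
#' base (the reference base with probability `bias_toward_ref`), emulating
#' reads from the alternate allele failing to align. Contamination is
#' site-level: every subject heterozygous at a contaminated site is
#' affected, because mapping bias is a property of the locus, not the
#' subject. Contaminated sites also receive positional artefact flags
#' (clustered / near-indel / repeat) with probability `flag_prob`, so the
#' positional QC filters can find most of them; the remainder are left for
#' the cohort-level common-bias filter.
#'
#' @param cohort A `synthetic_cohort`.
#' @param fraction Fraction of SNP sites to contaminate.
#' @param bias_toward_ref Probability a contaminated site expresses the
#'   reference base.
#' @param flag_prob Probability a contaminated site carries a positional
#'   artefact flag.
#' @return The modified cohort with `truth` rows of type `mapping_bias`.
#' @export
inject_mapping_bias <- function(cohort, fraction, bias_toward_ref = 1,
                                flag_prob = 0.8) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            fraction >= 0, fraction <= 1,
            bias_toward_ref >= 0, bias_toward_ref <= 1)
  if (fraction == 0) return(cohort)
  set.seed(cohort$config$seed + 1000003L)
  n_sites <- nrow(cohort$sites)
  n_pick <- round(fraction * n_sites)
  if (n_pick == 0) return(cohort)
  picked <- sort(sample.int(n_sites, n_pick))
  picked_ids <- cohort$sites$site_id[picked]
  toward_ref <- stats::runif(n_pick) < bias_toward_ref

  cc <- cohort$allele_counts
  hit <- match(cc$site_id, picked_ids)
  sel <- !is.na(hit)
  depth <- cc$ref_reads[sel] + cc$alt_reads[sel]
  ref_side <- toward_ref[hit[sel]]
  cc$ref_reads[sel] <- ifelse(ref_side, depth, 0L)
  cc$alt_reads[sel] <- ifelse(ref_side, 0L, depth)
  cohort$allele_counts <- cc

  flagged <- stats::runif(n_pick) < flag_prob
  which_flag <- sample(c("flag_clustered", "flag_near_indel", "flag_repeat"),
                       n_pick, replace = TRUE)
  gt <- cohort$genotypes
  for (fl in c("flag_clustered", "flag_near_indel", "flag_repeat")) {
    fl_sites <- picked_ids[flagged & which_flag == fl]
    gt[[fl]][gt$site_id %in% fl_sites] <- TRUE
  }
  cohort$genotypes <- gt

  cohort$truth <- rbind(cohort$truth, data.frame(
    type = "mapping_bias", gene_id = cohort$sites$gene_id[picked],
    subject_id = NA_character_, site_id = picked_ids,
    param = as.numeric(toward_ref), overexpressed_hap = NA_character_,
    stringsAsFactors = FALSE))
  cohort
}

#' Subsample heterozygous SNPs at a fixed stride
#'
#' Retains every `stride`-th SNP per subject in genomic order (rows 1,
#' 1+stride, 1+2*stride, ...), thinning dense variant sets (for example
#' F1-hybrid-scale SNP density) to human-WGS-like density.
#'
#' @param genotypes A genotype data.frame with `subject_id`, `chrom`, `pos`.
#' @param stride Keep one SNP in every `stride`.
#' @return The subsampled genotype data.frame.
#' @export
subsample_snps <- function(genotypes, stride) {
  if (!is.numeric(stride) || length(stride) != 1 || stride < 1 ||
      stride != round(stride))
    stop("subsample_snps: 'stride' must be an integer >= 1")
  if (stride == 1) return(genotypes)
  ord <- order(genotypes$subject_id,
               suppressWarnings(as.integer(sub("^chr", "", genotypes$chrom))),
               genotypes$pos)
  g <- genotypes[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(g)), g$subject_id), function(i) {
    i[seq(1, length(i), by = stride)]
  }), use.names = FALSE)
  out <- g[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
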