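#' Build an expression table with reads-per-million normalization
#'
#' Wraps a gene x sample count matrix with per-sample library sizes and the
#' derived r.p.m. matrix (count x 10^6 / total aligned reads). A gene is
#' flagged expressed in a sample at r.p.m. >= 2 (see [expressed_rpm_min()]).
#'
#' @param counts Integer matrix, genes in rows, samples in columns.
#' @param totals Named numeric vector of total aligned reads per sample;
#'   names must cover `colnames(counts)`.
#' @param sample_info Optional data.frame with `sample_id`, `subject_id`,
#'   `tissue` describing the columns.
#' @return A list of class `expression_table` with `counts`, `rpm`,
#'   `totals`, `samples` and `expressed` (logical matrix).
#' @export
compute_rpm <- function(counts, totals, sample_info = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("compute_rpm: 'counts' must have sample column names")
  if (is.null(names(totals))) {
    if (length(totals) != ncol(counts))
      stop("compute_rpm: 'totals' must be named or match ncol(counts)")
    names(totals) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(totals))
  if (length(missing))
    stop("compute_rpm: no total aligned reads for sample(s): ",
         paste(missing, collapse = ", "))
  totals <- totals[colnames(counts)]
  if (any(totals <= 0))
    stop("compute_rpm: total aligned reads must be positive (sample ",
         names(totals)[which(totals <= 0)[1]], ")")
  if (any(counts < 0))
    stop("compute_rpm: negative counts")
  rpm <- sweep(counts, 2, totals / 1e6, "/")
  if (is.null(sample_info))
    sample_info <- data.frame(sample_id = colnames(counts),
                              subject_id = colnames(counts),
                              tissue = "unknown",
                              total_reads = unname(totals),
                              stringsAsFactors = FALSE)
  structure(list(counts = counts, rpm = rpm, totals = totals,
                 samples = sample_info,
                 expressed = rpm >= expressed_rpm_min()),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; mean expressed genes/sample:",
      round(mean(colSums(x$expressed)), 1), "\n")
  invisible(x)
}

req_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' Read per-SNP allele counts from TSV
#'
#' Columns: subject_id, tissue, chrom, pos, ref, alt, ref_reads, alt_reads.
#' Rows with negative counts or duplicated (subject, tissue, chrom, pos)
#' keys are rejected.
#'
#' @param path TSV path (lines starting with `#` are ignored).
#' @return A typed data.frame of allele counts.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  req_cols(df, c("subject_id", "tissue", "chrom", "pos", "ref", "alt",
                 "ref_reads", "alt_reads"), "read_allele_counts")
  df$chrom <- as.character(df$chrom)
  bad <- which(df$ref_reads < 0 | df$alt_reads < 0)
  if (length(bad))
    stop("read_allele_counts: negative read count at row ", bad[1])
  key <- paste(df$subject_id, df$tissue, df$chrom, df$pos)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("read_allele_counts: duplicate (subject, tissue, chrom, pos) ",
         "key at row ", dup[1])
  df
}

#' Write allele counts (and other tables) as commented-header TSV
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param header_lines Optional character vector written as `# `-prefixed
#'   header lines (e.g. config hash, seed).
#' @export
write_tsv_commented <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read heterozygous SNPs from a VCF
#'
#' Returns only biallelic heterozygous SNPs, with genotype quality (GQ),
#' DNA allele balance (from AD: ALT/(REF+ALT)) and parental origin of the
#' alternate allele. Parental origin is resolved from trio genotypes when
#' unambiguous (the alternate allele present in exactly one parent);
#' without trios, a phased GT is interpreted as maternal|paternal. Sites
#' that are multi-allelic, non-SNP, or homozygous are skipped (counted in
#' a message).
#'
#' @param path Proband VCF path (VCF 4.x; plain text or gzip).
#' @param trio_paths Optional named list/vector with elements `mother` and
#'   `father` giving parental VCF paths.
#' @return Data.frame of heterozygous SNPs with columns subject_id, chrom,
#'   pos, ref, alt, gq, dna_ab, parent_of_alt.
#' @export
read_het_vcf <- function(path, trio_paths = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n0 <- nrow(fix)
  gt_raw <- vcfR::extract.gt(v, "GT")
  subject <- colnames(gt_raw)[1]
  gt <- gt_raw[, 1]
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1 & !is.na(gt)
  allele_mat <- do.call(rbind, strsplit(gsub("\\|", "/", gt), "/"))
  het <- biallelic & allele_mat[, 1] != allele_mat[, 2]
  skipped <- n0 - sum(het)
  if (skipped > 0)
    message("read_het_vcf: skipped ", skipped,
            " non-biallelic/non-SNP/non-het site(s)")
  gq <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "GQ")[, 1]))
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  ad_mat <- suppressWarnings(
    do.call(rbind, lapply(strsplit(ad, ","),
                          function(x) as.numeric(x[1:2]))))
  dna_ab <- ad_mat[, 2] / (ad_mat[, 1] + ad_mat[, 2])

  out <- data.frame(subject_id = subject,
                    chrom = as.character(fix$CHROM),
                    pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    gq = gq, dna_ab = dna_ab,
                    parent_of_alt = "unknown",
                    stringsAsFactors = FALSE)[het, , drop = FALSE]
  phased <- grepl("\\|", gt[het])
  first_is_alt <- allele_mat[het, 1] != "0"
  out$parent_of_alt[phased] <- ifelse(first_is_alt[phased],
                                      "maternal", "paternal")
  if (!is.null(trio_paths)) {
    parent_alleles <- function(p) {
      pv <- vcfR::read.vcfR(p, verbose = FALSE)
      pfix <- as.data.frame(vcfR::getFIX(pv), stringsAsFactors = FALSE)
      pgt <- vcfR::extract.gt(pv, "GT")[, 1]
      has_alt <- grepl("1", pgt)
      is_het <- vapply(strsplit(gsub("\\|", "/", pgt), "/"),
                       function(a) a[1] != a[2], logical(1))
      data.frame(key = paste(pfix$CHROM, pfix$POS), has_alt = has_alt,
                 is_het = is_het, stringsAsFactors = FALSE)
    }
    mom <- parent_alleles(trio_paths[["mother"]])
    dad <- parent_alleles(trio_paths[["father"]])
    key <- paste(out$chrom, out$pos)
    m_alt <- mom$has_alt[match(key, mom$key)]
    d_alt <- dad$has_alt[match(key, dad$key)]
    m_alt[is.na(m_alt)] <- FALSE
    d_alt[is.na(d_alt)] <- FALSE
    origin <- rep("unknown", nrow(out))
    origin[m_alt & !d_alt] <- "maternal"
    origin[d_alt & !m_alt] <- "paternal"
    out$parent_of_alt <- origin  # both-parents-het stays unknown
  }
  rownames(out) <- NULL
  out
}

#' Write a minimal VCF of heterozygous SNPs for one subject
#'
#' Emits a VCF 4.2 file with GT, GQ and AD fields; trio subjects get a
#' phased GT (maternal|paternal), others an unphased 0/1.
#'
#' @param snps Data.frame with chrom, pos, ref, alt, gq, dna_ab and
#'   parent_of_alt (maternal/paternal/unknown).
#' @param subject_id Sample name.
#' @param path Output path.
#' @param depth Assumed DNA depth used to reconstruct AD from `dna_ab`.
#' @param header_lines Extra `##`-prefixed metadata lines (e.g. seed).
#' @export
write_het_vcf <- function(snps, subject_id, path, depth = 60,
                          header_lines = NULL) {
  snps <- snps[order(suppressWarnings(
    as.integer(sub("^chr", "", snps$chrom))), snps$pos), , drop = FALSE]
  gtf <- ifelse(snps$parent_of_alt == "maternal", "1|0",
                ifelse(snps$parent_of_alt == "paternal", "0|1", "0/1"))
  alt_reads <- round(snps$dna_ab * depth)
  hdr <- c("##fileformat=VCFv4.2",
           header_lines,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  subject_id))
  body <- paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt, ".", "PASS",
                ".", "GT:GQ:AD",
                paste0(gtf, ":", snps$gq, ":",
                       depth - alt_reads, ",", alt_reads),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a known-imprinted-gene catalog
#'
#' TSV with columns `gene` (or `gene_id`) and `expressed_parent`
#' ("maternal"/"paternal").
#' @param path TSV path.
#' @return Data.frame with gene_id and expressed_parent.
#' @export
read_imprinted_catalog <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if ("gene" %in% names(df) && !"gene_id" %in% names(df))
    names(df)[names(df) == "gene"] <- "gene_id"
  req_cols(df, c("gene_id", "expressed_parent"), "read_imprinted_catalog")
  bad <- !df$expressed_parent %in% c("maternal", "paternal")
  if (any(bad))
    stop("read_imprinted_catalog: invalid expressed_parent at row ",
         which(bad)[1])
  df
}

#' Flag SNPs in alternatively spliced exons
#'
#' A SNP cannot be assessed for allele-specific expression when it lies in
#' an exon present in only a subset of the gene's isoforms: allele bias at
#' such a SNP can reflect allele-specific splicing instead. The flag is set
#' when the containing exon's isoform set is a strict subset of all isoform
#' identifiers seen for that gene.
#'
#' @param snps Data.frame with `gene_id`, `chrom`, `pos`.
#' @param exons Data.frame with `gene_id`, `start`, `end`, `isoform_ids`
#'   (comma-separated string per exon).
#' @return `snps` with logical column `flag_alt_spliced` replaced/updated.
#' @export
flag_alt_spliced_snps <- function(snps, exons) {
  req_cols(exons, c("gene_id", "start", "end", "isoform_ids"),
           "flag_alt_spliced_snps")
  if (any(exons$start >= exons$end))
    stop("flag_alt_spliced_snps: exon with start >= end")
  iso_sets <- strsplit(exons$isoform_ids, ",")
  if (any(lengths(iso_sets) == 0))
    stop("flag_alt_spliced_snps: exon with empty isoform_ids")
  gene_iso <- tapply(unlist(iso_sets),
                     rep(exons$gene_id, lengths(iso_sets)),
                     function(x) unique(x))
  exon_alt <- vapply(seq_len(nrow(exons)), function(i) {
    all_iso <- gene_iso[[exons$gene_id[i]]]
    length(setdiff(all_iso, iso_sets[[i]])) > 0
  }, logical(1))
  flag <- vapply(seq_len(nrow(snps)), function(i) {
    e <- exons$gene_id == snps$gene_id[i] &
      exons$start <= snps$pos[i] & exons$end >= snps$pos[i]
    any(exon_alt[e])
  }, logical(1))
  snps$flag_alt_spliced <- flag
  snps
}

#' Write a synthetic cohort to disk
#'
#' Genotypes as one VCF per subject, allele counts / expression counts /
#' truth labels as TSV, with the simulation seed recorded in each header.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_line <- paste0("seed=", cohort$config$seed)
  for (s in cohort$subjects$subject_id) {
    snps <- cohort$genotypes[cohort$genotypes$subject_id == s, ]
    write_het_vcf(snps, s, file.path(dir, paste0(s, ".vcf")),
                  header_lines = paste0("##", seed_line))
  }
  write_tsv_commented(
    cohort$allele_counts[c("subject_id", "tissue", "chrom", "pos", "ref",
                           "alt", "ref_reads", "alt_reads")],
    file.path(dir, "allele_counts.tsv"), seed_line)
  expr <- data.frame(gene_id = rownames(cohort$expression$counts),
                     cohort$expression$counts, check.names = FALSE)
  write_tsv_commented(expr, file.path(dir, "expression_counts.tsv"),
                      seed_line)
  write_tsv_commented(cohort$truth, file.path(dir, "truth.tsv"), seed_line)
  write_tsv_commented(cohort$fetal_reference,
                      file.path(dir, "fetal_reference.tsv"), seed_line)
  invisible(dir)
}
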