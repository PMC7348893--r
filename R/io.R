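# Readers and writers: multi-sample VCF (via vcfR), sample-metadata and
# gene-map TSVs, and 12-column tabular homology hit tables.
#
# Coordinate convention: VCF positions are 1-based and so are the site
# positions stored in a genotype_matrix; allele index 0 is the VCF REF.

#' Read sample metadata
#'
#' TSV with header and columns `sample_id`, `sex`, `role`.
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "role")
  if (!all(need %in% names(meta))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  }
  meta
}

#' Write sample metadata
#' @param individuals Data frame with `sample_id`, `sex`, `role`.
#' @param path Output path.
#' @export
write_sample_metadata <- function(individuals, path) {
  utils::write.table(individuals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-map table
#'
#' TSV with header and columns `gene_id`, `map_cM`, `cross_status` and
#' optionally `true_region`.
#' @param path File path.
#' @return Data frame.
#' @export
read_gene_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "map_cM", "cross_status") %in% names(map))) {
    stop("gene map must have columns gene_id, map_cM, cross_status")
  }
  map
}

#' @rdname read_gene_map
#' @param records Data frame to write.
#' @export
write_gene_map <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tabular homology hit table
#'
#' The standard headerless 12-column tabular format of nucleotide
#' homology searches: query, subject, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score.
#'
#' @param path File path.
#' @return Data frame with columns `qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`.
#' @export
read_homology_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != 12) stop("expected 12 tab-separated columns")
  names(hits) <- cols
  hits
}

#' Write genotype matrices as a multi-sample VCF
#'
#' One contig per gene (contig id = gene id, length = gene length),
#' VCF 4.2, unphased `GT` calls. All matrices must share the same sample
#' panel.
#'
#' @param matrices A [genotype_matrix()] or list of them.
#' @param path Output path (plain-text `.vcf`).
#' @export
write_vcf <- function(matrices, path) {
  if (inherits(matrices, "genotype_matrix")) matrices <- list(matrices)
  ind <- matrices[[1]]$individuals$sample_id
  for (gm in matrices) {
    if (!identical(gm$individuals$sample_id, ind)) {
      stop("all matrices must share the same sample panel")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=parboundary",
    vapply(matrices, function(gm) {
      sprintf("##contig=<ID=%s,length=%d>", gm$gene_id, gm$gene_length)
    }, ""),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind), collapse = "\t")
  ), con)
  for (gm in matrices) {
    for (s in seq_along(gm$positions)) {
      al <- gm$alleles[[s]]
      gt <- ifelse(is.na(gm$a1[s, ]), "./.",
                   paste0(gm$a1[s, ], "/", gm$a2[s, ]))
      writeLines(paste(c(
        gm$gene_id, gm$positions[s], ".", al[1],
        if (length(al) > 1) paste(al[-1], collapse = ",") else ".",
        ".", "PASS", ".", "GT", gt
      ), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a multi-sample VCF into genotype matrices
#'
#' Parses a VCF 4.x file (one contig per gene) and returns one
#' [genotype_matrix()] per contig. Indel records (REF or any ALT longer
#' than one base) are removed; multiallelic SNPs are retained.
#' Half-missing calls are treated as fully missing.
#'
#' @param path VCF file path.
#' @param metadata Data frame with `sample_id`, `sex`, `role` covering
#'   every sample in the VCF (see [read_sample_metadata()]).
#' @return Named list of [genotype_matrix()] (names = gene ids), in
#'   order of first appearance; empty list for an empty VCF body.
#' @export
read_vcf <- function(path, metadata) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(list())
  samples <- colnames(v@gt)[-1]
  missing_meta <- setdiff(samples, metadata$sample_id)
  if (length(missing_meta)) {
    stop("VCF sample(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  ind <- metadata[match(samples, metadata$sample_id),
                  c("sample_id", "sex", "role")]
  rownames(ind) <- NULL

  # contig lengths from the header, if declared
  meta_lines <- grep("^##contig=", v@meta, value = TRUE)
  contig_len <- stats::setNames(
    as.integer(sub(".*length=([0-9]+).*", "\\1", meta_lines)),
    sub(".*ID=([^,>]+).*", "\\1", meta_lines)
  )

  gt_raw <- v@gt[, -1, drop = FALSE]
  alt_list <- strsplit(ifelse(is.na(fix$ALT) | fix$ALT == ".", "", fix$ALT), ",")
  is_snp <- nchar(fix$REF) == 1 &
    vapply(alt_list, function(a) all(nchar(a) == 1), TRUE)

  out <- list()
  for (chrom in unique(fix$CHROM)) {
    rows <- which(fix$CHROM == chrom & is_snp)
    pos <- as.integer(fix$POS[rows])
    alleles <- lapply(rows, function(i) c(fix$REF[i], alt_list[[i]]))
    n_ind <- nrow(ind)
    a1 <- matrix(NA_integer_, length(rows), n_ind)
    a2 <- matrix(NA_integer_, length(rows), n_ind)
    if (length(rows)) {
      gt <- sub(":.*", "", gt_raw[rows, , drop = FALSE])
      parts <- strsplit(gt, "[/|]")
      g1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
      g2 <- suppressWarnings(as.integer(vapply(parts, function(p) {
        if (length(p) >= 2) p[2] else NA_character_
      }, "")))
      a1 <- matrix(g1, length(rows), n_ind)
      a2 <- matrix(g2, length(rows), n_ind)
    }
    glen <- if (chrom %in% names(contig_len)) contig_len[[chrom]] else
      max(pos, 1L)
    out[[chrom]] <- genotype_matrix(
      gene_id = chrom, positions = pos, alleles = alleles,
      a1 = a1, a2 = a2, individuals = ind, gene_length = glen
    )
  }
  out
}
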