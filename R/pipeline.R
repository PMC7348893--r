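# End-to-end orchestration: simulate -> call Y-SNPs -> scan wild females
# -> infer boundaries & classify -> diversity statistics, plus the
# fixture-replication entry point. Outputs are plain TSV/JSON so every
# stage interoperates file-for-file with external tools.

#' Run the full inference pipeline on simulated data
#'
#' Simulates a dataset under `params`, calls Y-SNPs from the cross for
#' every gene, scans the wild females for leaked Y alleles, infers the
#' region boundaries from the data ([infer_boundaries()]), classifies the
#' genes (non-strict: a pseudoautosomal gene whose recombinants escaped
#' the finite cross is labelled partially sex-linked), and computes the
#' per-gene diversity statistics on the wild panel. Identical `params`
#' (including the seed) give identical outputs.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Optional directory; when given, writes `genes.tsv`,
#'   `ysnps.tsv`, `evidence.tsv`, `classified.tsv`, `stats.tsv`,
#'   `samples.tsv`, `cross_wild.vcf` and a JSON run `manifest.json`
#'   recording seed, thresholds and per-file checksums.
#' @param min_complete_sons,min_complete_daughters Passed to
#'   [call_y_snps()].
#' @return List with `records`, `ysnps`, `evidence`, `anchors`,
#'   `classified`, `stats`, `summary`.
#' @export
run_xy_pipeline <- function(params, out_dir = NULL,
                            min_complete_sons = 15L,
                            min_complete_daughters = 24L) {
  sim <- simulate_dataset(params)
  ysnps <- lapply(sim$matrices, call_y_snps,
                  min_complete_sons = min_complete_sons,
                  min_complete_daughters = min_complete_daughters)
  evidence <- do.call(rbind, Map(scan_females, ysnps, sim$matrices))
  anchors <- infer_boundaries(sim$records, evidence)
  classified <- classify_genes(sim$records, evidence, anchors, strict = FALSE)
  stats <- diversity_scan(sim$matrices)
  out <- list(
    records = sim$records,
    ysnps = do.call(rbind, ysnps),
    evidence = evidence,
    anchors = anchors,
    classified = classified,
    stats = stats,
    summary = summarize_classification(classified)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_gene_map(sim$records, p("genes.tsv"))
    utils::write.table(out$ysnps, p("ysnps.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(evidence, p("evidence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(classified, p("classified.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(stats, p("stats.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_sample_metadata(sim$matrices[[1]]$individuals, p("samples.tsv"))
    write_vcf(sim$matrices, p("cross_wild.vcf"))
    files <- c("genes.tsv", "ysnps.tsv", "evidence.tsv", "classified.tsv",
               "stats.tsv", "samples.tsv", "cross_wild.vcf")
    manifest <- list(
      seed = params$seed,
      n_genes = params$n_genes,
      thresholds = list(min_complete_sons = min_complete_sons,
                        min_complete_daughters = min_complete_daughters),
      anchors = unclass(anchors),
      checksums = as.list(tools::md5sum(file.path(out_dir, files)))
    )
    names(manifest$checksums) <- files
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               p("manifest.json"))
  }
  out
}

#' Replicate the published tables from the packaged fixtures
#'
#' Runs the anchor-based classifier and summariser on the packaged gene
#' panel, and the marker-map integration on homology hits reconstructed
#' from the packaged correspondence table. This is the paper-replication
#' mode: the anchors are the published ones, and the outputs are the
#' whole-table counts.
#'
#' @param anchors A [boundary_calls()] object (published defaults).
#' @return List with `classified` (per-gene categories), `gene_summary`
#'   (counts: total genes, genes analyzed proximal to the PAR, genes with
#'   Y-SNPs, genes with Y alleles in wild females, fuzzy genes),
#'   `integration` (per-marker matches) and `marker_summary` (counts of
#'   same-gene, scaffold-colocated and total matched markers).
#' @export
replicate_tables <- function(anchors = boundary_calls()) {
  t3 <- load_table3_fixture()
  records <- data.frame(gene_id = t3$gene_id, map_cM = t3$map_cM,
                        cross_status = t3$cross_status,
                        stringsAsFactors = FALSE)
  evidence <- t3[, c("gene_id", "y_snps_analyzed", "y_snps_in_females",
                     "n_females_with_y")]
  classified <- classify_genes(records, evidence, anchors)
  gene_summary <- summarize_classification(classified)

  syn <- synthesize_table2_hits()
  integration <- integrate_maps(
    syn$map_a, syn$map_b,
    direct_hits = filter_hits(syn$direct),
    scaffold_hits_a = filter_hits(syn$scaffold_a),
    scaffold_hits_b = filter_hits(syn$scaffold_b)
  )
  marker_summary <- list(
    n_same_gene = sum(integration$match_type == "same-gene"),
    n_scaffold_colocated = sum(integration$match_type == "scaffold-colocated"),
    n_matched = sum(integration$match_type != "none")
  )
  list(
    classified = classified,
    gene_summary = gene_summary,
    integration = integration,
    marker_summary = marker_summary
  )
}
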