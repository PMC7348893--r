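# Packaged fixtures: the wild sample panel, the cross-study marker
# correspondence table, and the gene panel spanning the PAR boundary, as
# published. Loading is pure (no network, no environment dependence) and
# the files are checksum-pinned.

fixture_md5 <- c(
  table1_wild_panel.tsv = "6923524f01687a675b2c19c737ae81eb",
  table2_marker_correspondence.tsv = "e641bd54a4f781a738a778802501be1e",
  table3_gene_panel.tsv = "068a83b43e4bd541347e3fb9f39aa6f0"
)

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "parboundary")
  if (path == "") stop("fixture not found: ", name)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(fixture_md5[[name]]))) {
    stop("fixture corrupted (checksum mismatch): ", name)
  }
  path
}

#' Load the wild sample panel fixture
#'
#' The eight wild individuals (3 males, 5 females) whose transcriptomes
#' provide the population sample of the study design.
#'
#' @return Data frame with `sample_id`, `sex`, `country`, `location`.
#' @export
load_table1_fixture <- function() {
  utils::read.delim(fixture_path("table1_wild_panel.tsv"),
                    stringsAsFactors = FALSE)
}

#' Load the cross-study marker correspondence fixture
#'
#' The 32 markers of the reference X-chromosome map and their
#' counterparts in the denser map: `same-gene` rows are identical genes
#' recovered in both maps, `scaffold-colocated` rows are distinct genes
#' whose sequences land on the same genomic scaffold, `none` rows have no
#' counterpart.
#'
#' @return Data frame with `marker_a`, `map_a_cM`, `status_a`,
#'   `marker_b`, `map_b_cM`, `status_b`, `match_type`.
#' @export
load_table2_fixture <- function() {
  t2 <- utils::read.delim(fixture_path("table2_marker_correspondence.tsv"),
                          stringsAsFactors = FALSE)
  stopifnot(nrow(t2) == 32)
  t2
}

#' Load the PAR-boundary gene panel fixture
#'
#' The 86 genes between the fully sex-linked anchor (62.6 cM) and the
#' distal pseudoautosomal anchor (72.1 cM): 50 individually named genes
#' plus 36 unnamed pseudoautosomal genes that the source table reports
#' only in aggregate. The aggregate is expanded here into 36 synthetic
#' placeholder records (`par_gene_01` ...) with `cross_status = "PAR"`,
#' `region_label = "PAR"` and map positions evenly interpolated between
#' 64.8 and 72.1 cM, so whole-table counts are computable; placeholder
#' rows carry `placeholder = TRUE`. Genes whose downstream Y-SNP columns
#' are not reported (zero analyzed Y-SNPs) have `NA` there, not zero.
#'
#' @return Data frame with `gene_id`, `map_cM`, `cross_status`
#'   (`"X"`/`"PAR"`: segregation in the cross), `region_label` (`"X"`,
#'   `"fuzzy-I"`, `"fuzzy-II"`, `"PAR"`: the published region call),
#'   `y_snps_analyzed`, `y_snps_in_females`, `n_females_with_y`,
#'   `placeholder`; 86 rows, source ordering preserved.
#' @export
load_table3_fixture <- function() {
  t3 <- utils::read.delim(fixture_path("table3_gene_panel.tsv"),
                          stringsAsFactors = FALSE)
  t3$placeholder <- FALSE
  par_maps <- seq(64.8, 72.1, length.out = 38)
  expansion <- data.frame(
    gene_id = sprintf("par_gene_%02d", 1:36),
    map_cM = round(par_maps[2:37], 3),
    cross_status = "PAR",
    region_label = "PAR",
    y_snps_analyzed = 0L,
    y_snps_in_females = NA_integer_,
    n_females_with_y = NA_integer_,
    placeholder = TRUE,
    stringsAsFactors = FALSE
  )
  i <- match("Contig16617", t3$gene_id)
  out <- rbind(t3[seq_len(i), ], expansion, t3[(i + 1):nrow(t3), ])
  rownames(out) <- NULL
  stopifnot(nrow(out) == 86)
  out
}

#' Synthesise homology hit tables consistent with the marker fixture
#'
#' Reconstructs, deterministically, a set of direct and genome-scaffold
#' homology hits that encode the matches of the packaged marker
#' correspondence table: reciprocal high-identity direct hits for
#' `same-gene` pairs, shared-scaffold hits for `scaffold-colocated`
#' pairs, and sub-threshold decoy hits for a few unmatched markers (so
#' that the stringency filter does real work). Running [filter_hits()]
#' and [integrate_maps()] on these tables reproduces the fixture's match
#' structure.
#'
#' @param t2 The fixture from [load_table2_fixture()].
#' @return List with `direct`, `scaffold_a`, `scaffold_b` hit data
#'   frames and the two marker maps `map_a`, `map_b`.
#' @export
synthesize_table2_hits <- function(t2 = load_table2_fixture()) {
  hit <- function(q, s, pident, evalue, bitscore) {
    data.frame(qseqid = q, sseqid = s, pident = pident, length = 500L,
               mismatch = round(500 * (100 - pident) / 100), gapopen = 0L,
               qstart = 1L, qend = 500L, sstart = 1L, send = 500L,
               evalue = evalue, bitscore = bitscore,
               stringsAsFactors = FALSE)
  }
  direct <- list()
  scaf_a <- list()
  scaf_b <- list()
  for (i in seq_len(nrow(t2))) {
    a <- t2$marker_a[i]
    b <- t2$marker_b[i]
    type <- t2$match_type[i]
    bs <- 1500 - i
    if (type == "same-gene") {
      direct[[length(direct) + 1]] <- hit(a, b, 99.8, 1e-150, bs)
      direct[[length(direct) + 1]] <- hit(b, a, 99.8, 1e-150, bs)
      # a genuine gene also sits on a scaffold; same-gene must win
      scaf <- sprintf("scaffold_%03d", i)
      scaf_a[[length(scaf_a) + 1]] <- hit(a, scaf, 99.5, 1e-120, bs)
      scaf_b[[length(scaf_b) + 1]] <- hit(b, scaf, 99.5, 1e-120, bs)
    } else if (type == "scaffold-colocated") {
      scaf <- sprintf("scaffold_%03d", i)
      scaf_a[[length(scaf_a) + 1]] <- hit(a, scaf, 99.0, 1e-110, bs)
      scaf_b[[length(scaf_b) + 1]] <- hit(b, scaf, 99.0, 1e-110, bs)
      # sub-threshold direct cross-hit: filtered out before integration
      direct[[length(direct) + 1]] <- hit(a, b, 95.0, 1e-90, bs / 2)
    } else if (i %% 3 == 0) {
      # decoys for unmatched markers: fail identity or significance
      direct[[length(direct) + 1]] <-
        hit(a, t2$marker_b[which(t2$match_type == "same-gene")[1]],
            96.0, 1e-100, 400)
      scaf_a[[length(scaf_a) + 1]] <-
        hit(a, sprintf("scaffold_decoy_%03d", i), 99.9, 1e-20, 300)
    }
  }
  map_b_rows <- !is.na(t2$marker_b)
  list(
    direct = do.call(rbind, direct),
    scaffold_a = do.call(rbind, scaf_a),
    scaffold_b = do.call(rbind, scaf_b),
    map_a = data.frame(marker = t2$marker_a, map_cM = t2$map_a_cM,
                       status = t2$status_a, stringsAsFactors = FALSE),
    map_b = data.frame(marker = t2$marker_b[map_b_rows],
                       map_cM = t2$map_b_cM[map_b_rows],
                       status = t2$status_b[map_b_rows],
                       stringsAsFactors = FALSE)
  )
}
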