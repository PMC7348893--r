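# Cross-study genetic-map integration from homology-search hit tables.

#' Filter homology hits at stringent thresholds
#'
#' Keeps hits with `evalue < max_e` and `pident > min_ident` (both bounds
#' strict). Defaults are the stringent settings used to match markers
#' between maps: e-value below 1e-80 and identity above 97.5%.
#'
#' @param hits Data frame in 12-column tabular homology format (columns
#'   `qseqid`, `sseqid`, `pident`, `length`, `mismatch`, `gapopen`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`); see
#'   [read_homology_hits()].
#' @param max_e Strict upper bound on e-value.
#' @param min_ident Strict lower bound on percent identity.
#' @return The surviving rows (set semantics: idempotent, order-free).
#' @export
filter_hits <- function(hits, max_e = 1e-80, min_ident = 97.5) {
  keep <- hits$evalue < max_e & hits$pident > min_ident
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best partner per query: highest bitscore, then lowest evalue, then
# lexicographic subject id
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Integrate two genetic maps through homology hits
#'
#' Matches each marker of map A to at most one marker of map B:
#' \itemize{
#'   \item `same-gene`: a direct hit from A to B that survives filtering
#'     and is reciprocated by a B-to-A hit (reciprocity guards against
#'     paralog chaining); the best reciprocal partner is taken (highest
#'     bitscore, then lowest e-value, then lexicographic subject id).
#'   \item `scaffold-colocated`: no direct match, but the best
#'     genome-scaffold hits of the A marker and of a B marker land on the
#'     same scaffold.
#'   \item `none`: otherwise.
#' }
#'
#' @param map_a,map_b Data frames with columns `marker`, `map_cM`,
#'   `status` (`"X"`/`"PAR"`); output rows follow `map_a` order.
#' @param direct_hits Pre-filtered direct hits (both directions may be in
#'   one table; queries from A with subjects in B and vice versa).
#' @param scaffold_hits_a,scaffold_hits_b Pre-filtered hits of each map's
#'   markers against genome scaffolds.
#' @return Data frame with one row per `map_a` marker: `marker_a`,
#'   `map_a_cM`, `status_a`, `marker_b`, `map_b_cM`, `status_b`,
#'   `match_type`.
#' @export
integrate_maps <- function(map_a, map_b, direct_hits = NULL,
                           scaffold_hits_a = NULL, scaffold_hits_b = NULL) {
  stopifnot(all(c("marker", "map_cM", "status") %in% names(map_a)),
            all(c("marker", "map_cM", "status") %in% names(map_b)))
  empty <- data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE)
  direct_hits <- direct_hits %||% empty
  scaffold_hits_a <- scaffold_hits_a %||% empty
  scaffold_hits_b <- scaffold_hits_b %||% empty

  ab <- direct_hits[direct_hits$qseqid %in% map_a$marker &
                      direct_hits$sseqid %in% map_b$marker, , drop = FALSE]
  ba <- direct_hits[direct_hits$qseqid %in% map_b$marker &
                      direct_hits$sseqid %in% map_a$marker, , drop = FALSE]
  # keep only reciprocated A->B hits, then pick the best partner
  recip <- paste(ab$sseqid, ab$qseqid) %in% paste(ba$qseqid, ba$sseqid)
  best_direct <- best_hits(ab[recip, , drop = FALSE])

  best_scaf_a <- best_hits(scaffold_hits_a)
  best_scaf_b <- best_hits(scaffold_hits_b)

  rows <- lapply(seq_len(nrow(map_a)), function(i) {
    a <- map_a$marker[i]
    partner <- NA_character_
    type <- "none"
    j <- match(a, best_direct$qseqid)
    if (!is.na(j)) {
      partner <- best_direct$sseqid[j]
      type <- "same-gene"
    } else {
      k <- match(a, best_scaf_a$qseqid)
      if (!is.na(k)) {
        scaf <- best_scaf_a$sseqid[k]
        cand <- best_scaf_b[best_scaf_b$sseqid == scaf, , drop = FALSE]
        if (nrow(cand)) {
          o <- order(-cand$bitscore, cand$evalue, cand$qseqid)
          partner <- cand$qseqid[o[1]]
          type <- "scaffold-colocated"
        }
      }
    }
    jb <- match(partner, map_b$marker)
    data.frame(
      marker_a = a, map_a_cM = map_a$map_cM[i], status_a = map_a$status[i],
      marker_b = partner,
      map_b_cM = if (is.na(jb)) NA_real_ else map_b$map_cM[jb],
      status_b = if (is.na(jb)) NA_character_ else map_b$status[jb],
      match_type = type,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
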