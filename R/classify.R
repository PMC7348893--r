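# Gene classification into sex-linkage categories and boundary inference.

#' Boundary anchors for gene classification
#'
#' Three cM positions partition the gene order: genes at or proximal to
#' `last_fully_X_cM` are fully sex-linked (`"X"`); genes between there and
#' `fuzzy_split_cM` (inclusive) form the proximal fuzzy zone (`"fuzzy-I"`,
#' zero or one Y alleles seen in wild females); genes between
#' `fuzzy_split_cM` and `first_PAR_cM` form the distal fuzzy zone
#' (`"fuzzy-II"`, multiple Y alleles in several females); genes that
#' recombine in the cross are pseudoautosomal (`"PAR"`). The defaults
#' (62.6, 63.0, 64.8 cM) are the anchor positions of the study map the
#' packaged gene table comes from.
#'
#' @param last_fully_X_cM,fuzzy_split_cM,first_PAR_cM Anchor positions in
#'   cM, non-decreasing.
#' @return An object of class `boundary_calls`.
#' @export
boundary_calls <- function(last_fully_X_cM = 62.6, fuzzy_split_cM = 63.0,
                           first_PAR_cM = 64.8) {
  if (!(last_fully_X_cM <= fuzzy_split_cM && fuzzy_split_cM <= first_PAR_cM)) {
    stop("anchors must satisfy last_fully_X <= fuzzy_split <= first_PAR")
  }
  structure(
    list(last_fully_X_cM = last_fully_X_cM,
         fuzzy_split_cM = fuzzy_split_cM,
         first_PAR_cM = first_PAR_cM),
    class = "boundary_calls"
  )
}

#' Classify genes into sex-linkage categories
#'
#' Anchor-based classification: genes with `cross_status == "PAR"` are
#' `"PAR"`; sex-linked genes (`cross_status == "X"`) are `"X"`,
#' `"fuzzy-I"` or `"fuzzy-II"` by map position relative to the anchors
#' (a gene sharing a cM position with an anchor is assigned to the
#' anchor's proximal side).
#'
#' @param records Data frame with columns `gene_id`, `map_cM`,
#'   `cross_status` (`"X"`/`"PAR"`).
#' @param evidence Optional data frame of per-gene wild evidence (from
#'   [scan_females()] rows); merged into the result by `gene_id`.
#' @param anchors A [boundary_calls()] object.
#' @param strict If `TRUE` (default), a sex-linked gene mapping distally
#'   to `first_PAR_cM` is an error (inconsistent input). If `FALSE`, such
#'   genes -- e.g. pseudoautosomal genes whose recombinants escaped a
#'   finite cross -- are assigned `"fuzzy-II"` (partially sex-linked is
#'   the strongest statement their data support).
#' @return Data frame with `gene_id`, `map_cM`, `cross_status`,
#'   `category`, plus evidence columns where supplied.
#' @export
classify_genes <- function(records, evidence = NULL,
                           anchors = boundary_calls(), strict = TRUE) {
  stopifnot(inherits(anchors, "boundary_calls"),
            all(c("gene_id", "map_cM", "cross_status") %in% names(records)))
  x_genes <- records$cross_status == "X"
  beyond <- x_genes & records$map_cM > anchors$first_PAR_cM
  if (strict && any(beyond)) {
    stop("sex-linked gene(s) mapping beyond first_PAR_cM: ",
         paste(records$gene_id[beyond], collapse = ", "))
  }
  category <- ifelse(
    !x_genes, "PAR",
    ifelse(records$map_cM <= anchors$last_fully_X_cM, "X",
      ifelse(records$map_cM <= anchors$fuzzy_split_cM, "fuzzy-I", "fuzzy-II"))
  )
  out <- data.frame(
    gene_id = records$gene_id,
    map_cM = records$map_cM,
    cross_status = records$cross_status,
    category = category,
    stringsAsFactors = FALSE
  )
  if (!is.null(evidence)) {
    ev_cols <- setdiff(names(evidence), "gene_id")
    out <- merge(out, evidence[, c("gene_id", ev_cols)], by = "gene_id",
                 all.x = TRUE, sort = FALSE)
    out <- out[match(records$gene_id, out$gene_id), ]
    rownames(out) <- NULL
  }
  out
}

#' Infer region boundaries from the data
#'
#' Data-driven counterpart of the fixed anchors, for datasets (such as
#' simulations or new crosses) where no published anchors exist:
#' \itemize{
#'   \item `first_PAR_cM`: map position of the most proximal gene with
#'     `cross_status == "PAR"`;
#'   \item `last_fully_X_cM`: map position of the most distal gene lying
#'     proximal to every gene with Y alleles observed in wild females;
#'   \item `fuzzy_split_cM`: the position that maximises the two-segment
#'     Poisson likelihood of the per-gene female-Y-SNP counts within the
#'     fuzzy zone (two segment means; ties broken to the most proximal
#'     maximiser).
#' }
#'
#' @param records Data frame with `gene_id`, `map_cM`, `cross_status`.
#' @param evidence Data frame with `gene_id` and `y_snps_in_females`; at
#'   least one gene must show female Y evidence.
#' @return A [boundary_calls()] object.
#' @export
infer_boundaries <- function(records, evidence) {
  d <- merge(records, evidence[, c("gene_id", "y_snps_in_females")],
             by = "gene_id", all.x = TRUE, sort = FALSE)
  d$y_snps_in_females[is.na(d$y_snps_in_females)] <- 0L
  d <- d[order(d$map_cM), ]
  par_maps <- d$map_cM[d$cross_status == "PAR"]
  if (!length(par_maps)) stop("no PAR gene present; cannot place first_PAR_cM")
  first_par <- min(par_maps)
  fem <- d$map_cM[d$y_snps_in_females > 0]
  if (!length(fem)) stop("no gene with female Y evidence")
  prox <- d$map_cM[d$map_cM < min(fem)]
  last_x <- if (length(prox)) max(prox) else min(d$map_cM) - 1
  fz <- d[d$cross_status == "X" & d$map_cM > last_x & d$map_cM < first_par, ]
  fuzzy_split <- if (nrow(fz) >= 2) {
    y <- fz$y_snps_in_females
    m <- length(y)
    ll <- vapply(seq_len(m - 1L), function(k) {
      pois_seg_ll(y[seq_len(k)]) + pois_seg_ll(y[(k + 1L):m])
    }, 0)
    fz$map_cM[which.max(ll)]  # which.max takes the first (most proximal) tie
  } else if (nrow(fz) == 1) {
    fz$map_cM[1]
  } else {
    last_x
  }
  boundary_calls(
    last_fully_X_cM = last_x,
    fuzzy_split_cM = min(max(fuzzy_split, last_x), first_par),
    first_PAR_cM = first_par
  )
}

# Poisson log-likelihood of a segment at its MLE mean (constants dropped)
pois_seg_ll <- function(y) {
  lam <- mean(y)
  if (lam == 0) return(0)
  sum(y) * log(lam) - length(y) * lam
}

#' Summarise a gene classification
#'
#' @param results Output of [classify_genes()] (with evidence columns
#'   merged where available).
#' @return A list of counts: `n_genes_total`; `n_analyzed_proximal`
#'   (sex-linked genes proximal to the PAR); `n_with_y_snps` (genes with
#'   at least one Y-SNP identified in the cross); `n_with_female_y`
#'   (genes whose Y alleles appear in wild females); `n_fuzzy` (genes in
#'   either fuzzy category).
#' @export
summarize_classification <- function(results) {
  has <- function(col) if (col %in% names(results)) results[[col]] else NA
  list(
    n_genes_total = nrow(results),
    n_analyzed_proximal = sum(results$category != "PAR"),
    n_with_y_snps = sum(has("y_snps_analyzed") >= 1, na.rm = TRUE),
    n_with_female_y = sum(has("y_snps_in_females") >= 1, na.rm = TRUE),
    n_fuzzy = sum(results$category %in% c("fuzzy-I", "fuzzy-II"))
  )
}
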