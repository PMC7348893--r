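# Scan wild samples for Y-SNP alleles in females.

#' Scan wild females for Y-linked alleles
#'
#' A fully Y-linked allele can never reach a female, so its presence in a
#' wild female is evidence that the gene occasionally recombines in male
#' meiosis. Because a wild sample integrates over many thousands of
#' historical meioses, this scan detects recombination far too rare to be
#' seen in a genetic cross.
#'
#' @param ysnps A `ysnp_table` from [call_y_snps()], restricted to the
#'   gene of `wild`.
#' @param wild A [genotype_matrix()] whose `role == "wild"` individuals
#'   include at least one female.
#' @return A one-row data frame (`wild_evidence`) with columns `gene_id`,
#'   `y_snps_analyzed` (Y-SNPs with a non-missing call in at least one
#'   wild female), `y_snps_in_females` (those whose Y allele appears in at
#'   least one wild female), `n_females_with_y` (distinct carrier
#'   females), and `y_snps_in_wild_males` (QC: Y-SNPs seen in at least
#'   one wild male; expected close to `y_snps_analyzed`).
#' @export
scan_females <- function(ysnps, wild) {
  gm <- wild
  stopifnot(inherits(gm, "genotype_matrix"), inherits(ysnps, "data.frame"))
  if (nrow(ysnps) && !all(ysnps$gene_id == gm$gene_id)) {
    stop("gene mismatch between ysnps (", paste(unique(ysnps$gene_id),
         collapse = ","), ") and wild matrix (", gm$gene_id, ")")
  }
  wf <- gm_which(gm, role = "wild", sex = "female")
  wm <- gm_which(gm, role = "wild", sex = "male")
  if (!length(wf)) stop("wild matrix contains no wild female")

  n_analyzed <- 0L
  n_in_females <- 0L
  n_in_males <- 0L
  carriers <- character(0)
  for (k in seq_len(nrow(ysnps))) {
    s <- match(ysnps$pos[k], gm$positions)
    if (is.na(s)) next  # site absent from the wild callset: not analyzable
    a <- match(ysnps$y_allele[k], gm$alleles[[s]]) - 1L
    f_called <- wf[!is.na(gm$a1[s, wf])]
    if (!length(f_called)) next
    n_analyzed <- n_analyzed + 1L
    if (!is.na(a)) {
      hit_f <- f_called[gm$a1[s, f_called] == a | gm$a2[s, f_called] == a]
      if (length(hit_f)) {
        n_in_females <- n_in_females + 1L
        carriers <- union(carriers, gm$individuals$sample_id[hit_f])
      }
      m_called <- wm[!is.na(gm$a1[s, wm])]
      if (length(m_called) &&
          any(gm$a1[s, m_called] == a | gm$a2[s, m_called] == a)) {
        n_in_males <- n_in_males + 1L
      }
    }
  }
  structure(
    data.frame(
      gene_id = gm$gene_id,
      y_snps_analyzed = n_analyzed,
      y_snps_in_females = n_in_females,
      n_females_with_y = length(carriers),
      y_snps_in_wild_males = n_in_males,
      stringsAsFactors = FALSE
    ),
    class = c("wild_evidence", "data.frame")
  )
}
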