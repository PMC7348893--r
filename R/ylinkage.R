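# Y-SNP identification from segregation in the genetic cross.

#' Call Y-linked SNPs from a genetic cross
#'
#' Identifies Y-linked alleles by their segregation pattern in a
#' father/mother/sons/daughters family: a Y allele rides on the father's Y
#' chromosome, so it is transmitted to every son and to no daughter, and
#' it cannot occur in the mother.
#'
#' An allele `a` at site `s` is emitted as a Y-SNP iff
#' \enumerate{
#'   \item `a` is present in the father's genotype, and the father is
#'     heterozygous at `s` (a father-homozygous allele sits on both his X
#'     and Y, so X/Y phase would be unresolvable);
#'   \item `a` is present in the genotype of every son with a non-missing
#'     call at `s`;
#'   \item `a` is absent from the mother's genotype and from every
#'     daughter's genotype with a non-missing call at `s`;
#'   \item at least `min_complete_sons` sons and `min_complete_daughters`
#'     daughters have non-missing calls at `s` (sites failing this are
#'     skipped, not failed).
#' }
#' At most one allele is emitted per site (the lowest allele index wins in
#' the degenerate case, reachable only through missing data, where two
#' alleles both qualify); multiallelic sites are otherwise evaluated per
#' candidate allele independently.
#'
#' @param matrix A [genotype_matrix()] containing exactly one `father`,
#'   one `mother`, and at least one `son`.
#' @param min_complete_sons,min_complete_daughters Minimum number of
#'   non-missing son/daughter calls required to evaluate a site. Defaults
#'   (15 of 20 sons, 24 of 32 daughters) guard against missing-data
#'   artifacts in the default family design.
#' @return A data frame of class `ysnp_table` with columns `gene_id`,
#'   `pos` (1-based bp), `y_allele` (allele string) and `allele_index`
#'   (0-based VCF allele index), unique by `(gene_id, pos)`, with
#'   attributes `n_sons_used` and `n_daughters_used`.
#' @export
call_y_snps <- function(matrix, min_complete_sons = 15L,
                        min_complete_daughters = 24L) {
  gm <- matrix
  stopifnot(inherits(gm, "genotype_matrix"))
  fa <- gm_which(gm, role = "father")
  mo <- gm_which(gm, role = "mother")
  sons <- gm_which(gm, role = "son")
  dtrs <- gm_which(gm, role = "daughter")
  if (length(fa) != 1) stop("exactly one father required, found ", length(fa))
  if (length(mo) != 1) stop("exactly one mother required, found ", length(mo))
  if (!length(sons)) stop("no sons in the cross")

  hits <- vector("list", length(gm$positions))
  for (s in seq_along(gm$positions)) {
    f1 <- gm$a1[s, fa]; f2 <- gm$a2[s, fa]
    if (is.na(f1) || f1 == f2) next  # father missing or homozygous
    son_called <- !is.na(gm$a1[s, sons])
    dtr_called <- if (length(dtrs)) !is.na(gm$a1[s, dtrs]) else logical(0)
    if (sum(son_called) < min_complete_sons) next
    if (sum(dtr_called) < min_complete_daughters) next
    m1 <- gm$a1[s, mo]; m2 <- gm$a2[s, mo]
    if (is.na(m1)) next  # mother's genotype is part of the criterion
    sc <- sons[son_called]
    dc <- dtrs[dtr_called]
    for (a in c(f1, f2)) {
      if (a == m1 || a == m2) next
      if (!all(gm$a1[s, sc] == a | gm$a2[s, sc] == a)) next
      if (length(dc) && any(gm$a1[s, dc] == a | gm$a2[s, dc] == a)) next
      hits[[s]] <- data.frame(
        gene_id = gm$gene_id,
        pos = gm$positions[s],
        y_allele = gm$alleles[[s]][a + 1L],
        allele_index = a,
        stringsAsFactors = FALSE
      )
      break  # one allele per site
    }
  }
  out <- do.call(rbind, c(hits, list(data.frame(
    gene_id = character(0), pos = integer(0),
    y_allele = character(0), allele_index = integer(0),
    stringsAsFactors = FALSE
  ))))
  rownames(out) <- NULL
  attr(out, "n_sons_used") <- length(sons)
  attr(out, "n_daughters_used") <- length(dtrs)
  class(out) <- c("ysnp_table", "data.frame")
  out
}
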