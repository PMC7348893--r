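# Per-gene diploid genotype container.
#
# Internal representation: two integer matrices `a1`, `a2` (sites x
# individuals) holding 0-based allele indices into the per-site allele list
# (index 0 = the reference allele, matching VCF), normalised so a1 <= a2
# (calls are unordered). A missing call has NA in both matrices; half-missing
# VCF calls are collapsed to fully missing on import.

#' Construct a per-gene genotype matrix
#'
#' Holds the unphased diploid genotypes of a panel of individuals at the
#' SNP sites of one gene, together with each individual's sex and pedigree
#' role. This is the unit of data every stage of the pipeline operates on:
#' Y-SNP calling consumes the cross individuals, the wild-female scan and
#' the diversity statistics consume the wild panel.
#'
#' @param gene_id Character scalar; the gene/contig identifier.
#' @param positions Integer vector of 1-based site positions within the
#'   gene, strictly increasing, all `<= gene_length`.
#' @param alleles List (one element per site) of character vectors of
#'   alleles; element 1 is the reference allele (VCF allele index 0).
#' @param a1,a2 Integer matrices (sites x individuals) of 0-based allele
#'   indices with `a1 <= a2`; `NA` in both marks a missing call.
#' @param individuals Data frame with columns `sample_id`, `sex`
#'   (`"male"`/`"female"`) and `role` (`"father"`, `"mother"`, `"son"`,
#'   `"daughter"` or `"wild"`), one row per column of `a1`.
#' @param gene_length Gene length in bp; the window size used as the
#'   denominator of per-site diversity.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gene_id, positions, alleles, a1, a2, individuals,
                            gene_length) {
  positions <- as.integer(positions)
  n_sites <- length(positions)
  n_ind <- nrow(individuals)
  a1 <- matrix(as.integer(a1), n_sites, n_ind)
  a2 <- matrix(as.integer(a2), n_sites, n_ind)
  if (n_sites > 1 && any(diff(positions) <= 0)) {
    stop("site positions must be strictly increasing")
  }
  if (length(positions) && max(positions) > gene_length) {
    stop("site position exceeds gene_length")
  }
  if (length(alleles) != n_sites) stop("one allele vector per site required")
  stopifnot(all(c("sample_id", "sex", "role") %in% names(individuals)))
  # normalise unordered calls and validate allele indices
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
  }
  n_alleles <- lengths(alleles)
  if (n_sites) {
    amax <- pmax(
      apply(a2, 1, function(x) if (all(is.na(x))) -1L else max(x, na.rm = TRUE)),
      -1L
    )
    if (any(amax > n_alleles - 1L)) {
      stop("call references an allele index not defined for its site")
    }
  }
  structure(
    list(
      gene_id = as.character(gene_id),
      gene_length = as.integer(gene_length),
      positions = positions,
      alleles = alleles,
      a1 = a1, a2 = a2,
      individuals = as.data.frame(individuals, stringsAsFactors = FALSE)
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    sprintf(
      "<genotype_matrix> gene %s: %d sites, %d individuals (%s), length %d bp\n",
      x$gene_id, length(x$positions), nrow(x$individuals),
      paste(sprintf("%d %s", table(x$individuals$role),
                    names(table(x$individuals$role))), collapse = ", "),
      x$gene_length
    )
  )
  invisible(x)
}

# column indices of samples matching role/sex, or sample ids
gm_which <- function(gm, role = NULL, sex = NULL, samples = NULL) {
  keep <- rep(TRUE, nrow(gm$individuals))
  if (!is.null(samples)) keep <- keep & gm$individuals$sample_id %in% samples
  if (!is.null(role)) keep <- keep & gm$individuals$role %in% role
  if (!is.null(sex)) keep <- keep & gm$individuals$sex %in% sex
  which(keep)
}

# Default analysis panel for population statistics: the wild samples when a
# wild panel is present (the cross family is not a population sample),
# otherwise all individuals.
gm_default_panel <- function(gm) {
  w <- gm_which(gm, role = "wild")
  if (length(w)) w else seq_len(nrow(gm$individuals))
}

# allele counts at one site over a set of sample columns; named by 0-based
# allele index, missing calls dropped
site_allele_counts <- function(gm, site, cols) {
  x <- c(gm$a1[site, cols], gm$a2[site, cols])
  x <- x[!is.na(x)]
  if (!length(x)) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}
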