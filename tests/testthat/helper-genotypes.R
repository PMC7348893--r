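# Build small genotype matrices by hand from genotype strings.
#
# `geno` is a character matrix (sites x individuals) of "i/j" 0-based
# allele-index calls ("./." = missing); alleles default to REF/ALT pairs.

make_gm <- function(geno, roles, sexes, positions = NULL, alleles = NULL,
                    gene_id = "geneA", gene_length = 1000L) {
  geno <- as.matrix(geno)
  n_sites <- nrow(geno)
  n_ind <- ncol(geno)
  positions <- positions %||% seq_len(n_sites) * 10L
  alleles <- alleles %||% rep(list(c("A", "T")), n_sites)
  split2 <- function(g, k) {
    v <- suppressWarnings(as.integer(vapply(strsplit(g, "/"), `[`, "", k)))
    v
  }
  a1 <- matrix(split2(geno, 1), n_sites, n_ind)
  a2 <- matrix(split2(geno, 2), n_sites, n_ind)
  genotype_matrix(
    gene_id = gene_id, positions = positions, alleles = alleles,
    a1 = a1, a2 = a2,
    individuals = data.frame(
      sample_id = sprintf("s%02d", seq_len(n_ind)),
      sex = sexes, role = roles, stringsAsFactors = FALSE
    ),
    gene_length = gene_length
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A standard family layout: father, mother, ns sons, nd daughters, then
# optional wild males/females.
family_layout <- function(ns, nd, nwm = 0, nwf = 0) {
  list(
    roles = c("father", "mother", rep("son", ns), rep("daughter", nd),
              rep("wild", nwm + nwf)),
    sexes = c("male", "female", rep("male", ns), rep("female", nd),
              rep("male", nwm), rep("female", nwf))
  )
}

# Rebuild a genotype_matrix with its individuals (columns) permuted.
permute_individuals <- function(gm, perm) {
  genotype_matrix(
    gene_id = gm$gene_id, positions = gm$positions, alleles = gm$alleles,
    a1 = gm$a1[, perm, drop = FALSE], a2 = gm$a2[, perm, drop = FALSE],
    individuals = gm$individuals[perm, ], gene_length = gm$gene_length
  )
}

# Y-diagnostic truth of a simulated gene
sim_truth <- function(gm) attr(gm, "truth")
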