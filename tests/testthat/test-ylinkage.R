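# Independent brute-force evaluation of the segregation criterion, written
# directly from its definition: for each site and each allele of a
# heterozygous father, check presence in every called son, absence from the
# mother and every called daughter, and the completeness thresholds.
oracle_y_snps <- function(gm, min_sons, min_dtrs) {
  ind <- gm$individuals
  fa <- which(ind$role == "father")
  mo <- which(ind$role == "mother")
  out <- NULL
  for (s in seq_along(gm$positions)) {
    for (a in 0:(length(gm$alleles[[s]]) - 1L)) {
      geno_of <- function(j) c(gm$a1[s, j], gm$a2[s, j])
      f <- geno_of(fa)
      if (anyNA(f) || !(a %in% f) || f[1] == f[2]) next
      m <- geno_of(mo)
      if (anyNA(m) || a %in% m) next
      ok <- TRUE
      n_sons <- 0L
      n_dtrs <- 0L
      for (j in seq_len(nrow(ind))) {
        g <- geno_of(j)
        if (anyNA(g)) next
        if (ind$role[j] == "son") {
          n_sons <- n_sons + 1L
          if (!(a %in% g)) ok <- FALSE
        }
        if (ind$role[j] == "daughter") {
          n_dtrs <- n_dtrs + 1L
          if (a %in% g) ok <- FALSE
        }
      }
      if (ok && n_sons >= min_sons && n_dtrs >= min_dtrs) {
        out <- rbind(out, data.frame(pos = gm$positions[s], allele = a))
        break
      }
    }
  }
  out
}

test_that("the canonical segregation pattern yields exactly one Y-SNP", {
  lay <- family_layout(20, 32)
  # father G/T, mother G/G, all sons G/T, all daughters G/G
  geno <- matrix(c("0/1", "0/0", rep("0/1", 20), rep("0/0", 32)), nrow = 1)
  gm <- make_gm(geno, lay$roles, lay$sexes, alleles = list(c("G", "T")))
  ys <- call_y_snps(gm, min_complete_sons = 15, min_complete_daughters = 24)
  expect_equal(nrow(ys), 1)
  expect_equal(ys$y_allele, "T")
  orc <- oracle_y_snps(gm, 15, 24)
  expect_equal(ys$pos, orc$pos)
  expect_equal(ys$allele_index, orc$allele)
})

test_that("one discordant son, a carrier daughter, or a homozygous father rejects the site", {
  lay <- family_layout(20, 32)
  base <- c("0/1", "0/0", rep("0/1", 20), rep("0/0", 32))
  g_son <- base; g_son[3] <- "0/0"            # one son without the allele
  g_dtr <- base; g_dtr[25] <- "0/1"           # one daughter carrying it
  g_hom <- base; g_hom[1] <- "1/1"            # father homozygous
  for (g in list(g_son, g_dtr, g_hom)) {
    gm <- make_gm(matrix(g, nrow = 1), lay$roles, lay$sexes)
    expect_equal(nrow(call_y_snps(gm, 15, 24)), 0)
  }
})

test_that("monomorphic matrices yield an empty table", {
  lay <- family_layout(5, 5)
  gm <- make_gm(matrix("0/0", 3, 12), lay$roles, lay$sexes)
  expect_equal(nrow(call_y_snps(gm, 3, 3)), 0)
})

test_that("sites below the completeness thresholds are skipped, not failed", {
  lay <- family_layout(20, 32)
  g <- c("0/1", "0/0", rep("0/1", 20), rep("0/0", 32))
  g[3:12] <- "./."  # only 10 called sons
  gm <- make_gm(matrix(g, nrow = 1), lay$roles, lay$sexes)
  expect_equal(nrow(call_y_snps(gm, 15, 24)), 0)
  expect_equal(nrow(call_y_snps(gm, 10, 24)), 1)
})

test_that("calls agree with the brute-force oracle on randomised families", {
  lay <- family_layout(8, 8)
  set.seed(71)
  for (rep in 1:25) {
    geno <- matrix(sprintf("%d/%d", sample(0:1, 6 * 18, TRUE),
                           sample(0:1, 6 * 18, TRUE)), 6, 18)
    geno[stats::runif(length(geno)) < 0.1] <- "./."
    gm <- make_gm(geno, lay$roles, lay$sexes)
    ys <- call_y_snps(gm, min_complete_sons = 5, min_complete_daughters = 5)
    orc <- oracle_y_snps(gm, 5, 5)
    expect_equal(ys$pos, if (is.null(orc)) integer(0) else orc$pos)
    expect_equal(ys$allele_index,
                 if (is.null(orc)) integer(0) else orc$allele)
  }
})

test_that("simulated NRY genes recover exactly the Y-diagnostic site set", {
  p <- sim_params(region_labels = rep("NRY", 10), seed = 23)
  for (g in 1:10) {
    gm <- simulate_gene(p, g)
    ys <- call_y_snps(gm)
    expect_setequal(ys$pos, sim_truth(gm)$diagnostic_pos)
    # the Y allele is always the derived diagnostic allele, never seen in
    # the mother
    mo <- which(gm$individuals$role == "mother")
    for (k in seq_len(nrow(ys))) {
      s <- match(ys$pos[k], gm$positions)
      expect_false(ys$allele_index[k] %in% c(gm$a1[s, mo], gm$a2[s, mo]))
    }
  }
})

test_that("emission is monotone in evidence", {
  p <- sim_params(region_labels = "NRY", seed = 31)
  gm <- simulate_gene(p, 1)
  ys <- call_y_snps(gm)
  expect_gt(nrow(ys), 0)
  # dropping a son can only grow or preserve the emitted set
  keep <- gm$individuals$role != "son" |
    gm$individuals$sample_id != "son_01"
  gm_less <- permute_individuals(gm, which(keep))
  ys_less <- call_y_snps(gm_less, min_complete_sons = 15L)
  expect_true(all(ys$pos %in% ys_less$pos))
  # adding a daughter that carries the Y allele shrinks the set
  hit <- match(ys$pos[1], gm$positions)
  new_a1 <- cbind(gm$a1, gm$a1[, 2])
  new_a2 <- cbind(gm$a2, gm$a2[, 2])
  new_a2[hit, ncol(new_a2)] <- ys$allele_index[1]
  gm_plus <- genotype_matrix(gm$gene_id, gm$positions, gm$alleles,
                             new_a1, new_a2,
                             rbind(gm$individuals,
                                   data.frame(sample_id = "daughter_x",
                                              sex = "female",
                                              role = "daughter")),
                             gm$gene_length)
  ys_plus <- call_y_snps(gm_plus)
  expect_true(all(ys_plus$pos %in% ys$pos))
  expect_false(ys$pos[1] %in% ys_plus$pos)
})

test_that("pedigree structure is validated", {
  lay <- family_layout(3, 3)
  gm <- make_gm(matrix("0/0", 1, 8), lay$roles, lay$sexes)
  no_father <- permute_individuals(gm, 2:8)
  expect_error(call_y_snps(no_father), "father")
  no_sons <- permute_individuals(gm, c(1, 2, 6, 7, 8))
  expect_error(call_y_snps(no_sons), "son")
})
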