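test_that("NRY genes transmit every Y-diagnostic allele to all sons and to no female", {
  p <- sim_params(region_labels = rep("NRY", 3), d_xy = c(NRY = 8, FUZZY = 0, PAR = 0),
                  seed = 11)
  for (g in 1:3) {
    gm <- simulate_gene(p, g)
    tr <- sim_truth(gm)
    rows <- match(tr$diagnostic_pos, gm$positions)
    sons <- which(gm$individuals$role == "son")
    fem <- which(gm$individuals$sex == "female")
    for (s in rows) {
      expect_true(all(gm$a1[s, sons] == 1L | gm$a2[s, sons] == 1L))
      expect_false(any(gm$a1[s, fem] == 1L | gm$a2[s, fem] == 1L))
    }
  }
})

test_that("a divergence-free, mutation-free gene is monomorphic and yields no Y-SNPs", {
  p <- sim_params(region_labels = "NRY", theta = 1e-9,
                  d_xy = c(NRY = 0, FUZZY = 0, PAR = 0), seed = 2)
  gm <- simulate_gene(p, 1)
  expect_length(gm$positions, 0)
  expect_equal(nrow(call_y_snps(gm)), 0)
})

test_that("identical parameters give bit-identical datasets", {
  p <- sim_params(region_labels = rep(c("NRY", "FUZZY", "PAR"), c(3, 3, 3)),
                  seed = 42)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$matrices, d2$matrices)
})

test_that("wild-female leak events match the binomial expectation", {
  # leak_prob 0.1 at ~10 diagnostic sites over 10 female X copies:
  # E[events] = 0.1 * E[n_sites] * 10 = 10
  p <- sim_params(region_labels = "FUZZY",
                  d_xy = c(NRY = 0, FUZZY = 10, PAR = 0),
                  leak_prob = c(NRY = 0, FUZZY = 0.1, PAR = 0),
                  male_recomb_fuzzy = 0, seed = 5)
  events <- vapply(seq_len(600), function(r) {
    gm <- simulate_gene(p, 1, seed = 1000 + r)
    tr <- sim_truth(gm)
    rows <- match(tr$diagnostic_pos, gm$positions)
    wf <- which(gm$individuals$role == "wild" & gm$individuals$sex == "female")
    sum(gm$a1[rows, wf] == 1L) + sum(gm$a2[rows, wf] == 1L)
  }, 0)
  expect_equal(mean(events), 10, tolerance = 0.08)
})

test_that("children carry only alleles present in a parent (no de-novo mutation)", {
  p <- sim_params(region_labels = rep(c("NRY", "FUZZY", "PAR"), c(2, 2, 2)),
                  seed = 9)
  sim <- simulate_dataset(p)
  for (gm in sim$matrices) {
    fa <- which(gm$individuals$role == "father")
    mo <- which(gm$individuals$role == "mother")
    kids <- which(gm$individuals$role %in% c("son", "daughter"))
    for (s in seq_along(gm$positions)) {
      parental <- unique(c(gm$a1[s, c(fa, mo)], gm$a2[s, c(fa, mo)]))
      expect_true(all(c(gm$a1[s, kids], gm$a2[s, kids]) %in% parental))
    }
  }
})

test_that("expected female leak burden is non-decreasing in leak_prob", {
  mean_events <- vapply(c(0.01, 0.05, 0.2), function(lp) {
    p <- sim_params(region_labels = "FUZZY",
                    d_xy = c(NRY = 0, FUZZY = 10, PAR = 0),
                    leak_prob = c(NRY = 0, FUZZY = lp, PAR = 0),
                    male_recomb_fuzzy = 0, seed = 1)
    mean(vapply(seq_len(150), function(r) {
      gm <- simulate_gene(p, 1, seed = 5000 + r)
      rows <- match(sim_truth(gm)$diagnostic_pos, gm$positions)
      wf <- which(gm$individuals$role == "wild" &
                    gm$individuals$sex == "female")
      sum(gm$a1[rows, wf] == 1L) + sum(gm$a2[rows, wf] == 1L)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_events) > 0))
})

test_that("the default design yields the 86-gene study layout", {
  p <- sim_params(seed = 1)
  sim <- simulate_dataset(p)
  expect_equal(nrow(sim$records), 86)
  expect_equal(as.vector(table(factor(sim$records$true_region,
                                      c("NRY", "FUZZY", "PAR")))),
               c(28, 20, 38))
  # NRY genes can never look recombinant in the cross
  expect_true(all(sim$records$cross_status[sim$records$true_region == "NRY"] == "X"))
  # panel composition: 2 parents + 52 progeny + 8 wild
  roles <- table(sim$matrices[[1]]$individuals$role)
  expect_equal(unname(roles[c("son", "daughter", "wild")]),
               c(20L, 32L, 8L), ignore_attr = TRUE)
})

test_that("unlinked pseudoautosomal genes are almost always detected as recombining", {
  p <- sim_params(region_labels = rep("PAR", 40), par_recomb = 0.5, seed = 8)
  sim <- simulate_dataset(p)
  # per gene: detected unless no recombinant among 52 meioses (2^-52) or
  # the father's homologs are identical at every site
  expect_gte(mean(sim$records$cross_status == "PAR"), 0.8)
})

test_that("invalid designs and indices are rejected", {
  expect_error(sim_params(region_labels = c("PAR", "NRY")), "contiguous")
  expect_error(sim_params(leak_prob = c(NRY = 0.1, FUZZY = 0.1, PAR = 0)),
               "NRY")
  expect_error(sim_params(d_xy = c(NRY = 5, FUZZY = 5, PAR = 2)), "PAR")
  p <- sim_params(region_labels = "NRY", seed = 1)
  expect_error(simulate_gene(p, 2), "unknown gene_index")
})
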