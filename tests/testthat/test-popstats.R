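wild8 <- function(geno, ...) {
  make_gm(geno, roles = rep("wild", 8),
          sexes = c(rep("male", 3), rep("female", 5)), ...)
}

test_that("pi matches hand values and the all-pairs brute force", {
  gm <- wild8(matrix("0/0", 4, 8))
  expect_equal(nucleotide_diversity(gm, "male"), 0)
  # 4 chromosomes, one SNP at frequency 2/4, window 100 bp
  g2 <- make_gm(matrix(c("0/1", "0/1", "0/0", "0/0", "0/0"), 1, 5),
                roles = rep("wild", 5),
                sexes = c("female", "female", "male", "male", "male"),
                gene_length = 100L)
  expect_equal(nucleotide_diversity(g2, "female"), (2 * 2 / 6) / 100)
  p <- sim_params(region_labels = c("NRY", "FUZZY", "PAR"),
                  missing_rate = 0.05, seed = 41)
  for (g in 1:3) {
    gm <- simulate_gene(p, g)
    for (sex in c("male", "female")) {
      cols <- intersect(which(gm$individuals$role == "wild"),
                        which(gm$individuals$sex == sex))
      expect_equal(nucleotide_diversity(gm, sex),
                   brute_pi(gm, cols, gm$gene_length), tolerance = 1e-12)
    }
  }
})

test_that("gametolog divergence inflates male but not female diversity", {
  p <- sim_params(region_labels = "NRY",
                  d_xy = c(NRY = 10, FUZZY = 0, PAR = 0), seed = 2)
  wins <- vapply(seq_len(100), function(r) {
    gm <- simulate_gene(p, 1, seed = 30000 + r)
    nucleotide_diversity(gm, "male") > nucleotide_diversity(gm, "female")
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("between-sex theta is 0 without differentiation and 1 at a fixed difference", {
  # same allele-frequency process in both sexes, 50 diploids per sex
  set.seed(6)
  n <- 100
  geno <- matrix("0/0", 300, n)
  for (s in 1:300) {
    p0 <- stats::runif(1, 0.1, 0.9)
    draws <- matrix(stats::rbinom(2 * n, 1, p0), 2, n)
    geno[s, ] <- sprintf("%d/%d", draws[1, ], draws[2, ])
  }
  gm <- make_gm(geno, roles = rep("wild", n),
                sexes = rep(c("male", "female"), each = n / 2),
                gene_length = 3000L)
  expect_lt(abs(fst_weir_cockerham(gm)), 0.02)
  fixed <- make_gm(matrix(c(rep("0/0", 4), rep("1/1", 4)), 1, 8),
                   roles = rep("wild", 8),
                   sexes = rep(c("male", "female"), each = 4))
  expect_identical(fst_weir_cockerham(fixed), 1)
})

test_that("theta equals the independent variance-component evaluation", {
  set.seed(8)
  for (rep in 1:20) {
    geno <- matrix(sprintf("%d/%d", sample(0:2, 50, TRUE, c(.5, .4, .1)),
                           sample(0:2, 50, TRUE, c(.5, .4, .1))), 5, 10)
    if (rep %% 3 == 0) geno[stats::runif(50) < 0.15] <- "./."
    gm <- make_gm(geno, roles = rep("wild", 10),
                  sexes = rep(c("male", "female"), each = 5),
                  alleles = rep(list(c("A", "C", "T")), 5))
    males <- 1:5
    females <- 6:10
    expect_equal(fst_weir_cockerham(gm), anova_theta(gm, males, females),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches the constant-by-constant oracle and is absent for S = 0", {
  mono <- wild8(matrix("0/0", 3, 8))
  expect_true(is.na(tajimas_d(mono)))
  # n = 4 chromosomes, one singleton
  g4 <- make_gm(matrix(c("0/1", "0/0"), 1, 2), roles = rep("wild", 2),
                sexes = c("male", "female"))
  expect_equal(tajimas_d(g4), oracle_tajima(g4, 1:2), tolerance = 1e-14)
  p <- sim_params(region_labels = c("NRY", "FUZZY", "PAR"),
                  missing_rate = 0.05, seed = 43)
  for (g in 1:3) {
    gm <- simulate_gene(p, g)
    cols <- which(gm$individuals$role == "wild")
    expect_equal(tajimas_d(gm), oracle_tajima(gm, cols), tolerance = 1e-12)
  }
  expect_error(tajimas_d(g4, samples = "s01"), ">= 4 chromosomes")
})

test_that("neutral pseudoautosomal genes give near-zero mean D on 16 chromosomes", {
  p <- sim_params(region_labels = "PAR", seed = 3)
  d <- vapply(seq_len(500), function(r) {
    gm <- simulate_gene(p, 1, seed = 40000 + r)
    tajimas_d(gm)
  }, 0)
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.15)
})

test_that("pi comparison reproduces the pooled-variance t-test", {
  same <- data.frame(category = "PAR", pi_males = c(1, 2, 3) / 100,
                     pi_females = c(1, 2, 3) / 100)
  cmp <- compare_pi(same, "PAR")
  expect_equal(cmp$ratio, 1)
  expect_equal(cmp$p_value, 1)
  # closed-form check on two hand vectors
  x <- c(0.010, 0.012, 0.008)
  y <- c(0.004, 0.005, 0.003)
  d <- data.frame(category = "X", pi_males = x, pi_females = y)
  cmp2 <- compare_pi(d, "X")
  sp2 <- (2 * stats::var(x) + 2 * stats::var(y)) / 4
  t_exp <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(cmp2$t_stat, t_exp)
  expect_equal(cmp2$p_value, 2 * stats::pt(-abs(t_exp), 4))
  expect_equal(cmp2$ratio, mean(x) / mean(y))
})

test_that("male diversity excess recovers the tuned expectation on sex-linked genes", {
  # with the Y background folded onto the father's X, male pairs differ at
  # a diagnostic site for the 9 X-Y pairs among C(6,2) = 15, so
  # E[pi_m] ~= (12/15) * theta + (9/15) * d/L and E[pi_f] ~= theta
  d_set <- 18
  theta <- 0.0025
  L <- 1000
  expected_ratio <- ((12 / 15) * theta + (9 / 15) * d_set / L) / theta
  p <- sim_params(region_labels = "NRY", theta = theta,
                  d_xy = c(NRY = d_set, FUZZY = 0, PAR = 0), seed = 4)
  rat <- vapply(seq_len(200), function(r) {
    gm <- simulate_gene(p, 1, seed = 50000 + r)
    c(nucleotide_diversity(gm, "male"), nucleotide_diversity(gm, "female"))
  }, c(0, 0))
  recovered <- mean(rat[1, ]) / mean(rat[2, ])
  expect_equal(recovered, expected_ratio, tolerance = 0.2)
})

test_that("the D-distance regression recovers exact and noisy slopes", {
  pts <- data.frame(category = "PAR", map_cM = c(0, 1, 2),
                    tajimas_d = c(1, 0, -1))
  fit <- regress_d_on_distance(pts, boundary_cM = 0)
  expect_equal(fit$slope, -1)
  expect_equal(fit$intercept, 1)
  expect_lt(fit$p_value, 1e-12)
  # unbiased slope recovery under noise
  set.seed(12)
  slopes <- vapply(seq_len(200), function(r) {
    x <- seq(0, 8, length.out = 20)
    d <- data.frame(category = "PAR", map_cM = x + 64.8,
                    tajimas_d = 0.5 - 0.12 * x + stats::rnorm(20, 0, 0.3))
    regress_d_on_distance(d, 64.8)$slope
  }, 0)
  expect_equal(mean(slopes), -0.12, tolerance = 0.05)
  expect_error(regress_d_on_distance(pts[1:2, ], 0), ">= 3")
})
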