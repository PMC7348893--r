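# Per-gene population-genetic statistics: sex-stratified nucleotide
# diversity, Weir-Cockerham F_ST between the sexes, and Tajima's D.
#
# All statistics count 2N chromosomes per N diploids, including males at
# sex-linked genes, where the X and Y copies are the two "alleles" -- the
# convention of VCF-based tooling, and the reason X-Y gametolog divergence
# shows up as inflated male heterozygosity.

resolve_panel <- function(gm, samples) {
  if (is.null(samples)) gm_default_panel(gm) else gm_which(gm, samples = samples)
}

#' Per-site nucleotide diversity of one sex
#'
#' Computes pi, the average per-site pairwise difference between
#' chromosomes, over the diploid genotypes of one sex:
#' `pi = (1 / gene_length) * sum_sites sum_{i<j} n_i n_j / choose(n, 2)`
#' with `n_i` the count of allele i among the `n = 2N` chromosomes at the
#' site. Sites with any missing call in the group are excluded from the
#' numerator, but the denominator stays at `gene_length` (window
#' convention: the gene is the window).
#'
#' @param matrix A [genotype_matrix()].
#' @param group `"male"` or `"female"`.
#' @param samples Optional sample ids restricting the panel; default is
#'   the wild panel when present, otherwise all individuals.
#' @param gene_length Window length in bp; defaults to the gene's length.
#' @return Per-site diversity (numeric scalar).
#' @export
nucleotide_diversity <- function(matrix, group = c("male", "female"),
                                 samples = NULL, gene_length = NULL) {
  gm <- matrix
  stopifnot(inherits(gm, "genotype_matrix"))
  group <- match.arg(group)
  gene_length <- gene_length %||% gm$gene_length
  if (gene_length <= 0) stop("gene_length must be positive")
  cols <- intersect(resolve_panel(gm, samples), gm_which(gm, sex = group))
  if (length(cols) < 1) stop("group '", group, "' has no individuals")
  n <- 2L * length(cols)
  if (n < 2) stop("need >= 2 chromosomes in the group")
  total <- 0
  for (s in seq_along(gm$positions)) {
    if (anyNA(gm$a1[s, cols])) next  # site-complete within group
    cnt <- site_allele_counts(gm, s, cols)
    if (length(cnt) < 2) next
    total <- total + (choose(n, 2) - sum(choose(cnt, 2))) / choose(n, 2)
  }
  total / gene_length
}

# Weir & Cockerham (1984) variance components for one allele at one site.
# n_i: diploid sample sizes; p_i: allele frequencies; h_i: observed
# heterozygote proportions (individuals carrying exactly one copy).
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  N <- sum(n_i)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  pbar <- sum(n_i * p_i) / N
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / N
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Weir-Cockerham F_ST between the sexes
#'
#' The Weir & Cockerham (1984) theta estimator with per-site, per-allele
#' variance components `a` (among groups), `b` (among individuals within
#' groups) and `c` (within individuals), aggregated over the gene as a
#' ratio of sums: `theta = sum(a) / sum(a + b + c)`. Monomorphic sites
#' contribute zero to both sums; the raw value is reported and may be
#' slightly negative. Between the sexes, theta is elevated where X-Y
#' divergence segregates with sex, i.e. where male meiosis does not
#' recombine.
#'
#' @inheritParams nucleotide_diversity
#' @param grouping Grouping variable; only `"sex"` is supported.
#' @return Theta (numeric scalar), or `NA` if no site is informative.
#' @export
fst_weir_cockerham <- function(matrix, grouping = "sex", samples = NULL) {
  gm <- matrix
  stopifnot(inherits(gm, "genotype_matrix"), identical(grouping, "sex"))
  panel <- resolve_panel(gm, samples)
  males <- intersect(panel, gm_which(gm, sex = "male"))
  females <- intersect(panel, gm_which(gm, sex = "female"))
  if (!length(males) || !length(females)) stop("both sexes must be non-empty")
  groups <- list(males, females)
  num <- 0
  den <- 0
  for (s in seq_along(gm$positions)) {
    called <- lapply(groups, function(g) g[!is.na(gm$a1[s, g])])
    n_i <- lengths(called)
    if (any(n_i == 0) || mean(n_i) <= 1) next
    all_alleles <- sort(unique(unlist(lapply(called, function(g) {
      c(gm$a1[s, g], gm$a2[s, g])
    }))))
    if (length(all_alleles) < 2) next  # monomorphic across called samples
    for (a in all_alleles) {
      p_i <- vapply(called, function(g) {
        mean(c(gm$a1[s, g], gm$a2[s, g]) == a)
      }, 0)
      h_i <- vapply(called, function(g) {
        mean((gm$a1[s, g] == a) != (gm$a2[s, g] == a))
      }, 0)
      comp <- wc_components(n_i, p_i, h_i)
      num <- num + comp[["a"]]
      den <- den + sum(comp)
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# standard Tajima constants for n chromosomes
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D over the full sample
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))` where `k` is the mean
#' number of pairwise differences between chromosomes over the gene, `S`
#' the number of segregating sites, and `a1, ..., e2` the standard
#' constants in `n`, the number of chromosomes (2 per diploid). With
#' missing data, `k` uses pairwise-complete chromosomes per site and `S`
#' counts sites with at least two called chromosomes; the constants use
#' the full `n`.
#'
#' @inheritParams nucleotide_diversity
#' @return `D`, or `NA` when `S = 0` (undefined, not zero).
#' @export
tajimas_d <- function(matrix, samples = NULL) {
  gm <- matrix
  stopifnot(inherits(gm, "genotype_matrix"))
  cols <- resolve_panel(gm, samples)
  n <- 2L * length(cols)
  if (n < 4) stop("Tajima's D needs >= 4 chromosomes")
  S <- 0L
  khat <- 0
  for (s in seq_along(gm$positions)) {
    cnt <- site_allele_counts(gm, s, cols)
    nc <- sum(cnt)
    if (nc < 2 || length(cnt) < 2) next
    S <- S + 1L
    # pairwise-complete: each chromosome pair contributes its differences
    # at sites where both members are called; averaging over all
    # choose(n, 2) pairs decomposes site-wise into this sum
    khat <- khat + (choose(nc, 2) - sum(choose(cnt, 2))) / choose(n, 2)
  }
  if (S == 0L) return(NA_real_)
  cst <- tajima_constants(n)
  (khat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Per-gene diversity scan
#'
#' Runs [nucleotide_diversity()] (per sex), [fst_weir_cockerham()] and
#' [tajimas_d()] on each gene and returns one row per gene.
#'
#' @param matrices List of [genotype_matrix()].
#' @param samples Optional sample ids; default per gene is its wild panel.
#' @return Data frame with `gene_id`, `pi_males`, `pi_females`, `fst_mf`,
#'   `tajimas_d`, `n_segregating`, `gene_length`.
#' @export
diversity_scan <- function(matrices, samples = NULL) {
  rows <- lapply(matrices, function(gm) {
    cols <- resolve_panel(gm, samples)
    nseg <- sum(vapply(seq_along(gm$positions), function(s) {
      cnt <- site_allele_counts(gm, s, cols)
      sum(cnt) >= 2 && length(cnt) >= 2
    }, TRUE))
    data.frame(
      gene_id = gm$gene_id,
      pi_males = nucleotide_diversity(gm, "male", samples = samples),
      pi_females = nucleotide_diversity(gm, "female", samples = samples),
      fst_mf = fst_weir_cockerham(gm, samples = samples),
      tajimas_d = tajimas_d(gm, samples = samples),
      n_segregating = nseg,
      gene_length = gm$gene_length,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare male and female diversity across the genes of a region
#'
#' Two-sample pooled-variance Student's t-test of per-gene `pi_males`
#' against `pi_females` within one map region.
#'
#' @param results Data frame holding `pi_males`, `pi_females` and a
#'   `category` column (e.g. [diversity_scan()] merged with
#'   [classify_genes()]).
#' @param region Category value(s) to keep; `"fuzzy"` expands to both
#'   fuzzy categories.
#' @return List with `mean_pi_males`, `mean_pi_females`, `ratio`,
#'   `t_stat`, `p_value`, `n_genes`.
#' @export
compare_pi <- function(results, region) {
  if (identical(region, "fuzzy")) region <- c("fuzzy-I", "fuzzy-II")
  d <- results[results$category %in% region, , drop = FALSE]
  if (nrow(d) < 2) stop("need >= 2 genes in region")
  x <- d$pi_males
  y <- d$pi_females
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- if (se == 0) {
    if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
  } else {
    (mean(x) - mean(y)) / se
  }
  p <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  list(
    mean_pi_males = mean(x),
    mean_pi_females = mean(y),
    ratio = mean(x) / mean(y),
    t_stat = t_stat,
    p_value = p,
    n_genes = n1
  )
}

#' Regress Tajima's D on distance from the PAR boundary
#'
#' Ordinary least squares of per-gene Tajima's D on cM distance from the
#' boundary, over pseudoautosomal genes; the slope's two-sided p-value
#' comes from the t distribution with n - 2 df. A significant negative
#' slope indicates that the excess of intermediate-frequency variants
#' decays with distance from the sex-linked region.
#'
#' @param results Data frame with `tajimas_d`, `map_cM` and (if present)
#'   a `category` column, from which only `"PAR"` genes are used.
#' @param boundary_cM The PAR boundary position in cM.
#' @return List with `slope` (D per cM), `intercept`, `p_value`, `n`.
#' @export
regress_d_on_distance <- function(results, boundary_cM) {
  d <- results
  if ("category" %in% names(d)) d <- d[d$category == "PAR", , drop = FALSE]
  d <- d[!is.na(d$tajimas_d), , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 PAR genes with defined D")
  dist <- d$map_cM - boundary_cM
  if (stats::var(dist) == 0) stop("zero variance in distance")
  fit <- stats::lm(d$tajimas_d ~ dist)
  # an exactly collinear input is legitimate here: its slope p-value is 0
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) < 2 || is.nan(sm[2, 4])) 0 else sm[2, 4]
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p_value = p,
    n = nrow(d)
  )
}
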