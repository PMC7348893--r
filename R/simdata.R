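# Forward simulator for one gene of an XY system sampled as a genetic cross
# plus a wild panel.
#
# Model: a neutral infinite-sites X-chromosome background (unlinked sites,
# derived-allele counts drawn from the standard neutral frequency spectrum,
# so E[pi] = theta per site), a single Y lineage carrying Poisson(d_xy)
# private "Y-diagnostic" derived alleles relative to the X consensus (zero
# within-Y polymorphism), and a leak process by which each wild-female X
# copy independently carries the Y allele at each diagnostic site with
# probability leak_prob -- the footprint of rare historical recombination in
# male meiosis. For PAR genes the paternal homologs are exchangeable draws
# from the X pool (d_xy = 0) and recombine freely with the sex locus.

#' Simulate genotypes for one gene
#'
#' Generates the full study panel at a single gene: father, mother,
#' `n_sons` sons, `n_daughters` daughters, and the wild males and females.
#' Sons inherit the father's Y haplotype except when a male-meiosis
#' recombination event replaced it with his X (and daughters vice versa).
#'
#' The returned object carries a `truth` attribute recording the simulated
#' region, the Y-diagnostic site positions, and whether any progeny
#' genotype is detectably recombinant with respect to the father's
#' expected transmissions -- the ground truth used to benchmark the
#' inference stages.
#'
#' @param params A [sim_params()] object.
#' @param gene_index Gene index in `1:params$n_genes`.
#' @param seed Optional integer seed; default derives deterministically
#'   from `params$seed` and `gene_index`, so genes are reproducible
#'   independently.
#' @return A [genotype_matrix()].
#' @export
simulate_gene <- function(params, gene_index, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (gene_index < 1 || gene_index > params$n_genes) {
    stop("unknown gene_index: ", gene_index)
  }
  if (params$gene_length <= 0) stop("non-positive gene_length")
  seed <- seed %||% gene_seed(params$seed, gene_index)
  with_seed(seed, sim_gene_impl(params, gene_index))
}

sim_gene_impl <- function(params, gene_index) {
  region <- params$region_labels[gene_index]
  L <- params$gene_length
  nwf <- params$n_wild_females
  nwm <- params$n_wild_males
  is_par <- region == "PAR"

  # founder X copies: mother (2), father's X (1), 2 per wild female, 1 per
  # wild male; for PAR genes the Y-side copies (father + wild males) are
  # additional exchangeable draws from the same neutral pool
  n_x <- 3L + 2L * nwf + nwm
  n_hap <- n_x + if (is_par) 1L + nwm else 0L

  a1n <- sum(1 / seq_len(max(n_hap - 1L, 1L)))
  n_diag <- if (is_par) 0L else stats::rpois(1, unname(params$d_xy[region]))
  n_diag <- min(n_diag, L %/% 2L)
  S <- min(stats::rpois(1, params$theta * L * a1n), L - n_diag)
  npos <- S + n_diag
  pos <- sort(sample.int(L, npos))
  diag_rows <- if (n_diag > 0) sort(sample.int(npos, n_diag)) else integer(0)
  neutral_rows <- setdiff(seq_len(npos), diag_rows)

  # founder haplotypes: 0 = ancestral, 1 = derived
  H <- matrix(0L, npos, n_hap)
  if (length(neutral_rows) && n_hap > 1) {
    counts <- sample.int(n_hap - 1L, length(neutral_rows), replace = TRUE,
                         prob = 1 / seq_len(n_hap - 1L))
    for (k in seq_along(neutral_rows)) {
      H[neutral_rows[k], sample.int(n_hap, counts[k])] <- 1L
    }
  }

  # column layout of the founder pool
  col_mother <- 1:2
  col_father_x <- 3L
  col_wf <- if (nwf) 3L + seq_len(2L * nwf) else integer(0)
  col_wm_x <- if (nwm) 3L + 2L * nwf + seq_len(nwm) else integer(0)

  father_x <- H[, col_father_x]

  if (is_par) {
    col_father_y <- n_x + 1L
    col_wm_y <- if (nwm) n_x + 1L + seq_len(nwm) else integer(0)
    y_father <- H[, col_father_y]
    wm_second <- lapply(seq_len(nwm), function(i) H[, col_wm_y[i]])
  } else {
    # Single Y lineage: its neutral background is collapsed onto the
    # father's X haplotype, so X and Y differ exactly at the
    # Poisson(d_xy) private Y-diagnostic sites. Current X polymorphism
    # is younger than the X-Y split, so the family segregation pattern
    # is informative only at the X-Y divergent sites; folding the
    # neutral background keeps that identifiability exact.
    y_father <- father_x
    y_father[diag_rows] <- 1L
    wm_second <- rep(list(y_father), nwm)
  }

  # leak: each wild-female X copy carries the Y allele at each diagnostic
  # site with probability leak_prob
  wf_cols <- lapply(col_wf, function(j) H[, j])
  if (!is_par && n_diag > 0 && nwf > 0) {
    p_leak <- unname(params$leak_prob[region])
    if (p_leak > 0) {
      for (i in seq_along(wf_cols)) {
        hit <- stats::runif(n_diag) < p_leak
        if (any(hit)) wf_cols[[i]][diag_rows[hit]] <- 1L
      }
    }
  }

  # progeny
  ns <- params$n_sons
  nd <- params$n_daughters
  nkids <- ns + nd
  r <- male_recomb_prob(params, gene_index)
  maternal <- sample(col_mother, nkids, replace = TRUE)
  recomb_event <- stats::runif(nkids) < r
  is_son <- c(rep(TRUE, ns), rep(FALSE, nd))
  # sons expect Y, daughters expect X; a recombination event swaps them
  gets_y <- ifelse(is_son, !recomb_event, recomb_event)
  kid_pat <- lapply(seq_len(nkids), function(k) {
    if (gets_y[k]) y_father else father_x
  })
  kid_mat <- lapply(maternal, function(j) H[, j])
  # detectably recombinant: wrong lineage AND the received haplotype
  # differs from the expected one at >= 1 site
  kid_recombinant <- recomb_event & any(y_father != father_x)

  hapA <- cbind(
    father_x,
    H[, col_mother[1]],
    do.call(cbind, c(kid_mat, list(matrix(0L, npos, 0)))),
    if (nwm) do.call(cbind, lapply(col_wm_x, function(j) H[, j, drop = FALSE])),
    if (nwf) do.call(cbind, wf_cols[seq(1, 2 * nwf, by = 2)])
  )
  hapB <- cbind(
    y_father,
    H[, col_mother[2]],
    do.call(cbind, c(kid_pat, list(matrix(0L, npos, 0)))),
    if (nwm) do.call(cbind, wm_second),
    if (nwf) do.call(cbind, wf_cols[seq(2, 2 * nwf, by = 2)])
  )

  ids <- c(
    "father", "mother",
    sprintf("son_%02d", seq_len(ns)), sprintf("daughter_%02d", seq_len(nd)),
    if (nwm) sprintf("wildM_%d", seq_len(nwm)),
    if (nwf) sprintf("wildF_%d", seq_len(nwf))
  )
  sexes <- c(
    "male", "female", rep("male", ns), rep("female", nd),
    rep("male", nwm), rep("female", nwf)
  )
  roles <- c(
    "father", "mother", rep("son", ns), rep("daughter", nd),
    rep("wild", nwm + nwf)
  )

  if (params$missing_rate > 0 && npos > 0) {
    miss <- matrix(stats::runif(npos * length(ids)) < params$missing_rate,
                   npos, length(ids))
    hapA[miss] <- NA_integer_
    hapB[miss] <- NA_integer_
  }

  ref <- sample(c("A", "C", "G", "T"), npos, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                "", USE.NAMES = FALSE)
  alleles <- lapply(seq_len(npos), function(i) c(ref[i], alt[i]))

  gm <- genotype_matrix(
    gene_id = sprintf("gene_%03d", gene_index),
    positions = pos, alleles = alleles,
    a1 = hapA, a2 = hapB,
    individuals = data.frame(sample_id = ids, sex = sexes, role = roles,
                             stringsAsFactors = FALSE),
    gene_length = L
  )
  attr(gm, "truth") <- list(
    region = region,
    map_cM = params$map_positions[gene_index],
    diagnostic_pos = pos[diag_rows],
    diagnostic_allele = if (length(diag_rows)) alt[diag_rows] else character(0),
    any_recombinant = any(kid_recombinant),
    n_recombinant = sum(kid_recombinant)
  )
  gm
}

#' Simulate a full multi-gene dataset
#'
#' Calls [simulate_gene()] for every gene of `params` with a
#' deterministically derived per-gene seed (identical parameters give
#' bit-identical output) and derives each gene's cross status from the
#' simulated cross itself: `"PAR"` if any son or daughter genotype is
#' detectably recombinant with respect to the father's expected
#' transmissions, `"X"` otherwise -- exactly the information a segregation
#' analysis of the family would have.
#'
#' @param params A [sim_params()] object.
#' @return A list with `records` (data frame: `gene_id`, `map_cM`,
#'   `cross_status`, `true_region`) and `matrices` (list of
#'   [genotype_matrix()], one per gene).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  matrices <- lapply(seq_len(params$n_genes), function(g) {
    simulate_gene(params, g)
  })
  truths <- lapply(matrices, attr, "truth")
  records <- data.frame(
    gene_id = vapply(matrices, function(m) m$gene_id, ""),
    map_cM = params$map_positions,
    cross_status = ifelse(vapply(truths, `[[`, TRUE, "any_recombinant"),
                          "PAR", "X"),
    true_region = params$region_labels,
    stringsAsFactors = FALSE
  )
  list(records = records, matrices = matrices)
}
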