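#' Parameters for the XY cross-plus-wild-panel simulator
#'
#' Defines the data-generating conditions for a set of genes spanning the
#' junction of a young sex chromosome: a fully sex-linked block (`"NRY"`),
#' a partially sex-linked "fuzzy boundary" block (`"FUZZY"`) where male
#' meiosis recombines only rarely, and a freely recombining pseudoautosomal
#' block (`"PAR"`), ordered proximal to distal along the genetic map.
#'
#' The default design mirrors the study system the package targets: 86
#' genes (28 NRY, 20 fuzzy, 38 PAR), a two-parent cross with 20 sons and
#' 32 daughters, and a wild panel of 3 males and 5 females.
#'
#' @param region_labels Character vector over genes with values `"NRY"`,
#'   `"FUZZY"`, `"PAR"`; must form three contiguous blocks in that order
#'   (blocks may be empty).
#' @param n_genes Number of genes; defaults to `length(region_labels)`.
#' @param map_positions Non-decreasing numeric vector of cM positions per
#'   gene. Default places the NRY at 60-62.6 cM, the fuzzy zone at
#'   62.7-63.6 cM and the PAR at 64.8-72.1 cM, the map interval the
#'   classifier's default anchors refer to.
#' @param theta Population-scaled mutation rate per site; the expected
#'   per-site nucleotide diversity of the X-chromosome background.
#' @param gene_length Gene length in bp (window size for diversity).
#' @param d_xy Named vector (`NRY`, `FUZZY`, `PAR`): expected number of
#'   fixed X-Y ("Y-diagnostic") differences per gene, proportional to
#'   stratum age. Must be 0 for PAR. Defaults are calibrated to the male
#'   diversity excess of the study system (see the methods vignette).
#' @param leak_prob Named vector (`NRY`, `FUZZY`, `PAR`): probability that
#'   a wild-female X-chromosome copy carries the Y allele at a
#'   Y-diagnostic site (the footprint of rare historical male
#'   recombination). Must be 0 for NRY; ignored for PAR (no diagnostic
#'   sites there). The fuzzy-zone default matches the fraction of Y-SNPs
#'   observed in wild females in the study system.
#' @param male_recomb_fuzzy Per-meiosis probability that a fuzzy-zone gene
#'   recombines away from the sex-determining region in the cross. Of
#'   order `leak_prob` divided by the coalescent depth of the wild sample,
#'   hence effectively zero in a 52-meiosis family.
#' @param par_recomb Optional fixed per-meiosis recombination probability
#'   for every PAR gene (e.g. 0.5 for unlinked). If `NULL`, derived from
#'   map distance via Haldane's function on a male map expanded by
#'   `par_recomb_inflation` (recombination in male meiosis is confined to,
#'   and therefore concentrated in, the PAR).
#' @param par_recomb_inflation Male/sex-averaged map ratio inside the PAR.
#' @param n_sons,n_daughters Progeny counts of the cross.
#' @param n_wild_males,n_wild_females Wild panel composition.
#' @param missing_rate Per-call missing-data probability.
#' @param seed Integer base seed; every gene's RNG stream derives from it.
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(region_labels = rep(c("NRY", "FUZZY", "PAR"),
                                           times = c(28, 20, 38)),
                       n_genes = length(region_labels),
                       map_positions = NULL,
                       theta = 0.0025,
                       gene_length = 1000L,
                       d_xy = c(NRY = 7, FUZZY = 14, PAR = 0),
                       leak_prob = c(NRY = 0, FUZZY = 0.02, PAR = 0),
                       male_recomb_fuzzy = 1e-5,
                       par_recomb = NULL,
                       par_recomb_inflation = 10,
                       n_sons = 20L, n_daughters = 32L,
                       n_wild_males = 3L, n_wild_females = 5L,
                       missing_rate = 0,
                       seed = 1L) {
  region_labels <- match.arg(region_labels, c("NRY", "FUZZY", "PAR"),
                             several.ok = TRUE)
  if (n_genes != length(region_labels)) {
    stop("n_genes must equal length(region_labels)")
  }
  r <- rle(region_labels)
  if (!identical(r$values, intersect(c("NRY", "FUZZY", "PAR"), r$values))) {
    stop("region_labels must be contiguous blocks ordered NRY, FUZZY, PAR")
  }
  if (is.null(map_positions)) {
    blocks <- list(NRY = c(60, 62.6), FUZZY = c(62.7, 63.6), PAR = c(64.8, 72.1))
    map_positions <- unlist(lapply(seq_along(r$values), function(i) {
      b <- blocks[[r$values[i]]]
      round(seq(b[1], b[2], length.out = r$lengths[i]), 3)
    }), use.names = FALSE)
  }
  if (length(map_positions) != n_genes) stop("one map position per gene required")
  if (any(diff(map_positions) < 0)) stop("map_positions must be non-decreasing")
  if (any(map_positions < 0)) stop("map positions must be >= 0")
  stopifnot(
    theta > 0, gene_length > 0,
    all(c("NRY", "FUZZY", "PAR") %in% names(d_xy)),
    all(c("NRY", "FUZZY", "PAR") %in% names(leak_prob)),
    n_sons >= 1, n_daughters >= 1, n_wild_males >= 0, n_wild_females >= 0,
    missing_rate >= 0, missing_rate < 1
  )
  if (d_xy[["PAR"]] != 0) stop("d_xy must be 0 for PAR genes")
  if (leak_prob[["NRY"]] != 0) stop("leak_prob must be 0 for NRY genes")
  structure(
    list(
      n_genes = as.integer(n_genes),
      region_labels = region_labels,
      map_positions = as.numeric(map_positions),
      theta = theta,
      gene_length = as.integer(gene_length),
      d_xy = d_xy,
      leak_prob = leak_prob,
      male_recomb_fuzzy = male_recomb_fuzzy,
      par_recomb = par_recomb,
      par_recomb_inflation = par_recomb_inflation,
      n_sons = as.integer(n_sons),
      n_daughters = as.integer(n_daughters),
      n_wild_males = as.integer(n_wild_males),
      n_wild_females = as.integer(n_wild_females),
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

# per-meiosis probability that gene g's paternal transmission is recombinant
# with respect to the sex-determining region
male_recomb_prob <- function(params, gene_index) {
  region <- params$region_labels[gene_index]
  if (region == "NRY") return(0)
  if (region == "FUZZY") return(params$male_recomb_fuzzy)
  if (!is.null(params$par_recomb)) return(params$par_recomb)
  non_par <- params$map_positions[params$region_labels != "PAR"]
  origin <- if (length(non_par)) max(non_par) else min(params$map_positions)
  d_cm <- (params$map_positions[gene_index] - origin) * params$par_recomb_inflation
  0.5 * (1 - exp(-2 * d_cm / 100))
}
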