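# Independent oracles used across test files. Each re-derives its
# statistic by a different route than the package implementation:
# - brute_pi: all-chromosome-pairs brute force
# - anova_theta: nested ANOVA sums-of-squares route to the
#   Weir-Cockerham variance components
# - oracle_tajima: constant-by-constant direct evaluation with per-pair
#   difference counting

brute_pi <- function(gm, cols, gene_length) {
  haps <- rbind(t(gm$a1[, cols, drop = FALSE]), t(gm$a2[, cols, drop = FALSE]))
  ok_site <- apply(haps, 2, function(x) !anyNA(x))
  total <- 0
  n <- nrow(haps)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(haps[i, ok_site] != haps[j, ok_site])
    }
  }
  total / choose(n, 2) / gene_length
}

anova_theta <- function(gm, males, females) {
  num <- 0
  den <- 0
  for (s in seq_along(gm$positions)) {
    grp <- list(males[!is.na(gm$a1[s, males])],
                females[!is.na(gm$a1[s, females])])
    n_i <- lengths(grp)
    if (any(n_i == 0) || mean(n_i) <= 1) next
    alleles <- sort(unique(unlist(lapply(grp, function(g) {
      c(gm$a1[s, g], gm$a2[s, g])
    }))))
    if (length(alleles) < 2) next
    N <- sum(n_i)
    r <- 2
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    for (a in alleles) {
      xbar_ij <- lapply(grp, function(g) {
        ((gm$a1[s, g] == a) + (gm$a2[s, g] == a)) / 2
      })
      p_i <- vapply(xbar_ij, mean, 0)
      pbar <- sum(n_i * p_i) / N
      ssg <- sum(vapply(seq_len(r), function(i) {
        g <- grp[[i]]
        x1 <- gm$a1[s, g] == a
        x2 <- gm$a2[s, g] == a
        sum((x1 - xbar_ij[[i]])^2 + (x2 - xbar_ij[[i]])^2)
      }, 0))
      ssi <- sum(vapply(seq_len(r), function(i) {
        2 * sum((xbar_ij[[i]] - p_i[i])^2)
      }, 0))
      ssp <- sum(2 * n_i * (p_i - pbar)^2)
      msg <- ssg / N
      msi <- ssi / (N - r)
      msp <- ssp / (r - 1)
      s2g <- msg
      s2i <- (msi - msg) / 2
      s2p <- (msp - msi) / (2 * nc)
      num <- num + s2p
      den <- den + s2p + s2i + s2g
    }
  }
  if (den == 0) NA_real_ else num / den
}

oracle_tajima <- function(gm, cols) {
  haps <- rbind(t(gm$a1[, cols, drop = FALSE]), t(gm$a2[, cols, drop = FALSE]))
  n <- nrow(haps)
  seg <- apply(haps, 2, function(x) length(unique(x[!is.na(x)])) >= 2)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(haps[i, ]) & !is.na(haps[j, ])
      k <- k + sum(haps[i, ok] != haps[j, ok])
    }
  }
  k <- k / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}
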