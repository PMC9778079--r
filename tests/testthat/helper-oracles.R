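# Independent oracles used by the tests. These deliberately re-derive the
# science by brute force (gamete enumeration, nested-loop joins, grid
# quadrature) and never call the package paths they check.

# alleles (B-copy counts) carried by a diploid genotype code
alleles_of <- function(code) switch(code + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))

# gamete-enumeration consistency oracle: enumerate every gamete pair the
# model allows and ask whether any produces the offspring genotype
oracle_consistent <- function(sire, dam, off, sex, model) {
  if (is.na(sire) || is.na(dam) || is.na(off)) return(NA)
  da <- alleles_of(dam)
  if (model == "pseudoautosomal") {
    sa <- alleles_of(sire)
    g <- expand.grid(s = sa, d = da)
    return(any(g$s + g$d == off))
  }
  if (sex == "male") {
    # hemizygous: one maternal allele, array-coded 0/2
    if (off == 1L) return(FALSE)
    return((off %/% 2L) %in% da)
  }
  # female: sire hemizygous allele plus one dam allele
  if (sire == 1L) return(FALSE)
  any((sire %/% 2L) + da == off)
}

# brute-force per-trio dam-transmission resolution at a heterosomal marker
oracle_dam_transmissions <- function(sire, dam, off, sex, stratum) {
  n_a <- n_b <- 0L
  for (i in seq_along(off)) {
    if (stratum != "pooled" && sex[i] != stratum) next
    if (is.na(dam[i]) || dam[i] != 1L || is.na(off[i])) next
    if (sex[i] == "male") {
      if (off[i] == 0L) n_a <- n_a + 1L
      if (off[i] == 2L) n_b <- n_b + 1L
    } else if (sex[i] == "female") {
      if (is.na(sire[i]) || sire[i] == 1L) next
      mat <- off[i] - sire[i] %/% 2L
      if (mat == 0L) n_a <- n_a + 1L
      if (mat == 1L) n_b <- n_b + 1L
    }
  }
  list(n_a = n_a, n_b = n_b)
}

# brute-force pseudoautosomal resolution: exhaustive gamete assignment,
# counting a parent's transmission only when it is unique
oracle_parent_transmissions <- function(sire, dam, off, sex, stratum) {
  n_a_s <- n_b_s <- n_a_d <- n_b_d <- n_amb <- 0L
  for (i in seq_along(off)) {
    if (stratum != "pooled" && sex[i] != stratum) next
    if (is.na(sire[i]) || is.na(dam[i]) || is.na(off[i])) next
    sa <- alleles_of(sire[i]); da <- alleles_of(dam[i])
    g <- expand.grid(s = sa, d = da)
    g <- g[g$s + g$d == off[i], , drop = FALSE]
    if (!nrow(g)) next                      # inconsistent
    if (sire[i] == 1L) {
      ts <- unique(g$s)
      if (length(ts) == 1L) {
        if (ts == 0L) n_a_s <- n_a_s + 1L else n_b_s <- n_b_s + 1L
      }
    }
    if (dam[i] == 1L) {
      td <- unique(g$d)
      if (length(td) == 1L) {
        if (td == 0L) n_a_d <- n_a_d + 1L else n_b_d <- n_b_d + 1L
      }
    }
    if (sire[i] == 1L && dam[i] == 1L && off[i] == 1L)
      n_amb <- n_amb + 1L
  }
  list(n_a_sire = n_a_s, n_b_sire = n_b_s, n_a_dam = n_a_d, n_b_dam = n_b_d,
       n_ambiguous = n_amb)
}

# dense-grid quadrature oracle for the genotypic model posterior
oracle_genotypic_grid <- function(n_aa, n_ab1, n_ab2, n_bb, n_grid = 401L) {
  a <- seq(-1 + 1e-6, 1 - 1e-6, length.out = n_grid)
  d <- a
  ll <- outer(a, d, function(ai, di) {
    n_aa * log((1 + ai) / (2 + ai + di)) +
      n_ab1 * log((1 + di) / (2 + ai + di)) +
      n_ab2 * log((1 + di) / (2 + di - ai)) +
      n_bb * log((1 - ai) / (2 + di - ai))
  })
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  list(mean_alpha_g = sum(rowSums(w) * a),
       mean_delta_g = sum(colSums(w) * d))
}

# batch-means effective sample size and Monte-Carlo standard error
mc_se <- function(x, n_batches = 50L) {
  n <- length(x)
  bs <- n %/% n_batches
  bm <- vapply(seq_len(n_batches),
               function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sqrt(stats::var(bm) / n_batches)
}

# delta-method MC standard error of the sample-based log10 Savage-Dickey BF.
# The fitted ordinate at the null behaves like a Gaussian tail,
# log10 f(0) ~ const - z^2 / (2 ln 10) with z = |mean| / sd, so errors in the
# estimated posterior mean and scale propagate with weights z/(sd ln 10) and
# z^2/(sd ln 10). ESS from batch means feeds the scale error sd/sqrt(2 ESS).
bf_mc_se <- function(samples) {
  m <- mean(samples); s <- stats::sd(samples)
  z <- abs(m) / s
  se_mean <- mc_se(samples)
  ess <- max(10, (s / se_mean)^2)
  se_sd <- s / sqrt(2 * ess)
  sqrt((z / (s * log(10)) * se_mean)^2 + (z^2 / (s * log(10)) * se_sd)^2)
}
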