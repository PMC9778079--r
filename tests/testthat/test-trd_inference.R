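# Bayesian allelic/genotypic fits, Savage-Dickey Bayes factors,
# empirical-null calibration.

test_that("closed-form dam-TRD posterior reproduces published worked examples", {
  cases <- list(list(470, 757, -0.12, 13.3, 1),    # strongest SNP, pooled
                list(0, 72, -0.49, 19.8, 1),       # empty A category window
                list(5, 91, -0.44, 19.13, 2),
                list(13, 103, -0.38, 16.11, 2),
                list(118, 310, -0.22, 18.12, 2),
                list(964, 623, 0.11, 14.5, 1),
                list(912, 707, 0.06, 4.14, 2))
  for (cs in cases) {
    ct <- transmission_counts(n_a_dam = cs[[1]], n_b_dam = cs[[2]])
    r <- fit_allelic(ct, trd_model_spec("alpha_d", "heterosomal"))
    expect_equal(round(r$params$post_mean, 2), cs[[3]],
                 info = sprintf("%d/%d", cs[[1]], cs[[2]]))
    expect_equal(round(r$params$log10_bf, cs[[5]]), cs[[4]],
                 info = sprintf("%d/%d", cs[[1]], cs[[2]]))
  }
  # balanced counts are exactly symmetric and favour the null
  ct <- transmission_counts(n_a_dam = 50L, n_b_dam = 50L)
  r <- fit_allelic(ct, trd_model_spec("alpha_d", "heterosomal"))
  expect_equal(r$params$post_mean, 0)
  expect_equal(r$params$log10_bf, log10(1 / dbeta(0.5, 51, 51)),
               tolerance = 1e-12)
  expect_lt(r$params$log10_bf, 0)
})

test_that("sampler agrees with Beta analytics within Monte-Carlo error", {
  set.seed(101)
  for (i in 1:4) {
    n <- sample(50:400, 1)
    n_a <- rbinom(1, n, runif(1, 0.25, 0.75))
    ct <- transmission_counts(n_a_dam = n_a, n_b_dam = n - n_a)
    r <- fit_allelic(ct, trd_model_spec("alpha_d", "heterosomal"),
                     cfg = short_cfg(seed = i), method = "mcmc")
    a <- n_a + 1; b <- n - n_a + 1
    exact_mean <- a / (a + b) - 0.5
    sam <- r$samples[, 1]
    expect_lt(abs(r$params$post_mean - exact_mean), 3 * mc_se(sam))
    exact_bf <- log10_bf_counts(n_a, n - n_a)
    expect_lt(abs(r$params$log10_bf - exact_bf),
              max(0.1, 3 * bf_mc_se(sam)))
  }
})

test_that("zero informative transmissions give a flagged result and BF 1", {
  ct <- transmission_counts()
  r <- fit_allelic(ct, trd_model_spec("alpha_d", "heterosomal"))
  expect_equal(r$method, "none")
  expect_match(r$flag, "no informative")
  expect_equal(r$params$log10_bf, 0)
  expect_true(is.na(r$params$post_mean))
})

test_that("the ambiguous AB x AB class enters as a mixture, not a count", {
  # only ambiguous offspring: likelihood is flat along alpha_s = alpha_d
  # but curved against opposite-sign distortion; posterior stays centred
  ct <- transmission_counts(n_a_sire = 30L, n_b_sire = 30L, n_a_dam = 30L,
                            n_b_dam = 30L, n_ambiguous = 40L,
                            n_het_sires = 20L, n_het_dams = 20L)
  r <- fit_allelic(ct, trd_model_spec(c("alpha_s", "alpha_d")),
                   cfg = short_cfg(seed = 5))
  expect_equal(r$method, "mcmc")
  expect_lt(abs(r$params$post_mean[1]), 0.05)
  expect_lt(abs(r$params$post_mean[2]), 0.05)
  # exact path must refuse a mixture model
  expect_error(fit_allelic(ct, trd_model_spec(c("alpha_s", "alpha_d")),
                           method = "exact"), "ambiguous")
})

test_that("|alpha| and log10 BF are monotone in count imbalance at fixed n", {
  n <- 200L
  prev_a <- -Inf; prev_bf <- -Inf
  for (n_b in seq(100L, 190L, by = 10L)) {
    ct <- transmission_counts(n_a_dam = n - n_b, n_b_dam = n_b)
    r <- fit_allelic(ct, trd_model_spec("alpha_d", "heterosomal"))
    expect_gte(abs(r$params$post_mean), prev_a)
    expect_gte(r$params$log10_bf, prev_bf)
    prev_a <- abs(r$params$post_mean)
    prev_bf <- r$params$log10_bf
  }
})

test_that("genotypic fit is centred at Mendelian proportions and matches the grid oracle", {
  # balanced categories: both parameters near zero
  r <- fit_genotypic(recessive_table(120, 120, 150, 150),
                     cfg = short_cfg(seed = 2))
  expect_lt(abs(r$params$post_mean[1]), 0.06)
  expect_lt(abs(r$params$post_mean[2]), 0.06)

  # small-count tables against dense 2-D quadrature
  set.seed(17)
  for (i in 1:3) {
    k <- as.list(sample(0:20, 4, replace = TRUE))
    r <- fit_genotypic(recessive_table(k[[1]], k[[2]], k[[3]], k[[4]]),
                       cfg = short_cfg(seed = 10 + i))
    or <- oracle_genotypic_grid(k[[1]], k[[2]], k[[3]], k[[4]])
    expect_lt(abs(r$params$post_mean[1] - or$mean_alpha_g),
              max(3 * mc_se(r$samples[, 1]), 0.01))
    expect_lt(abs(r$params$post_mean[2] - or$mean_delta_g),
              max(3 * mc_se(r$samples[, 2]), 0.01))
  }
})

test_that("missing homozygotes drive alpha_g negative with compensating delta_g", {
  # zero AA against 6 AB with balanced BB x AB, the published recessive shape
  r <- fit_genotypic(recessive_table(0, 6, 683, 689), cfg = short_cfg(seed = 3))
  expect_lt(r$params$post_mean[1], 0)
  expect_gt(r$params$post_mean[2], 0)
})

test_that("modelled genotype probabilities normalise within each mating class", {
  for (a in seq(-0.9, 0.9, by = 0.3)) for (d in seq(-0.9, 0.9, by = 0.3)) {
    w <- c(1 + a, 1 + d, 1 - a)
    p1 <- w[1:2] / sum(w[1:2])
    p2 <- w[2:3] / sum(w[2:3])
    expect_equal(sum(p1), 1)
    expect_equal(sum(p2), 1)
    expect_true(all(p1 >= 0) && all(p2 >= 0))
  }
})

test_that("empirical-null classes match exact binomial tails", {
  # no distortion -> the most permissive class
  expect_equal(empirical_null_class(0, 500L, n_reps = 1e5, seed = 2), ">5")
  # all-B transmission of 72: exact tail 2 * 0.5^72, far below the finest cut
  a_hat <- 1 / 74 - 0.5
  expect_equal(empirical_null_class(a_hat, 72L, n_reps = 1e6, seed = 2),
               "<=0.001")
  # the strongest published SNP lands in the finest class as printed
  a_hat <- 471 / 1229 - 0.5
  expect_equal(empirical_null_class(a_hat, 1227L, n_reps = 1e6, seed = 2),
               "<=0.001")
  # classes relax as |alpha| shrinks at fixed n
  cls <- vapply(c(0.45, 0.1, 0.05, 0.02, 0), function(a)
    empirical_null_class(a, 100L, n_reps = 1e5, seed = 3), "")
  ranks <- match(cls, c("<=0.001", "<=0.01", "<=0.1", "<=1", "<=5", ">5"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("type-I rate of decisive-and-calibrated calls is bounded under the null", {
  set.seed(71)
  n <- 300L
  n_markers <- 400L
  hits <- 0L
  for (i in seq_len(n_markers)) {
    n_a <- rbinom(1, n, 0.5)
    ct <- transmission_counts(n_a_dam = n_a, n_b_dam = n - n_a)
    r <- fit_allelic(ct, trd_model_spec("alpha_d", "heterosomal"))
    if (r$params$log10_bf >= 2) {
      cls <- empirical_null_class(r$params$post_mean, n, n_reps = 1e5,
                                  seed = 5)
      if (cls %in% c("<=0.001", "<=0.01", "<=0.1")) hits <- hits + 1L
    }
  }
  # nominal class level 0.1%: allow generous sampling slack above 0.4/400
  expect_lte(hits / n_markers, 0.005)
})

test_that("heterosomal model specs refuse sire parameters", {
  expect_error(trd_model_spec("alpha_s", "heterosomal"), "dam-specific")
  expect_error(trd_model_spec("alpha", "heterosomal"), "dam-specific")
  expect_silent(trd_model_spec(c("alpha_d_m", "alpha_d_f"), "heterosomal"))
})
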