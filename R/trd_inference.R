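# Bayesian estimation of allelic and genotypic TRD, Savage-Dickey Bayes
# factors, and empirical-null calibration.
#
# Allelic model: each resolved transmission from a heterozygous parent is
# Bernoulli with P(A) = 0.5 + alpha for that parent/stratum's parameter,
# alpha uniform on (-0.5, 0.5). Ambiguous AB x AB -> AB offspring contribute
# the mixture P_s(A) P_d(B) + P_s(B) P_d(A). When the model reduces to a
# single binomial the posterior of p = 0.5 + alpha is Beta(n_a + 1, n_b + 1)
# in closed form; the MCMC path must agree with it within Monte-Carlo error.

#' MCMC configuration
#'
#' A single random-walk Metropolis chain; proposals reflect at the parameter
#' bounds so the chain never leaves the prior support.
#'
#' @param iterations total chain length (default 110000).
#' @param burn_in discarded initial iterations (default 10000).
#' @param seed chain seed.
#' @param proposal_sd random-walk proposal standard deviation.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 110000L, burn_in = 10000L, seed = 1L,
                        proposal_sd = 0.05) {
  stopifnot(burn_in < iterations, proposal_sd > 0)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 proposal_sd = proposal_sd), class = "mcmc_config")
}

#' Allelic TRD model specification
#'
#' Names the active TRD parameters. Parameter names follow
#' `alpha[_parent][_sex]` with parent `s` (sire) or `d` (dam) and offspring
#' sex `m` or `f`: e.g. `"alpha_d"` (dam-TRD, pooled offspring), `"alpha_s_m"`
#' (sire-TRD to male offspring). The heterosomal region admits only dam
#' parameters, because sires are hemizygous there and cannot be heterozygous.
#'
#' @param params character vector of active parameter names.
#' @param region `"pseudoautosomal"` or `"heterosomal"`.
#' @return A list of class `trd_model_spec`.
#' @export
trd_model_spec <- function(params = "alpha_d",
                           region = c("pseudoautosomal", "heterosomal")) {
  region <- match.arg(region)
  valid <- c("alpha", "alpha_s", "alpha_d", "alpha_m", "alpha_f",
             "alpha_s_m", "alpha_s_f", "alpha_d_m", "alpha_d_f")
  if (!all(params %in% valid))
    stop("unknown parameter(s): ", paste(setdiff(params, valid), collapse = ", "))
  if (region == "heterosomal" &&
      any(grepl("^alpha_s", params) | params %in% c("alpha", "alpha_m", "alpha_f")))
    stop("the heterosomal region admits only dam-specific TRD parameters")
  structure(list(params = params, region = region), class = "trd_model_spec")
}

# which counts feed a parameter, given a stratum's transmission_counts
param_applies <- function(param, parent, stratum) {
  p <- strsplit(param, "_")[[1]]
  par_ok <- length(p) < 2L || !(p[2] %in% c("s", "d")) ||
    (p[2] == "s" && parent == "sire") || (p[2] == "d" && parent == "dam")
  sex <- if (p[length(p)] %in% c("m", "f")) p[length(p)] else NULL
  sex_ok <- is.null(sex) ||
    (sex == "m" && stratum == "male") || (sex == "f" && stratum == "female")
  par_ok && sex_ok
}

#' Fit the allelic TRD model
#'
#' Estimates the active TRD parameters from resolved transmission counts.
#' With `method = "auto"` the exact conjugate posterior (Beta on
#' p = 0.5 + alpha) is used whenever every parameter reduces to an
#' independent binomial (no ambiguous mixture class); otherwise a
#' Metropolis-within-Gibbs chain samples the joint posterior under uniform
#' (-0.5, 0.5) priors.
#'
#' @param counts a [transmission_counts()] or a list of them (one per
#'   offspring-sex stratum).
#' @param spec a [trd_model_spec()]; defaults to pooled dam-TRD.
#' @param cfg an [mcmc_config()].
#' @param method `"auto"`, `"exact"` or `"mcmc"`.
#' @param id identifier carried into the result.
#' @param null_class if `TRUE`, attach the empirical-null random-TRD class
#'   (see [empirical_null_class()]).
#' @param n_null_reps replicates for the empirical null.
#' @return An object of class `trd_result`.
#' @export
fit_allelic <- function(counts, spec = trd_model_spec("alpha_d"),
                        cfg = mcmc_config(), method = c("auto", "exact", "mcmc"),
                        id = NA_character_, null_class = FALSE,
                        n_null_reps = 1e6) {
  method <- match.arg(method)
  if (inherits(counts, "transmission_counts")) counts <- list(counts)
  strata <- vapply(counts, function(x) x$stratum, "")
  if (anyDuplicated(strata)) stop("duplicate strata in counts")

  # per-parameter resolved counts: sum over (parent, stratum) cells it governs
  cells <- list()
  for (ct in counts) for (parent in c("dam", "sire")) {
    na <- ct[[paste0("n_a_", parent)]]
    nb <- ct[[paste0("n_b_", parent)]]
    amb <- if (parent == "dam") ct$n_ambiguous else 0L  # counted once
    if (na + nb > 0L || (parent == "dam" && ct$n_ambiguous > 0L))
      cells[[length(cells) + 1L]] <- list(parent = parent,
                                          stratum = ct$stratum,
                                          n_a = na, n_b = nb)
  }
  par_of <- function(parent, stratum)
    Filter(function(p) param_applies(p, parent, stratum), spec$params)
  # map each cell to its governing parameter (at most one per parent role)
  cell_par <- lapply(cells, function(cl) {
    ps <- par_of(cl$parent, cl$stratum)
    if (length(ps) > 1L)
      stop("parameters ", paste(ps, collapse = ", "),
           " both govern ", cl$parent, "/", cl$stratum, " transmissions")
    if (length(ps)) ps else NA_character_
  })

  amb_by_stratum <- vapply(counts, function(x) x$n_ambiguous, 0L)
  names(amb_by_stratum) <- strata
  has_amb <- sum(amb_by_stratum) > 0L

  n_informative <- sum(vapply(counts, function(x) x$n_informative, 0L))
  sum_counts <- function(param, side) {
    tot <- 0L
    for (i in seq_along(cells))
      if (identical(cell_par[[i]], param)) tot <- tot + cells[[i]][[side]]
    tot
  }
  na_p <- vapply(spec$params, sum_counts, 0L, side = "n_a")
  nb_p <- vapply(spec$params, sum_counts, 0L, side = "n_b")

  if (n_informative == 0L) {
    res <- trd_result(id = id, region = spec$region,
                      params = data.frame(param = spec$params,
                                          post_mean = NA_real_,
                                          post_sd = NA_real_,
                                          log10_bf = 0,
                                          stringsAsFactors = FALSE),
                      counts = counts, method = "none",
                      flag = "no informative transmissions")
    return(res)
  }

  reducible <- !has_amb
  if (method == "exact" && !reducible)
    stop("model has an ambiguous mixture class; no exact posterior")
  use_exact <- method == "exact" || (method == "auto" && reducible)

  if (use_exact) {
    a <- na_p + 1; b <- nb_p + 1
    pm <- a / (a + b) - 0.5
    psd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    bf <- vapply(seq_along(spec$params), function(i)
      log10_bf_counts(na_p[i], nb_p[i]), 0)
    pdf <- data.frame(param = spec$params, post_mean = pm, post_sd = psd,
                      log10_bf = bf, stringsAsFactors = FALSE)
    samples <- NULL
    meth <- "exact"
  } else {
    sam <- allelic_mcmc(spec$params, cells, cell_par, amb_by_stratum,
                        par_of, cfg)
    pdf <- data.frame(param = spec$params,
                      post_mean = colMeans(sam),
                      post_sd = apply(sam, 2, stats::sd),
                      log10_bf = apply(sam, 2, log10_bf_samples,
                                       lower = -0.5, upper = 0.5),
                      stringsAsFactors = FALSE)
    samples <- sam
    meth <- "mcmc"
  }
  # under-represented offspring: carriers of the disfavoured allele
  pdf$n_underrepresented <- ifelse(is.na(pdf$post_mean), NA_integer_,
                                   ifelse(pdf$post_mean > 0, nb_p, na_p))
  res <- trd_result(id = id, region = spec$region, params = pdf,
                    counts = counts, method = meth, samples = samples)
  if (null_class) {
    cls <- vapply(seq_along(spec$params), function(i) {
      n <- na_p[i] + nb_p[i]
      if (n == 0L) return(NA_character_)
      empirical_null_class(pdf$post_mean[i], n, n_reps = n_null_reps,
                           seed = cfg$seed)
    }, "")
    res$params$random_trd_class <- cls
  }
  res
}

# Metropolis-within-Gibbs for the allelic model. Each active parameter is
# updated with a reflecting random-walk proposal; the log posterior is
# binomial over resolved cells plus the AB x AB -> AB mixture per stratum.
allelic_mcmc <- function(params, cells, cell_par, amb_by_stratum, par_of, cfg) {
  set.seed(cfg$seed)
  k <- length(params)
  theta <- stats::setNames(rep(0, k), params)

  # precompute per-parameter totals and mixture structure
  na_p <- nb_p <- stats::setNames(rep(0L, k), params)
  for (i in seq_along(cells)) {
    p <- cell_par[[i]]
    if (is.na(p)) next
    na_p[p] <- na_p[p] + cells[[i]]$n_a
    nb_p[p] <- nb_p[p] + cells[[i]]$n_b
  }
  amb <- amb_by_stratum[amb_by_stratum > 0L]
  amb_pars <- lapply(names(amb), function(st)
    list(n = unname(amb[st]),
         sire = { p <- par_of("sire", st); if (length(p)) p else NA },
         dam = { p <- par_of("dam", st); if (length(p)) p else NA }))

  logpost <- function(th) {
    lp <- sum(na_p * log(0.5 + th[params]) + nb_p * log(0.5 - th[params]))
    for (a in amb_pars) {
      ps <- if (is.na(a$sire)) 0 else th[[a$sire]]
      pd <- if (is.na(a$dam)) 0 else th[[a$dam]]
      lp <- lp + a$n * log((0.5 + ps) * (0.5 - pd) + (0.5 - ps) * (0.5 + pd))
    }
    lp
  }

  run_mwg(logpost, theta, lower = -0.5, upper = 0.5, cfg = cfg,
          init_scale = cfg$proposal_sd)
}

# Metropolis-within-Gibbs with reflecting random-walk proposals, adapted
# during burn-in (Robbins-Monro toward 44% acceptance). During burn-in the
# chain also learns per-parameter Beta approximations on the bounded
# support; after burn-in each update mixes the frozen random walk with an
# independence proposal from that Beta, which raises the effective sample
# size substantially (near-iid draws when the approximation is good) while
# remaining a valid MH kernel.
run_mwg <- function(logpost, theta, lower, upper, cfg, init_scale,
                    ind_prob = 0.9) {
  k <- length(theta)
  params <- names(theta)
  n_keep <- cfg$iterations - cfg$burn_in
  out <- matrix(NA_real_, n_keep, k, dimnames = list(NULL, params))
  lp_cur <- logpost(theta)
  eps <- 1e-9
  width <- upper - lower
  scales <- rep(init_scale, k)
  ind_a <- ind_b <- rep(NA_real_, k)

  # accumulate burn-in moments for the independence proposal
  bi_n <- 0L
  bi_sum <- bi_sumsq <- rep(0, k)

  for (it in seq_len(cfg$iterations)) {
    use_ind <- it > cfg$burn_in & !is.na(ind_a)
    for (j in seq_len(k)) {
      prop <- theta
      if (use_ind[j] && stats::runif(1) < ind_prob) {
        u_prop <- stats::rbeta(1, ind_a[j], ind_b[j])
        prop[j] <- lower + u_prop * width
        u_cur <- (theta[j] - lower) / width
        lq <- stats::dbeta(u_cur, ind_a[j], ind_b[j], log = TRUE) -
          stats::dbeta(u_prop, ind_a[j], ind_b[j], log = TRUE)
      } else {
        prop[j] <- reflect_bounds(theta[j] + stats::rnorm(1, 0, scales[j]),
                                  lower + eps, upper - eps)
        lq <- 0
      }
      lp_prop <- logpost(prop)
      acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur + lq
      if (acc) {
        theta <- prop
        lp_cur <- lp_prop
      }
      if (it <= cfg$burn_in)
        scales[j] <- min(width,
                         exp(log(scales[j]) + ((acc) - 0.44) / sqrt(it)))
    }
    if (it <= cfg$burn_in && it > cfg$burn_in %/% 2L) {
      u <- (theta - lower) / width
      bi_sum <- bi_sum + u
      bi_sumsq <- bi_sumsq + u^2
      bi_n <- bi_n + 1L
      if (it == cfg$burn_in && bi_n > 50L) {
        m <- bi_sum / bi_n
        v <- pmax(bi_sumsq / bi_n - m^2, 1e-12) * 1.5  # fattened proposal
        s <- m * (1 - m) / v - 1
        ok <- s > 0 & m > 0 & m < 1
        ind_a[ok] <- (m * s)[ok]
        ind_b[ok] <- ((1 - m) * s)[ok]
      }
    }
    if (it > cfg$burn_in) out[it - cfg$burn_in, ] <- theta
  }
  out
}

# fold x back into [lo, hi] by reflection (triangle wave, O(1))
reflect_bounds <- function(x, lo, hi) {
  w <- hi - lo
  r <- (x - lo) %% (2 * w)
  lo + min(r, 2 * w - r)
}

#' Fit the genotypic (recessive) TRD model
#'
#' Offspring-genotype probabilities within each mating class are the
#' Mendelian expectations reweighted by genotype factors
#' `1 + alpha_g` (AA), `1 + delta_g` (AB) and `1 - alpha_g` (BB),
#' renormalized per class. Priors are uniform on (-1, 1) for both
#' parameters (all weights are then non-negative). The recessive-lethal
#' signature is `alpha_g < 0` compensated by `delta_g > 0`.
#'
#' @param table a `mating_genotype_table` (see
#'   [recessive_category_counts()] / [recessive_table()]).
#' @param cfg an [mcmc_config()].
#' @param id identifier carried into the result.
#' @return A `trd_result` with parameters `alpha_g` and `delta_g`.
#' @export
fit_genotypic <- function(table, cfg = mcmc_config(), id = NA_character_) {
  n_aa <- sum(table$n[table$mating == "AAxAB" & table$offspring == "AA"])
  n_ab1 <- sum(table$n[table$mating == "AAxAB" & table$offspring == "AB"])
  n_ab2 <- sum(table$n[table$mating == "BBxAB" & table$offspring == "AB"])
  n_bb <- sum(table$n[table$mating == "BBxAB" & table$offspring == "BB"])
  if (n_aa + n_ab1 + n_ab2 + n_bb == 0L) {
    return(trd_result(id = id, region = "heterosomal",
                      params = data.frame(param = c("alpha_g", "delta_g"),
                                          post_mean = NA_real_,
                                          post_sd = NA_real_, log10_bf = 0,
                                          stringsAsFactors = FALSE),
                      counts = list(), method = "none",
                      flag = "no informative offspring"))
  }
  sam <- genotypic_mcmc(n_aa, n_ab1, n_ab2, n_bb, cfg)
  pdf <- data.frame(param = c("alpha_g", "delta_g"),
                    post_mean = colMeans(sam),
                    post_sd = apply(sam, 2, stats::sd),
                    log10_bf = apply(sam, 2, log10_bf_samples,
                                     lower = -1, upper = 1),
                    stringsAsFactors = FALSE)
  # genotype class observed less often than its Mendelian expectation
  pdf$n_underrepresented <- c(if (pdf$post_mean[1] < 0) n_aa else n_bb,
                              NA_integer_)
  res <- trd_result(id = id, region = "heterosomal", params = pdf,
                    counts = list(), method = "mcmc", samples = sam)
  res$table <- table
  res
}

genotypic_loglik <- function(a, d, n_aa, n_ab1, n_ab2, n_bb) {
  w_aa <- 1 + a; w_ab <- 1 + d; w_bb <- 1 - a
  n_aa * log(w_aa / (w_aa + w_ab)) + n_ab1 * log(w_ab / (w_aa + w_ab)) +
    n_ab2 * log(w_ab / (w_ab + w_bb)) + n_bb * log(w_bb / (w_ab + w_bb))
}

genotypic_mcmc <- function(n_aa, n_ab1, n_ab2, n_bb, cfg) {
  set.seed(cfg$seed)
  theta <- c(alpha_g = 0, delta_g = 0)
  ll <- function(th) genotypic_loglik(th[1], th[2], n_aa, n_ab1, n_ab2, n_bb)
  run_mwg(ll, theta, lower = -1, upper = 1, cfg = cfg,
          init_scale = 2 * cfg$proposal_sd)
}

#' Savage-Dickey Bayes factor from transmission counts
#'
#' For a binomial-reducible allelic model the posterior of
#' p = 0.5 + alpha is Beta(n_a + 1, n_b + 1) and the prior density at the
#' Mendelian null p = 0.5 equals 1, so the Bayes factor in favour of TRD is
#' `1 / dbeta(0.5, n_a + 1, n_b + 1)`. With no data the Bayes factor is 1.
#'
#' @param n_a,n_b resolved A and B transmission counts.
#' @return `log10_bf_counts()` returns the log10 Bayes factor;
#'   `bayes_factor()` returns it for a fitted result's parameters.
#' @export
log10_bf_counts <- function(n_a, n_b) {
  if (n_a + n_b == 0) return(0)
  -stats::dbeta(0.5, n_a + 1, n_b + 1, log = TRUE) / log(10)
}

#' Savage-Dickey Bayes factor from posterior samples
#'
#' Estimates the posterior ordinate at the null (0) by moment-matching a
#' Beta density on the parameter's bounded support to the post-burn-in
#' samples, then takes the prior-to-posterior density ratio. The parametric
#' ordinate reaches the far tails where a kernel estimate would return zero;
#' on binomial-reducible models the posterior is exactly Beta, so the
#' estimate agrees with [log10_bf_counts()] up to Monte-Carlo error.
#'
#' @param samples numeric vector of posterior draws of one parameter.
#' @param lower,upper prior support bounds (prior is uniform on them).
#' @return log10 Bayes factor in favour of the alternative.
#' @export
log10_bf_samples <- function(samples, lower = -0.5, upper = 0.5) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 10L) return(0)
  u <- (samples - lower) / (upper - lower)
  m <- mean(u); v <- stats::var(u)
  if (v <= 0) return(Inf)
  # method-of-moments Beta fit on (0,1)
  s <- m * (1 - m) / v - 1
  a <- m * s; b <- (1 - m) * s
  u0 <- (0 - lower) / (upper - lower)
  post_ord <- stats::dbeta(u0, a, b) / (upper - lower)
  prior_ord <- 1 / (upper - lower)
  log10(prior_ord) - log10(post_ord)
}

#' @rdname log10_bf_counts
#' @param result a `trd_result`.
#' @export
bayes_factor <- function(result) {
  stats::setNames(result$params$log10_bf, result$params$param)
}

# cache of sorted null |alpha_hat| vectors, keyed by "n:reps:seed"
.null_cache <- new.env(parent = emptyenv())

#' Empirical-null random-TRD probability class
#'
#' Simulates transmissions under the Mendelian ratio (alpha = 0) with the
#' observed number of informative transmissions, computes the posterior-mean
#' alpha of each replicate, and reports the upper-tail probability class of
#' the observed |alpha| among the printed classes
#' \{<=0.001, <=0.01, <=0.1, <=1, <=5, >5\} (percent). Null draws are cached
#' by informative-count bin (3 significant digits), so repeated markers with
#' similar support reuse one reference distribution.
#'
#' @param alpha_hat observed posterior-mean alpha.
#' @param n_informative resolved transmissions behind the estimate.
#' @param n_reps Monte-Carlo replicates (>= 1e6 resolves the finest class).
#' @param seed RNG seed for the null draws.
#' @return A class label string, e.g. `"<=0.001"`.
#' @export
empirical_null_class <- function(alpha_hat, n_informative, n_reps = 1e6,
                                 seed = 1L) {
  if (is.na(alpha_hat) || n_informative == 0L)
    return(NA_character_)
  n_bin <- max(1L, as.integer(signif(n_informative, 3)))
  key <- sprintf("%d:%g:%d", n_bin, n_reps, seed)
  if (is.null(.null_cache[[key]])) {
    old <- .Random.seed_save()
    set.seed(seed)
    x <- stats::rbinom(n_reps, n_bin, 0.5)
    .Random.seed_restore(old)
    .null_cache[[key]] <- sort(abs((x + 1) / (n_bin + 2) - 0.5))
  }
  nulls <- .null_cache[[key]]
  # upper-tail probability of |alpha_hat| among null replicates
  p <- (length(nulls) - findInterval(abs(alpha_hat) - 1e-12, nulls)) /
    length(nulls)
  random_trd_class(100 * p)
}

# percentage -> printed class label
random_trd_class <- function(pct) {
  cuts <- c(0.001, 0.01, 0.1, 1, 5)
  i <- which(pct <= cuts)[1]
  if (is.na(i)) ">5" else paste0("<=", format(cuts[i], scientific = FALSE))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' TRD result container
#'
#' @param id marker or window identifier.
#' @param region region the model applies to.
#' @param params `data.frame` with one row per parameter: `param`,
#'   `post_mean`, `post_sd`, `log10_bf`, optionally `n_underrepresented` and
#'   `random_trd_class`.
#' @param counts list of supporting [transmission_counts()].
#' @param method `"exact"`, `"mcmc"` or `"none"`.
#' @param samples optional matrix of post-burn-in draws.
#' @param flag optional quality flag.
#' @return An object of class `trd_result`.
#' @export
trd_result <- function(id, region, params, counts, method,
                       samples = NULL, flag = NULL) {
  structure(list(id = id, region = region, params = params, counts = counts,
                 method = method, samples = samples, flag = flag),
            class = "trd_result")
}

#' @export
print.trd_result <- function(x, ...) {
  cat(sprintf("trd_result %s [%s, %s]\n", x$id, x$region, x$method))
  print(x$params, row.names = FALSE)
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' @export
as.data.frame.trd_result <- function(x, ...) {
  p <- x$params
  ct <- if (length(x$counts)) x$counts[[1]] else transmission_counts()
  n_a <- sum(vapply(x$counts, function(c) c$n_a_dam + c$n_a_sire, 0L))
  n_b <- sum(vapply(x$counts, function(c) c$n_b_dam + c$n_b_sire, 0L))
  data.frame(id = x$id, region = x$region,
             stratum = if (length(x$counts) == 1L) ct$stratum else "pooled",
             param = p$param, post_mean = p$post_mean, post_sd = p$post_sd,
             log10_bf = p$log10_bf,
             n_a = if (length(x$counts)) n_a else NA_integer_,
             n_b = if (length(x$counts)) n_b else NA_integer_,
             n_ambiguous = sum(vapply(x$counts, function(c) c$n_ambiguous, 0L)),
             n_informative = sum(vapply(x$counts,
                                        function(c) c$n_informative, 0L)),
             n_het_sires = sum(vapply(x$counts, function(c) c$n_het_sires, 0L)),
             n_het_dams = sum(vapply(x$counts, function(c) c$n_het_dams, 0L)),
             n_underrepresented = if ("n_underrepresented" %in% names(p))
               p$n_underrepresented else NA_integer_,
             random_trd_class = if ("random_trd_class" %in% names(p))
               p$random_trd_class else NA_character_,
             stringsAsFactors = FALSE)
}
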