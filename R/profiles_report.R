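# Cross-marker descriptive summaries: the opposite sire-TRD decay profile
# along the pseudoautosomal region, LD decay by region class, and the TRD
# pattern taxonomy report.

#' Opposite sire-TRD decay profile
#'
#' Orders pseudoautosomal markers by distance from the pseudoautosomal
#' boundary, reports the male- and female-offspring sire-TRD posterior
#' means, flags markers with the opposite-TRD criterion (decisive Bayes
#' factor in both sexes, opposite signs), and fits a non-increasing
#' (isotonic) trend to the mean |alpha| against distance. Under X/Y linkage
#' at the boundary the profile starts near |alpha| = 0.5 and decays as
#' recombination accumulates.
#'
#' @param results `data.frame` of per-marker results (long format, as from
#'   [results_table()]) containing parameters `alpha_s_m` and `alpha_s_f`
#'   with columns `id`, `param`, `post_mean`, `log10_bf`, and a `pos`
#'   column in bp.
#' @param boundary_bp pseudoautosomal boundary position (default
#'   143,865,210).
#' @param log10_bf_min decisive-evidence threshold (default 2).
#' @return A `data.frame` of class `decay_profile`: one row per marker with
#'   both alphas, distance to the boundary, the opposite-TRD flag and the
#'   isotonic fit `iso_abs_alpha`.
#' @export
trd_decay_profile <- function(results, boundary_bp = 143865210,
                              log10_bf_min = 2) {
  need <- c("id", "param", "post_mean", "log10_bf", "pos")
  stopifnot(all(need %in% names(results)))
  rm_ <- results[results$param == "alpha_s_m", ]
  rf_ <- results[results$param == "alpha_s_f", ]
  ids <- intersect(rm_$id, rf_$id)
  if (!length(ids))
    return(structure(data.frame(id = character(), pos = integer(),
                                distance = numeric(), alpha_s_m = numeric(),
                                alpha_s_f = numeric(), opposite = logical(),
                                iso_abs_alpha = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("decay_profile", "data.frame")))
  im <- match(ids, rm_$id); fm <- match(ids, rf_$id)
  out <- data.frame(id = ids, pos = rm_$pos[im],
                    distance = rm_$pos[im] - boundary_bp,
                    alpha_s_m = rm_$post_mean[im],
                    alpha_s_f = rf_$post_mean[fm],
                    bf_m = rm_$log10_bf[im], bf_f = rf_$log10_bf[fm],
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  out$opposite <- !is.na(out$alpha_s_m) & !is.na(out$alpha_s_f) &
    sign(out$alpha_s_m) * sign(out$alpha_s_f) == -1 &
    out$bf_m >= log10_bf_min & out$bf_f >= log10_bf_min
  ab <- (abs(out$alpha_s_m) + abs(out$alpha_s_f)) / 2
  ok <- !is.na(ab)
  out$iso_abs_alpha <- NA_real_
  if (sum(ok) >= 2) {
    # isotone non-increasing fit: isoreg on negated values
    ir <- stats::isoreg(out$distance[ok], -ab[ok])
    out$iso_abs_alpha[ok] <- -ir$yf
  } else out$iso_abs_alpha[ok] <- ab[ok]
  rownames(out) <- NULL
  class(out) <- c("decay_profile", "data.frame")
  out
}

#' LD decay by region class
#'
#' Computes squared allele-frequency-corrected correlation (r^2) between
#' marker pairs, from phased haplotypes when available or genotype dosages
#' otherwise (composite LD), averages it within bp-distance bins and
#' region classes. Monomorphic markers are excluded.
#'
#' @param x a matrix of haplotypes or genotype dosages (markers x samples),
#'   or a `genotype_table`.
#' @param labels per-marker region class labels.
#' @param pos per-marker bp positions (taken from the map for a
#'   `genotype_table`).
#' @param breaks distance bin breaks in bp.
#' @param max_pairs cap on sampled marker pairs per class.
#' @return A `data.frame` with columns `region`, `bin_mid`, `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay <- function(x, labels, pos = NULL,
                     breaks = c(0, 1e5, 5e5, 1e6, 5e6, 1e7, 5e7, 1.5e8),
                     max_pairs = 20000L) {
  if (inherits(x, "genotype_table")) {
    pos <- x$map$pos
    x <- x$calls
  }
  stopifnot(nrow(x) == length(labels), nrow(x) == length(pos))
  out <- list()
  for (cls in unique(labels)) {
    i <- which(labels == cls)
    v <- apply(x[i, , drop = FALSE], 1, stats::var, na.rm = TRUE)
    i <- i[!is.na(v) & v > 0]
    if (length(i) < 2L) next
    pairs <- utils::combn(seq_along(i), 2)
    if (ncol(pairs) > max_pairs)
      pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
    r2 <- numeric(ncol(pairs))
    dd <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      a <- i[pairs[1, k]]; b <- i[pairs[2, k]]
      r <- stats::cor(x[a, ], x[b, ], use = "pairwise.complete.obs")
      r2[k] <- r^2
      dd[k] <- abs(pos[a] - pos[b])
    }
    bin <- cut(dd, breaks, include.lowest = TRUE)
    agg <- tapply(r2, bin, mean, na.rm = TRUE)
    cnt <- tapply(r2, bin, function(z) sum(!is.na(z)))
    mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
    out[[cls]] <- data.frame(region = cls, bin_mid = mids,
                             mean_r2 = as.numeric(agg),
                             n_pairs = as.integer(ifelse(is.na(cnt), 0, cnt)),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify significant results into TRD patterns
#'
#' Assigns each marker one primary pattern by precedence: opposite-sex
#' sire-TRD (decisive in both sexes, opposite signs) over single-sex
#' sire-TRD (decisive in one sex, near-null evidence in the other) over
#' unspecific sire-TRD, alongside dam-TRD and recessive counts. The
#' near-null bound for the non-significant sex is `log10_bf_null`
#' (default 0.5, i.e. BF < 3.16).
#'
#' @param sire_results long-format results with `alpha_s_m`/`alpha_s_f`
#'   rows (may be `NULL`).
#' @param dam_results long-format dam-TRD results (may be `NULL`).
#' @param recessive_results [recessive_scan()] output (may be `NULL`).
#' @param log10_bf_min decisive threshold (2).
#' @param log10_bf_null near-null threshold for the opposite sex (0.5).
#' @return A `data.frame` of pattern counts.
#' @export
trd_pattern_summary <- function(sire_results = NULL, dam_results = NULL,
                                recessive_results = NULL,
                                log10_bf_min = 2, log10_bf_null = 0.5) {
  n_opp <- n_male <- n_female <- n_unspec <- 0L
  if (!is.null(sire_results) && nrow(sire_results)) {
    rm_ <- sire_results[sire_results$param == "alpha_s_m", ]
    rf_ <- sire_results[sire_results$param == "alpha_s_f", ]
    ids <- union(rm_$id, rf_$id)
    for (id in ids) {
      am <- rm_[rm_$id == id, ]; af <- rf_[rf_$id == id, ]
      dm <- nrow(am) == 1 && !is.na(am$log10_bf) && am$log10_bf >= log10_bf_min
      df <- nrow(af) == 1 && !is.na(af$log10_bf) && af$log10_bf >= log10_bf_min
      if (dm && df &&
          sign(am$post_mean) * sign(af$post_mean) == -1) n_opp <- n_opp + 1L
      else if (dm && nrow(af) == 1 && af$log10_bf < log10_bf_null)
        n_male <- n_male + 1L
      else if (df && nrow(am) == 1 && am$log10_bf < log10_bf_null)
        n_female <- n_female + 1L
      else if (dm || df) n_unspec <- n_unspec + 1L
    }
  }
  n_dam <- if (!is.null(dam_results) && nrow(dam_results))
    length(unique(dam_results$id[dam_results$log10_bf >= log10_bf_min &
                                   grepl("^alpha_d", dam_results$param)]))
  else 0L
  n_rec <- if (!is.null(recessive_results) && nrow(recessive_results)) {
    rr <- recessive_results
    length(unique(rr$id[rr$param == "alpha_g" & !is.na(rr$post_mean) &
                          rr$post_mean < 0 & rr$log10_bf >= log10_bf_min]))
  } else 0L
  data.frame(pattern = c("opposite_sire_trd", "sire_trd_male_only",
                         "sire_trd_female_only", "sire_trd_unspecific",
                         "dam_trd", "recessive"),
             n = c(n_opp, n_male, n_female, n_unspec, n_dam, n_rec),
             stringsAsFactors = FALSE)
}

#' Write a run report
#'
#' Writes the pattern summary and any supplied tables as TSV files into
#' `dir`, in the layout of the per-marker and per-window result tables.
#' Re-running with the same inputs overwrites the same files (idempotent).
#'
#' @param dir output directory.
#' @param pattern_summary a [trd_pattern_summary()] result.
#' @param tables named list of result `data.frame`s to write alongside.
#' @param config,seed recorded in each table header.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(dir, pattern_summary, tables = list(),
                         config = NULL, seed = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  paths <- character(0)
  p <- file.path(dir, "pattern_summary.tsv")
  write_results(pattern_summary, p, config = config, seed = seed)
  paths <- c(paths, p)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_results(tables[[nm]], p, config = config, seed = seed)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Plot a decay profile
#'
#' Base-graphics view of the opposite sire-TRD decay: per-marker male and
#' female sire-TRD and the isotonic |alpha| trend against distance from the
#' pseudoautosomal boundary.
#'
#' @param profile a [trd_decay_profile()] result.
#' @param ... passed to [plot()].
#' @export
plot_decay_profile <- function(profile, ...) {
  if (!nrow(profile)) {
    graphics::plot.new()
    return(invisible(NULL))
  }
  d <- profile$distance / 1e6
  graphics::plot(d, profile$alpha_s_m, col = "blue", pch = 16,
                 ylim = c(-0.55, 0.55), xlab = "distance from boundary (Mb)",
                 ylab = expression(alpha[s]), ...)
  graphics::points(d, profile$alpha_s_f, col = "red", pch = 16)
  graphics::lines(d, profile$iso_abs_alpha, lwd = 2)
  graphics::lines(d, -profile$iso_abs_alpha, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(NULL)
}
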