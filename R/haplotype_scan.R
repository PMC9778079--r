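# Deterministic trio phasing, sliding-window haplotype construction with
# biallelic recoding, windowed TRD scans and consolidation of overlapping
# significant windows.

#' Phase offspring alleles from trio structure
#'
#' Rule-based, conservative phasing of each trio's offspring (no statistical
#' imputation): hemizygous male calls at heterosomal markers are trivially
#' maternal; female offspring at heterosomal markers inherit the sire's
#' hemizygous allele as paternal and the remainder as maternal;
#' pseudoautosomal heterozygous calls resolve when at least one parent is
#' homozygous. Sites that no rule resolves stay `NA` and any window touching
#' an unresolved site excludes that trio.
#'
#' @param trioset a [assemble_trios()] result.
#' @param labels character vector of per-marker region labels (from
#'   [classify_markers()]), `"heterosomal"` or `"pseudoautosomal"`.
#' @return A list of class `phased_trio_set` with marker x trio matrices
#'   `paternal` and `maternal` holding allele codes (0 = A, 1 = B, `NA` =
#'   unresolved; the paternal entry of a male heterosomal site is `NA`
#'   because no paternal X exists there).
#' @export
phase_trios <- function(trioset, labels) {
  stopifnot(inherits(trioset, "trio_set"))
  n_mark <- nrow(trioset$gt$map)
  stopifnot(length(labels) == n_mark)
  tr <- trioset$trios
  cc <- trioset$gt$calls
  n_tr <- nrow(tr)
  pat <- mat <- matrix(NA_integer_, n_mark, n_tr)
  sire <- cc[, tr$sire_col, drop = FALSE]
  dam <- cc[, tr$dam_col, drop = FALSE]
  off <- cc[, tr$off_col, drop = FALSE]
  male <- matrix(rep(tr$offspring_sex == "male", each = n_mark), n_mark, n_tr)
  female <- matrix(rep(tr$offspring_sex == "female", each = n_mark), n_mark, n_tr)
  het <- matrix(labels == "heterosomal", n_mark, n_tr)
  par <- matrix(labels == "pseudoautosomal", n_mark, n_tr)

  # heterosomal male: single maternal allele from the 0/2 call
  i <- het & male & !is.na(off) & off != 1L
  mat[i] <- off[i] %/% 2L

  # heterosomal female: paternal = sire hemizygous allele, maternal = rest
  i <- het & female & !is.na(off) & !is.na(sire) & sire != 1L
  sa <- sire %/% 2L
  ma <- off - sa
  ok <- i & !is.na(ma) & (ma == 0L | ma == 1L)
  pat[ok] <- sa[ok]
  mat[ok] <- ma[ok]

  # pseudoautosomal homozygous offspring: both alleles known
  i <- par & !is.na(off) & off != 1L
  pat[i] <- off[i] %/% 2L
  mat[i] <- off[i] %/% 2L

  # pseudoautosomal heterozygous offspring, one parent homozygous
  i <- par & !is.na(off) & off == 1L & !is.na(sire) & sire != 1L
  pat[i] <- sire[i] %/% 2L
  mat[i] <- 1L - sire[i] %/% 2L
  i <- par & !is.na(off) & off == 1L & !is.na(dam) & dam != 1L &
    (is.na(sire) | sire == 1L)
  mat[i] <- dam[i] %/% 2L
  pat[i] <- 1L - dam[i] %/% 2L

  structure(list(paternal = pat, maternal = mat, trioset = trioset,
                 labels = labels), class = "phased_trio_set")
}

#' @export
print.phased_trio_set <- function(x, ...) {
  cat(sprintf("phased_trio_set: %d markers x %d trios (maternal resolved %.1f%%)\n",
              nrow(x$maternal), ncol(x$maternal),
              100 * mean(!is.na(x$maternal))))
  invisible(x)
}

# haplotype string keys for a window's allele matrix (markers x trios)
hap_key <- function(m) apply(m, 2, paste, collapse = "")

# windows of a given size within one contiguous same-label run
window_starts <- function(labels, size, region) {
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- integer(0)
  for (r in seq_along(runs$values)) {
    if (runs$values[r] != region) next
    if (runs$lengths[r] < size) next
    out <- c(out, seq.int(starts[r], ends[r] - size + 1L))
  }
  out
}

#' Sliding-window biallelic haplotype TRD scan
#'
#' Slides windows of the given sizes (step one marker) across the region,
#' recodes each distinct window haplotype above the frequency floor in turn
#' as pseudo-allele A versus all other haplotypes pooled as B, and analyzes
#' each pseudo-marker with the dam-transmission machinery: the transmitted
#' maternal haplotype comes from the phased offspring and the dam's other
#' haplotype is the dam genotype minus the transmitted one, so a dam is
#' heterozygous for a pseudo-marker when exactly one of her two haplotypes
#' matches the focal haplotype. Windows with fewer than `min_het_dams`
#' heterozygous dams or fewer than `min_informative` informative offspring
#' are discarded. Windows spanning a region-label boundary are skipped.
#'
#' @param phased a [phase_trios()] result.
#' @param sizes window sizes in markers (default `c(2, 4, 10, 20)`).
#' @param region region to scan (default `"heterosomal"`).
#' @param stratum offspring-sex stratum.
#' @param cfg an [mcmc_config()] (used when `method = "mcmc"`).
#' @param method fitting method passed to [fit_allelic()].
#' @param min_het_dams,min_informative window retention filters (10 and 50).
#' @param freq_floor minimum haplotype frequency recoded (default 0.005).
#' @param null_class,n_null_reps empirical-null options (see
#'   [empirical_null_class()]).
#' @return A `data.frame` with one row per retained pseudo-marker: window
#'   coordinates (`"start_bp:end_bp"` id), window size, haplotype string,
#'   counts, posterior summary, log10 BF and optional random-TRD class.
#' @export
scan_windows <- function(phased, sizes = c(2L, 4L, 10L, 20L),
                         region = "heterosomal", stratum = "pooled",
                         cfg = mcmc_config(), method = "auto",
                         min_het_dams = 10L, min_informative = 50L,
                         freq_floor = 0.005, null_class = FALSE,
                         n_null_reps = 1e6) {
  ts <- phased$trioset
  map <- ts$gt$map
  rows_out <- list()
  sex <- ts$trios$offspring_sex
  in_stratum <- if (stratum == "pooled") sex %in% c("male", "female")
                else sex == stratum
  dam_calls <- ts$gt$calls[, ts$trios$dam_col, drop = FALSE]

  for (size in sizes) {
    for (st in window_starts(phased$labels, size, region)) {
      idx <- st:(st + size - 1L)
      mhap <- phased$maternal[idx, , drop = FALSE]
      usable <- in_stratum & colSums(is.na(mhap)) == 0L &
        colSums(is.na(dam_calls[idx, , drop = FALSE])) == 0L
      if (!any(usable)) next
      m <- mhap[, usable, drop = FALSE]
      other <- dam_calls[idx, usable, drop = FALSE] - m
      valid <- colSums(other == 0L | other == 1L) == size
      if (!any(valid)) next
      m <- m[, valid, drop = FALSE]
      other <- other[, valid, drop = FALSE]
      dam_ids <- ts$trios$dam_id[usable][valid]
      km <- hap_key(m)
      ko <- hap_key(other)
      freq <- table(c(km, ko)) / (2 * length(km))
      haps <- names(freq)[freq >= freq_floor]
      for (h in haps) {
        is_m <- km == h
        is_o <- ko == h
        inf <- xor(is_m, is_o)          # dam heterozygous for this haplotype
        n_a <- sum(inf & is_m)
        n_b <- sum(inf & !is_m)
        n_het_dams <- length(unique(dam_ids[inf]))
        if (n_het_dams < min_het_dams || (n_a + n_b) < min_informative) next
        ctr <- transmission_counts(n_a_dam = n_a, n_b_dam = n_b,
                                   stratum = stratum,
                                   n_het_dams = n_het_dams)
        fit <- fit_allelic(ctr, trd_model_spec("alpha_d", "heterosomal"),
                           cfg = cfg, method = method,
                           id = sprintf("%d:%d", map$pos[idx[1]],
                                        map$pos[idx[size]]),
                           null_class = null_class,
                           n_null_reps = n_null_reps)
        row <- as.data.frame(fit)
        row$size <- size
        row$start_index <- st
        row$end_index <- st + size - 1L
        row$haplotype <- h
        row$hap_freq <- as.numeric(freq[h])
        rows_out[[length(rows_out) + 1L]] <- row
      }
    }
  }
  if (!length(rows_out)) {
    out <- results_table(list())
    out$size <- integer(0); out$start_index <- integer(0)
    out$end_index <- integer(0); out$haplotype <- character(0)
    out$hap_freq <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows_out)
  rownames(out) <- NULL
  out
}

#' Consolidate overlapping significant windows
#'
#' Smooths each window's log10 Bayes factor along the marker index with a
#' Gaussian kernel, selects significant windows (log10 BF >= `log10_bf_min`
#' and, when present, a random-TRD class at or below `class_max`), groups
#' them by marker-index overlap or adjacency, and reports the member with
#' the maximal smoothed score as each region's representative.
#'
#' @param results a [scan_windows()] result.
#' @param bandwidth Gaussian kernel bandwidth in markers; defaults to the
#'   scan's window size (per size stratum).
#' @param log10_bf_min significance threshold (2 = decisive, BF >= 100).
#' @param class_max most permissive accepted random-TRD class (set `NULL`
#'   to ignore classes).
#' @return A `data.frame` with one row per consolidated region.
#' @export
consolidate <- function(results, bandwidth = NULL, log10_bf_min = 2,
                        class_max = "<=0.001") {
  if (nrow(results) == 0L)
    return(data.frame(region_id = integer(), representative = character(),
                      n_windows = integer(), peak_log10_bf = numeric(),
                      smoothed_score = numeric(), start_index = integer(),
                      end_index = integer(), stringsAsFactors = FALSE))
  classes <- c("<=0.001", "<=0.01", "<=0.1", "<=1", "<=5", ">5")
  res <- results
  res$center <- (res$start_index + res$end_index) / 2

  # per-window smoothed score, computed within each window-size stratum
  res$smoothed <- NA_real_
  for (sz in unique(res$size)) {
    i <- which(res$size == sz)
    h <- bandwidth %||% sz
    d <- outer(res$center[i], res$center[i], `-`) / h
    w <- exp(-0.5 * d^2)
    res$smoothed[i] <- as.numeric(w %*% res$log10_bf[i]) / rowSums(w)
  }

  sig <- res$log10_bf >= log10_bf_min
  if (!is.null(class_max) && "random_trd_class" %in% names(res) &&
      any(!is.na(res$random_trd_class))) {
    sig <- sig & !is.na(res$random_trd_class) &
      match(res$random_trd_class, classes) <= match(class_max, classes)
  }
  sig <- which(sig)
  if (!length(sig))
    return(consolidate(results[0, , drop = FALSE]))

  sg <- res[sig, , drop = FALSE]
  sg <- sg[order(sg$start_index, sg$end_index), , drop = FALSE]
  group <- integer(nrow(sg))
  gid <- 1L
  group[1] <- gid
  cur_end <- sg$end_index[1]
  for (i in seq_len(nrow(sg))[-1]) {
    if (sg$start_index[i] > cur_end + 1L) gid <- gid + 1L
    group[i] <- gid
    cur_end <- max(cur_end, sg$end_index[i])
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(sg)), group), function(ii) {
    g <- sg[ii, , drop = FALSE]
    rep_i <- which.max(g$smoothed)
    data.frame(region_id = group[ii[1]], representative = g$id[rep_i],
               n_windows = nrow(g), peak_log10_bf = max(g$log10_bf),
               smoothed_score = g$smoothed[rep_i],
               start_index = min(g$start_index),
               end_index = max(g$end_index), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Recessive (genotypic) haplotype scan
#'
#' Builds recessive mating-genotype category counts per window pseudo-marker
#' (female offspring, heterosomal region: hemizygous sire haplotype class
#' crossed with dams heterozygous for the focal haplotype) and fits the
#' genotypic TRD model. Reports the observed homozygous-daughter count and
#' its Mendelian expectation, so fully lethal haplotypes stand out as
#' zero-observed categories.
#'
#' @inheritParams scan_windows
#' @param min_class_total minimum offspring across categories to fit.
#' @return A `data.frame`, one row per pseudo-marker and parameter.
#' @export
recessive_scan <- function(phased, sizes = c(2L, 4L, 10L, 20L),
                           cfg = mcmc_config(), min_het_dams = 10L,
                           min_informative = 50L, freq_floor = 0.005,
                           min_class_total = 1L) {
  ts <- phased$trioset
  map <- ts$gt$map
  female <- ts$trios$offspring_sex == "female"
  dam_calls <- ts$gt$calls[, ts$trios$dam_col, drop = FALSE]
  sire_calls <- ts$gt$calls[, ts$trios$sire_col, drop = FALSE]
  rows_out <- list()

  for (size in sizes) {
    for (st in window_starts(phased$labels, size, "heterosomal")) {
      idx <- st:(st + size - 1L)
      mhap <- phased$maternal[idx, , drop = FALSE]
      shap <- sire_calls[idx, , drop = FALSE]
      # sire window haplotype: hemizygous, so all calls homozygous
      sire_ok <- colSums(is.na(shap)) == 0L & colSums(shap == 1L) == 0L
      usable <- female & sire_ok & colSums(is.na(mhap)) == 0L &
        colSums(is.na(dam_calls[idx, , drop = FALSE])) == 0L
      if (!any(usable)) next
      m <- mhap[, usable, drop = FALSE]
      other <- dam_calls[idx, usable, drop = FALSE] - m
      valid <- colSums(other == 0L | other == 1L) == size
      if (!any(valid)) next
      m <- m[, valid, drop = FALSE]
      other <- other[, valid, drop = FALSE]
      shap_v <- shap[, usable, drop = FALSE][, valid, drop = FALSE] %/% 2L
      dam_ids <- ts$trios$dam_id[usable][valid]
      km <- hap_key(m); ko <- hap_key(other); ks <- hap_key(shap_v)
      freq <- table(c(km, ko)) / (2 * length(km))
      haps <- names(freq)[freq >= freq_floor]
      for (h in haps) {
        inf <- xor(km == h, ko == h)    # dam heterozygous for haplotype h
        if (!any(inf)) next
        sire_h <- ks[inf] == h
        off_copies <- (km[inf] == h) + (ks[inf] == h)
        tab <- recessive_table(
          aa_ab_aa = sum(sire_h & off_copies == 2L),
          aa_ab_ab = sum(sire_h & off_copies == 1L),
          bb_ab_ab = sum(!sire_h & off_copies == 1L),
          bb_ab_bb = sum(!sire_h & off_copies == 0L),
          n_het_dams = length(unique(dam_ids[inf])))
        total <- sum(tab$n)
        if (attr(tab, "n_het_dams") < min_het_dams ||
            total < min_informative || total < min_class_total) next
        fit <- fit_genotypic(tab, cfg = cfg,
                             id = sprintf("%d:%d", map$pos[idx[1]],
                                          map$pos[idx[size]]))
        row <- as.data.frame(fit)
        row$size <- size
        row$start_index <- st
        row$end_index <- st + size - 1L
        row$haplotype <- h
        row$n_het_dams <- attr(tab, "n_het_dams")
        row$n_informative <- total
        row$observed_hom <- tab$n[1]
        # Mendelian expectation of homozygous daughters in AA x AB matings
        row$expected_hom <- (tab$n[1] + tab$n[2]) / 2
        rows_out[[length(rows_out) + 1L]] <- row
      }
    }
  }
  if (!length(rows_out)) {
    out <- results_table(list())
    for (cn in c("size", "start_index", "end_index"))
      out[[cn]] <- integer(0)
    out$haplotype <- character(0)
    out$observed_hom <- integer(0)
    out$expected_hom <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows_out)
  rownames(out) <- NULL
  out
}
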