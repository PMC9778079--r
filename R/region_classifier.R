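# Mendelian-inconsistency rates under the two X-chromosome inheritance
# models, marker classification and QC.
#
# The pseudoautosomal model is the standard autosomal check: the offspring
# genotype must be composable from one sire allele and one dam allele. The
# heterosomal model reflects male hemizygosity: a male offspring carries a
# single maternal allele (array-coded 0 or 2; a heterozygous male call is
# itself inconsistent), and a female offspring carries the sire's hemizygous
# allele plus one dam allele (a heterozygous sire call is inconsistent).

# alleles a parent with code g can transmit, as B-copy contributions {0,1}
transmissible <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)

# consistency lookup tables, built once at load time:
# .cons_pseudo[s+1, d+1, o+1]; .cons_hetero[s+1, d+1, o+1, sex(1=male,2=female)]
build_consistency_tables <- function() {
  ps <- array(FALSE, c(3, 3, 3))
  he <- array(FALSE, c(3, 3, 3, 2))
  for (s in 0:2) for (d in 0:2) for (o in 0:2) {
    st <- transmissible[[s + 1L]]
    dt <- transmissible[[d + 1L]]
    ps[s + 1, d + 1, o + 1] <- any(outer(st, dt, `+`) == o)
    # heterosomal, male offspring: one maternal allele, sire ignored
    he[s + 1, d + 1, o + 1, 1] <- (o %% 2L == 0L) && ((o %/% 2L) %in% dt)
    # heterosomal, female offspring: sire must be hemizygous (0 or 2)
    he[s + 1, d + 1, o + 1, 2] <- (s %% 2L == 0L) &&
      any((s %/% 2L) + dt == o)
  }
  list(pseudo = ps, hetero = he)
}
.cons_tab <- build_consistency_tables()

#' Trio Mendelian consistency under an inheritance model
#'
#' Checks a single sire/dam/offspring genotype triple under the
#' pseudoautosomal (autosome-like) or heterosomal (male-hemizygous) model.
#'
#' @param sire,dam,off genotype codes in \{0, 1, 2, NA\} (copies of allele B).
#' @param off_sex `"male"` or `"female"`; required for the heterosomal model.
#' @param model `"pseudoautosomal"` or `"heterosomal"`.
#' @return `"consistent"`, `"inconsistent"` or `"uninformative"` (any missing
#'   member, or unknown offspring sex under the heterosomal model).
#' @export
trio_inconsistency <- function(sire, dam, off, off_sex = "unknown",
                               model = c("pseudoautosomal", "heterosomal")) {
  model <- match.arg(model)
  for (g in list(sire, dam, off))
    if (!is.na(g) && !(g %in% 0:2)) stop("invalid genotype code: ", g)
  if (is.na(sire) || is.na(dam) || is.na(off)) return("uninformative")
  if (model == "pseudoautosomal") {
    ok <- .cons_tab$pseudo[sire + 1L, dam + 1L, off + 1L]
  } else {
    sx <- match(off_sex, c("male", "female"))
    if (is.na(sx)) return("uninformative")
    ok <- .cons_tab$hetero[sire + 1L, dam + 1L, off + 1L, sx]
  }
  if (ok) "consistent" else "inconsistent"
}

# vectorized consistency over trios at one marker: TRUE/FALSE/NA(uninformative)
consistency_vec <- function(sire, dam, off, sex, model) {
  n <- length(off)
  out <- rep(NA, n)
  if (model == "pseudoautosomal") {
    idx <- !is.na(sire) & !is.na(dam) & !is.na(off)
    out[idx] <- .cons_tab$pseudo[cbind(sire[idx] + 1L, dam[idx] + 1L,
                                       off[idx] + 1L)]
  } else {
    sxi <- match(sex, c("male", "female"))
    idx <- !is.na(sire) & !is.na(dam) & !is.na(off) & !is.na(sxi)
    out[idx] <- .cons_tab$hetero[cbind(sire[idx] + 1L, dam[idx] + 1L,
                                       off[idx] + 1L, sxi[idx])]
  }
  out
}

#' Classify markers as pseudoautosomal or heterosomal
#'
#' Computes per-marker Mendelian-inconsistency rates under both inheritance
#' models across informative trios and labels each marker. A marker is
#' heterosomal when its heterosomal inconsistency is below `inc_null` while
#' its pseudoautosomal inconsistency is at least `inc_high`, and conversely;
#' anything else is undetermined. A determinately labeled marker whose label
#' contradicts the unanimous determinate labels of its `k` neighbours on each
#' side is relabeled `discordant-removed` (a likely genotyping artifact or
#' misplaced marker) and excluded from TRD scans. Contiguous runs of
#' same-label determinate markers are numbered as segments.
#'
#' @param trioset a [assemble_trios()] result.
#' @param inc_null upper bound on the inconsistency rate under the matching
#'   model (default 0.01).
#' @param inc_high lower bound on the inconsistency rate under the wrong
#'   model (default 0.05).
#' @param k neighbour window half-width for discordance removal (default 2).
#' @return A `data.frame` of class `marker_classification` with the two
#'   rates, informative-trio counts, male heterozygosity rate, label and
#'   segment id.
#' @export
classify_markers <- function(trioset, inc_null = 0.01, inc_high = 0.05, k = 2L) {
  stopifnot(inherits(trioset, "trio_set"))
  map <- trioset$gt$map
  tr <- trioset$trios
  cc <- trioset$gt$calls
  n_mark <- nrow(map)
  males <- trioset$gt$individuals$sex == "male"

  inc_p <- inc_h <- male_het <- rep(NA_real_, n_mark)
  n_inf_p <- n_inf_h <- integer(n_mark)
  sire_m <- cc[, tr$sire_col, drop = FALSE]
  dam_m <- cc[, tr$dam_col, drop = FALSE]
  off_m <- cc[, tr$off_col, drop = FALSE]
  for (i in seq_len(n_mark)) {
    cp <- consistency_vec(sire_m[i, ], dam_m[i, ], off_m[i, ],
                          tr$offspring_sex, "pseudoautosomal")
    ch <- consistency_vec(sire_m[i, ], dam_m[i, ], off_m[i, ],
                          tr$offspring_sex, "heterosomal")
    n_inf_p[i] <- sum(!is.na(cp))
    n_inf_h[i] <- sum(!is.na(ch))
    inc_p[i] <- if (n_inf_p[i]) mean(!cp, na.rm = TRUE) else NA_real_
    inc_h[i] <- if (n_inf_h[i]) mean(!ch, na.rm = TRUE) else NA_real_
    mg <- cc[i, males]
    male_het[i] <- if (any(!is.na(mg))) mean(mg == 1L, na.rm = TRUE) else NA_real_
  }

  label <- rep("undetermined", n_mark)
  det <- !is.na(inc_p) & !is.na(inc_h)
  label[det & inc_h < inc_null & inc_p >= inc_high] <- "heterosomal"
  label[det & inc_p < inc_null & inc_h >= inc_high] <- "pseudoautosomal"

  # neighbour-consensus discordance removal within each chromosome
  final <- label
  for (ch in unique(map$chrom)) {
    on_ch <- which(map$chrom == ch)
    lab <- label[on_ch]
    for (j in seq_along(on_ch)) {
      if (!(lab[j] %in% c("pseudoautosomal", "heterosomal"))) next
      lo <- if (j > 1) seq.int(max(1L, j - k), j - 1L) else integer(0)
      hi <- if (j < length(lab)) seq.int(j + 1L, min(length(lab), j + k)) else integer(0)
      nb <- lab[c(lo, hi)]
      nb <- nb[nb %in% c("pseudoautosomal", "heterosomal")]
      if (length(nb) >= 2L && all(nb == nb[1]) && nb[1] != lab[j])
        final[on_ch[j]] <- "discordant-removed"
    }
  }

  # segment ids over determinate labels, in map order per chromosome
  segment <- rep(NA_integer_, n_mark)
  seg_id <- 0L
  for (ch in unique(map$chrom)) {
    on_ch <- which(map$chrom == ch)
    prev <- ""
    for (j in on_ch) {
      if (!(final[j] %in% c("pseudoautosomal", "heterosomal"))) next
      if (final[j] != prev) { seg_id <- seg_id + 1L; prev <- final[j] }
      segment[j] <- seg_id
    }
  }

  out <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                    pos = map$pos, n_trios = trioset$n_complete,
                    n_informative_pseudo = n_inf_p,
                    n_informative_hetero = n_inf_h,
                    inc_pseudo = inc_p, inc_hetero = inc_h,
                    male_het_rate = male_het, label = final,
                    segment = segment, stringsAsFactors = FALSE)
  class(out) <- c("marker_classification", "data.frame")
  out
}

#' Apply trio-count and inconsistency QC filters
#'
#' Retains markers with a determinate region label, at least `min_trios`
#' complete trios, and Mendelian inconsistency under their assigned model
#' below `max_inc`. Preliminary marker intake uses `min_trios = 10`; the scan
#' default is 100 trios and < 1\% inconsistency.
#'
#' @param classifications a [classify_markers()] result.
#' @param min_trios minimum complete trios (default 100).
#' @param max_inc maximum inconsistency rate under the assigned model
#'   (default 0.01, exclusive).
#' @return The retained subset of `classifications`.
#' @export
apply_qc <- function(classifications, min_trios = 100L, max_inc = 0.01) {
  cl <- classifications
  own_inc <- ifelse(cl$label == "heterosomal", cl$inc_hetero,
                    ifelse(cl$label == "pseudoautosomal", cl$inc_pseudo,
                           NA_real_))
  keep <- cl$label %in% c("heterosomal", "pseudoautosomal") &
    cl$n_trios >= min_trios & !is.na(own_inc) & own_inc < max_inc
  cl[keep, , drop = FALSE]
}
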