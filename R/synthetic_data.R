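# Forward simulator of sex-chromosome trio genotypes with configurable TRD.
#
# Mechanism: dams transmit one recombinant X per offspring (uniform genetic
# map along the whole chromosome), optionally distorted at injected markers
# or haplotype windows. Sires transmit their intact X heterosomal haplotype
# to daughters and nothing heterosomal to sons; in the pseudoautosomal
# region (PAR) the transmitted chromatid is a recombinant mosaic of the
# sire's X- and Y-borne PAR haplotypes under a genetic map whose distance
# grows away from the pseudoautosomal boundary. When the same allele rides
# the Y-PAR across sires (population X/Y linkage disequilibrium), this
# generates the opposite-sign sire-TRD between male and female offspring
# that decays with distance from the boundary.

#' Simulation configuration
#'
#' Defaults emulate a dairy-cattle-like trio design: a modest number of
#' heavily used sires, one genotyped dam per offspring, markers split
#' between a long heterosomal segment and a short terminal PAR.
#'
#' @param n_sires number of sires (matings assigned round-robin).
#' @param n_trios total sire-dam-offspring trios (one offspring per dam).
#' @param sex_ratio probability an offspring is male.
#' @param n_het_markers,n_par_markers marker counts per segment.
#' @param het_span,par_span bp spans of the heterosomal segment and the PAR
#'   (1-based, defaults matching the bovine X layout with the
#'   pseudoautosomal boundary at 143,865,210 bp).
#' @param freq_range allele-B population frequency range (drawn uniformly
#'   per marker).
#' @param par_map_length sire-meiosis PAR genetic length in Morgans,
#'   increasing linearly with bp distance from the boundary (0.5 M default:
#'   the PAR is a male recombination hotspot with an obligate crossover).
#' @param x_map_length dam-meiosis genetic length in Morgans across the
#'   whole simulated chromosome (uniform per bp).
#' @param y_linked_fraction fraction of sires whose Y-PAR haplotype carries
#'   allele A at every PAR marker (population X/Y LD; 1 gives the clean
#'   opposite sire-TRD signature).
#' @param dam_alpha `data.frame(marker, stratum, alpha)` of injected
#'   dam-TRD: at marker index `marker`, heterozygous dams transmit allele A
#'   with probability 0.5 + alpha to offspring of `stratum` (`"pooled"`,
#'   `"male"`, `"female"`).
#' @param hap_distortion optional `list(markers =, haplotype =, alpha =)`:
#'   dams carrying exactly one copy of `haplotype` (allele codes over marker
#'   indices `markers`) transmit it with probability 0.5 + alpha.
#' @param lethal optional `list(markers =, haplotype =)`: female conceptuses
#'   homozygous for the haplotype are lost and the meiosis redrawn.
#' @param carrier_freq frequency at which a population haplotype is seeded
#'   with the `hap_distortion`/`lethal` haplotype (creates local LD).
#' @param genotyping_error per-call probability of replacement by a random
#'   other code.
#' @param missing_rate per-call missingness probability.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 200L, n_trios = 5000L, sex_ratio = 0.5,
                       n_het_markers = 500L, n_par_markers = 100L,
                       het_span = c(29245, 137034696),
                       par_span = c(143865210, 148816634),
                       freq_range = c(0.2, 0.8),
                       par_map_length = 0.5, x_map_length = 1.5,
                       y_linked_fraction = 1.0,
                       dam_alpha = NULL, hap_distortion = NULL,
                       lethal = NULL, carrier_freq = 0.15,
                       genotyping_error = 0, missing_rate = 0) {
  stopifnot(sex_ratio >= 0, sex_ratio <= 1,
            genotyping_error >= 0, genotyping_error <= 1,
            missing_rate >= 0, missing_rate <= 1,
            y_linked_fraction >= 0, y_linked_fraction <= 1,
            het_span[1] < het_span[2], par_span[1] < par_span[2],
            het_span[2] < par_span[1])
  if (!is.null(dam_alpha) && any(abs(dam_alpha$alpha) > 0.5))
    stop("injected dam alpha must lie in [-0.5, 0.5]")
  structure(as.list(environment()), class = "sim_config")
}

haldane <- function(morgans) 0.5 * (1 - exp(-2 * morgans))

# recombinant gamete from two haplotype columns under per-interval
# recombination probabilities (first element: boundary-to-first-marker);
# start_state: 1 or 2, which haplotype the chain starts on
recombine <- function(h1, h2, rec_prob, start_state) {
  flips <- stats::runif(length(rec_prob)) < rec_prob
  state <- (start_state - 1L + cumsum(flips)) %% 2L  # 0 -> h1, 1 -> h2
  ifelse(state == 0L, h1, h2)
}

#' Simulate sex-chromosome trio genotypes
#'
#' Runs the forward model described in [sim_config()] and emits array-style
#' genotypes: females and pseudoautosomal males are diploid; males at
#' heterosomal markers carry their single maternal allele coded 0/2.
#' Genotyping error and missingness are applied last, after the truth is
#' recorded.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return A list with `trioset` (a [assemble_trios()] result) and `truth`
#'   (class `sim_truth`): sire X/Y PAR haplotypes, per-meiosis recombination
#'   counts, true transmitted maternal and paternal alleles before error,
#'   marker frequencies and the injected-parameter configuration.
#' @export
simulate_trios <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n_het <- cfg$n_het_markers
  n_par <- cfg$n_par_markers
  n_mark <- n_het + n_par
  pos <- c(round(seq(cfg$het_span[1], cfg$het_span[2], length.out = n_het)),
           round(seq(cfg$par_span[1], cfg$par_span[2], length.out = n_par)))
  map <- marker_map(sprintf("snpX_%04d", seq_len(n_mark)), chrom = "X",
                    pos = pos)
  is_par <- c(rep(FALSE, n_het), rep(TRUE, n_par))
  freq_b <- stats::runif(n_mark, cfg$freq_range[1], cfg$freq_range[2])

  draw_hap <- function() {
    h <- as.integer(stats::runif(n_mark) < freq_b)
    for (inj in list(cfg$hap_distortion, cfg$lethal))
      if (!is.null(inj) && stats::runif(1) < cfg$carrier_freq)
        h[inj$markers] <- inj$haplotype
    h
  }

  n_tr <- cfg$n_trios
  sire_of <- rep_len(seq_len(cfg$n_sires), n_tr)
  off_sex <- ifelse(stats::runif(n_tr) < cfg$sex_ratio, "male", "female")

  # founders
  sire_x <- vapply(seq_len(cfg$n_sires), function(i) draw_hap(), integer(n_mark))
  sire_y_par <- vapply(seq_len(cfg$n_sires), function(i) {
    if (i <= round(cfg$y_linked_fraction * cfg$n_sires)) rep(0L, n_par)
    else as.integer(stats::runif(n_par) < freq_b[is_par])
  }, integer(n_par))
  dam_h1 <- vapply(seq_len(n_tr), function(i) draw_hap(), integer(n_mark))
  dam_h2 <- vapply(seq_len(n_tr), function(i) draw_hap(), integer(n_mark))

  # genetic maps
  bp_all <- map$pos
  d_dam <- diff(bp_all) * cfg$x_map_length / diff(range(bp_all))
  rec_dam <- c(0.5, haldane(d_dam))      # first element: random start phase
  par_pos <- bp_all[is_par]
  g_par <- (par_pos - cfg$par_span[1]) / diff(cfg$par_span) * cfg$par_map_length
  rec_par <- haldane(diff(c(0, g_par)))  # from the boundary outward

  da <- cfg$dam_alpha
  hd <- cfg$hap_distortion

  dam_meiosis <- function(i, sex) {
    h1 <- dam_h1[, i]; h2 <- dam_h2[, i]
    gam <- recombine(h1, h2, rec_dam, 1L)
    if (!is.null(hd)) {
      k1 <- all(h1[hd$markers] == hd$haplotype)
      k2 <- all(h2[hd$markers] == hd$haplotype)
      if (xor(k1, k2)) {
        carrier <- if (k1) h1 else h2
        non <- if (k1) h2 else h1
        src <- if (stats::runif(1) < 0.5 + hd$alpha) carrier else non
        gam[hd$markers] <- src[hd$markers]
      }
    }
    if (!is.null(da)) for (r in seq_len(nrow(da))) {
      mrk <- da$marker[r]
      if (da$stratum[r] != "pooled" && da$stratum[r] != sex) next
      if (h1[mrk] != h2[mrk])          # heterozygous dam
        gam[mrk] <- as.integer(stats::runif(1) >= 0.5 + da$alpha[r])
    }
    gam
  }

  mat_tx <- matrix(NA_integer_, n_mark, n_tr)   # maternal gamete
  pat_tx <- matrix(NA_integer_, n_mark, n_tr)   # paternal gamete (X or Y+PAR)
  n_rec_sire <- integer(n_tr)

  for (i in seq_len(n_tr)) {
    s <- sire_of[i]
    tries <- 0L
    repeat {
      tries <- tries + 1L
      # a homozygous-carrier dam mated to a carrier sire can produce no
      # viable daughter at all: the observed offspring is then a son
      if (tries > 50L && off_sex[i] == "female") off_sex[i] <- "male"
      gam_m <- dam_meiosis(i, off_sex[i])
      x_par <- sire_x[is_par, s]
      y_par <- sire_y_par[, s]
      start <- if (off_sex[i] == "male") 2L else 1L  # sons start on Y side
      flips <- stats::runif(n_par) < rec_par
      state <- (start - 1L + cumsum(flips)) %% 2L
      par_gam <- ifelse(state == 0L, x_par, y_par)
      gam_p <- rep(NA_integer_, n_mark)
      gam_p[is_par] <- par_gam
      if (off_sex[i] == "female") gam_p[!is_par] <- sire_x[!is_par, s]
      # female-only recessive lethality over the configured haplotype
      if (!is.null(cfg$lethal) && off_sex[i] == "female") {
        lm <- cfg$lethal$markers
        if (all(gam_m[lm] == cfg$lethal$haplotype) &&
            all(gam_p[lm] == cfg$lethal$haplotype)) next
      }
      mat_tx[, i] <- gam_m
      pat_tx[, i] <- gam_p
      n_rec_sire[i] <- sum(flips)
      break
    }
  }

  # genotype emission (array-style: hemizygous males doubled)
  male <- off_sex == "male"
  off_calls <- mat_tx + ifelse(is.na(pat_tx), mat_tx, pat_tx)
  sire_calls <- matrix(NA_integer_, n_mark, cfg$n_sires)
  sire_calls[!is_par, ] <- 2L * sire_x[!is_par, , drop = FALSE]
  sire_calls[is_par, ] <- sire_x[is_par, , drop = FALSE] + sire_y_par
  dam_calls <- dam_h1 + dam_h2

  ids <- c(sprintf("sire_%04d", seq_len(cfg$n_sires)),
           sprintf("dam_%05d", seq_len(n_tr)),
           sprintf("off_%05d", seq_len(n_tr)))
  sexes <- c(rep("male", cfg$n_sires), rep("female", n_tr), off_sex)
  calls <- cbind(sire_calls, dam_calls, off_calls)

  if (cfg$genotyping_error > 0) {
    hit <- which(stats::runif(length(calls)) < cfg$genotyping_error)
    if (length(hit))
      calls[hit] <- (calls[hit] + sample(1:2, length(hit), TRUE)) %% 3L
  }
  if (cfg$missing_rate > 0)
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_

  gt <- genotype_table(calls, data.frame(id = ids, sex = sexes,
                                         stringsAsFactors = FALSE), map)
  ped <- data.frame(offspring_id = sprintf("off_%05d", seq_len(n_tr)),
                    sire_id = sprintf("sire_%04d", sire_of),
                    dam_id = sprintf("dam_%05d", seq_len(n_tr)),
                    offspring_sex = off_sex, stringsAsFactors = FALSE)
  trioset <- assemble_trios(gt, ped)

  truth <- structure(list(
    labels = ifelse(is_par, "pseudoautosomal", "heterosomal"),
    freq_b = freq_b, sire_x = sire_x, sire_y_par = sire_y_par,
    maternal = mat_tx, paternal = pat_tx, offspring_sex = off_sex,
    sire_of = sire_of, n_rec_sire_par = n_rec_sire,
    config = cfg, seed = seed), class = "sim_truth")
  list(trioset = trioset, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits PLINK-style PED/MAP files, a pedigree TSV and a per-meiosis truth
#' TSV into `dir`. Re-reading the PED/MAP with [read_genotypes()] and
#' [assemble_trios()] reproduces the simulated trio set.
#'
#' @param sim a [simulate_trios()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
emit_sim <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  gt <- sim$trioset$gt
  map <- gt$map
  map_path <- file.path(dir, paste0(prefix, ".map"))
  utils::write.table(data.frame(map$chrom, map$marker_id, 0, map$pos),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  trios <- sim$trioset$trios
  sire_of <- stats::setNames(trios$sire_id, trios$offspring_id)
  dam_of <- stats::setNames(trios$dam_id, trios$offspring_id)
  ids <- gt$individuals$id
  pat <- ifelse(ids %in% names(sire_of), sire_of[ids], "0")
  mat <- ifelse(ids %in% names(dam_of), dam_of[ids], "0")
  sex_code <- match(gt$individuals$sex, c("male", "female"))
  sex_code[is.na(sex_code)] <- 0L

  n_mark <- nrow(gt$calls)
  a_chr <- matrix("0", 2L * n_mark, length(ids))
  g <- gt$calls
  for (m in seq_len(n_mark)) {
    al <- c(map$allele_a[m], map$allele_b[m])
    gm <- g[m, ]
    a1 <- rep("0", length(gm))
    a2 <- rep("0", length(gm))
    a1[!is.na(gm) & gm <= 1L] <- al[1]   # A/A and A/B carry A first
    a2[!is.na(gm) & gm == 0L] <- al[1]
    a1[!is.na(gm) & gm == 2L] <- al[2]
    a2[!is.na(gm) & gm >= 1L] <- al[2]
    a_chr[2L * m - 1L, ] <- a1
    a_chr[2L * m, ] <- a2
  }
  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  ped_mat <- cbind("FAM1", ids, pat, mat, sex_code, "-9", t(a_chr))
  utils::write.table(ped_mat, ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ped_tsv <- file.path(dir, paste0(prefix, "_pedigree.tsv"))
  utils::write.table(trios[, c("offspring_id", "sire_id", "dam_id",
                               "offspring_sex")],
                     ped_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  truth_tsv <- file.path(dir, paste0(prefix, "_truth.tsv"))
  tru <- sim$truth
  utils::write.table(
    data.frame(offspring_id = sprintf("off_%05d", seq_along(tru$offspring_sex)),
               offspring_sex = tru$offspring_sex,
               sire = sprintf("sire_%04d", tru$sire_of),
               n_rec_sire_par = tru$n_rec_sire_par,
               maternal_hap = apply(tru$maternal, 2, paste, collapse = ""),
               stringsAsFactors = FALSE),
    truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ped_path, map_path, ped_tsv, truth_tsv))
}
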