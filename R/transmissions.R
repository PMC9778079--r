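# Reduction of trio genotypes at a marker (or biallelic pseudo-marker) to
# the sufficient statistics of the TRD models: per-parent, per-offspring-sex
# transmission counts and mating-type genotype tables.

#' Transmission count container
#'
#' Sufficient statistics for allelic TRD at one marker or pseudo-marker:
#' resolved A/B transmissions per parent, the ambiguous AB x AB -> AB class
#' (pseudoautosomal only, entering the likelihood as a mixture), and
#' supporting totals.
#'
#' @param n_a_dam,n_b_dam resolved dam-transmitted A and B counts.
#' @param n_a_sire,n_b_sire resolved sire-transmitted A and B counts.
#' @param stratum `"pooled"`, `"male"` or `"female"` offspring.
#' @param n_ambiguous AB x AB matings with AB offspring.
#' @param n_het_sires,n_het_dams numbers of distinct heterozygous parents
#'   contributing informative offspring.
#' @param n_inconsistent trios excluded as Mendelian inconsistencies.
#' @return An object of class `transmission_counts`.
#' @export
transmission_counts <- function(n_a_dam = 0L, n_b_dam = 0L, n_a_sire = 0L,
                                n_b_sire = 0L, stratum = "pooled",
                                n_ambiguous = 0L, n_het_sires = 0L,
                                n_het_dams = 0L, n_inconsistent = 0L) {
  for (v in c(n_a_dam, n_b_dam, n_a_sire, n_b_sire, n_ambiguous,
              n_het_sires, n_het_dams, n_inconsistent))
    if (!is_count(v)) stop("counts must be non-negative integers")
  stopifnot(stratum %in% c("pooled", "male", "female"))
  structure(list(n_a_dam = as.integer(n_a_dam), n_b_dam = as.integer(n_b_dam),
                 n_a_sire = as.integer(n_a_sire),
                 n_b_sire = as.integer(n_b_sire), stratum = stratum,
                 n_ambiguous = as.integer(n_ambiguous),
                 n_het_sires = as.integer(n_het_sires),
                 n_het_dams = as.integer(n_het_dams),
                 n_inconsistent = as.integer(n_inconsistent),
                 n_informative = as.integer(n_a_dam + n_b_dam + n_a_sire +
                                              n_b_sire + n_ambiguous)),
            class = "transmission_counts")
}

#' @export
print.transmission_counts <- function(x, ...) {
  cat(sprintf(paste0("transmission_counts (%s): dam A/B = %d/%d, ",
                     "sire A/B = %d/%d, ambiguous = %d, informative = %d\n"),
              x$stratum, x$n_a_dam, x$n_b_dam, x$n_a_sire, x$n_b_sire,
              x$n_ambiguous, x$n_informative))
  invisible(x)
}

# select trio indices for a stratum
stratum_index <- function(sex, stratum) {
  if (stratum == "pooled") sex %in% c("male", "female") else sex == stratum
}

#' Dam transmissions at a heterosomal marker
#'
#' Extracts resolved dam-transmitted alleles from heterozygous dams at a
#' heterosomal marker. Male offspring are hemizygous, so their single
#' maternal allele is read directly from the array-style 0/2 call (a
#' heterozygous male call is a model inconsistency and is excluded). Female
#' offspring carry the sire's hemizygous allele, so the maternal allele is
#' the offspring genotype minus the sire allele; trios whose sire call is
#' heterozygous or missing are excluded.
#'
#' @param trioset a [assemble_trios()] result.
#' @param marker marker id or row index.
#' @param stratum offspring-sex stratum (`"pooled"`, `"male"`, `"female"`).
#' @param label optional region label for the marker; an error is raised if
#'   it is not `"heterosomal"`.
#' @return A [transmission_counts()].
#' @export
dam_transmissions_heterosomal <- function(trioset, marker,
                                          stratum = c("pooled", "male", "female"),
                                          label = "heterosomal") {
  stratum <- match.arg(stratum)
  if (!identical(label, "heterosomal"))
    stop("marker is not labeled heterosomal")
  tc <- trio_calls(trioset, marker)
  use <- stratum_index(tc$sex, stratum) & !is.na(tc$dam) & tc$dam == 1L &
    !is.na(tc$off)
  n_a <- n_b <- n_inc <- 0L
  dams <- character(0)

  m <- use & tc$sex == "male"
  if (any(m)) {
    n_a <- n_a + sum(tc$off[m] == 0L)
    n_b <- n_b + sum(tc$off[m] == 2L)
    n_inc <- n_inc + sum(tc$off[m] == 1L)
    dams <- c(dams, trioset$trios$dam_id[m & tc$off != 1L])
  }
  f <- use & tc$sex == "female" & !is.na(tc$sire) & tc$sire %in% c(0L, 2L)
  if (any(f)) {
    sa <- tc$sire[f] %/% 2L            # sire hemizygous allele (0 = A, 1 = B)
    mat <- tc$off[f] - sa              # maternal allele if valid
    ok <- mat %in% c(0L, 1L)
    n_a <- n_a + sum(ok & mat == 0L)
    n_b <- n_b + sum(ok & mat == 1L)
    n_inc <- n_inc + sum(!ok)
    dams <- c(dams, trioset$trios$dam_id[which(f)[ok]])
  }
  transmission_counts(n_a_dam = n_a, n_b_dam = n_b, stratum = stratum,
                      n_het_dams = length(unique(dams)),
                      n_inconsistent = n_inc)
}

#' Dam transmission counts from published mating-genotype categories
#'
#' Converts a heterosomal mating-genotype table row (the layout of the
#' published per-marker tables: sire class A or B crossed with heterozygous
#' dams, offspring genotype categories) into resolved dam A/B transmission
#' counts. Under sire hemizygous A, offspring AA or male A received dam-A and
#' offspring AB received dam-B; male offspring B received dam-B. Under sire
#' hemizygous B, male offspring A received dam-A, offspring AB received
#' dam-A, and offspring BB or male B received dam-B.
#'
#' @param axab numeric length-3 vector `c(aa_a, ab, b)`: offspring counts for
#'   sire-A by dam-AB matings (female AA or male A; female AB; male B).
#' @param bxab numeric length-3 vector `c(a, ab, bb_b)`: offspring counts for
#'   sire-B by dam-AB matings (male A; female AB; female BB or male B).
#' @return A list with `n_a` and `n_b`, the dam-transmitted A and B counts.
#' @export
dam_counts_from_categories <- function(axab, bxab) {
  stopifnot(length(axab) == 3L, length(bxab) == 3L)
  list(n_a = as.integer(axab[1] + bxab[1] + bxab[2]),
       n_b = as.integer(axab[2] + axab[3] + bxab[3]))
}

#' Parent transmissions at a pseudoautosomal marker
#'
#' Resolves transmitted alleles from heterozygous parents under autosomal
#' inheritance. Matings with exactly one heterozygous parent resolve that
#' parent's transmitted allele from the offspring genotype; AB x AB matings
#' resolve both parents for AA or BB offspring, while AB offspring enter the
#' ambiguous class (a mixture term in the likelihood, not a resolved count).
#' Mendelian-inconsistent trios are excluded and tallied.
#'
#' @inheritParams dam_transmissions_heterosomal
#' @param label optional region label; an error is raised if it is not
#'   `"pseudoautosomal"`.
#' @return A list with elements `counts` (a [transmission_counts()]) and
#'   `mating_table` (offspring-genotype counts per sire x dam mating class).
#' @export
parent_transmissions_pseudoautosomal <- function(trioset, marker,
                                                 stratum = c("pooled", "male", "female"),
                                                 label = "pseudoautosomal") {
  stratum <- match.arg(stratum)
  if (!identical(label, "pseudoautosomal"))
    stop("marker is not labeled pseudoautosomal")
  tc <- trio_calls(trioset, marker)
  use <- which(stratum_index(tc$sex, stratum) & !is.na(tc$sire) &
                 !is.na(tc$dam) & !is.na(tc$off))
  s <- tc$sire[use]; d <- tc$dam[use]; o <- tc$off[use]
  cons <- .cons_tab$pseudo[cbind(s + 1L, d + 1L, o + 1L)]
  n_inc <- sum(!cons)
  keep <- cons
  s <- s[keep]; d <- d[keep]; o <- o[keep]; rows <- use[keep]

  n_a_s <- n_b_s <- n_a_d <- n_b_d <- n_amb <- 0L
  het_s <- het_d <- character(0)

  one_het_s <- s == 1L & d != 1L
  if (any(one_het_s)) {
    t_s <- o[one_het_s] - d[one_het_s] %/% 2L
    n_a_s <- n_a_s + sum(t_s == 0L)
    n_b_s <- n_b_s + sum(t_s == 1L)
    het_s <- c(het_s, trioset$trios$sire_id[rows[one_het_s]])
  }
  one_het_d <- d == 1L & s != 1L
  if (any(one_het_d)) {
    t_d <- o[one_het_d] - s[one_het_d] %/% 2L
    n_a_d <- n_a_d + sum(t_d == 0L)
    n_b_d <- n_b_d + sum(t_d == 1L)
    het_d <- c(het_d, trioset$trios$dam_id[rows[one_het_d]])
  }
  both <- s == 1L & d == 1L
  if (any(both)) {
    ob <- o[both]
    n_a_s <- n_a_s + sum(ob == 0L); n_a_d <- n_a_d + sum(ob == 0L)
    n_b_s <- n_b_s + sum(ob == 2L); n_b_d <- n_b_d + sum(ob == 2L)
    n_amb <- sum(ob == 1L)
    het_s <- c(het_s, trioset$trios$sire_id[rows[both]])
    het_d <- c(het_d, trioset$trios$dam_id[rows[both]])
  }

  mt <- as.data.frame(table(sire = factor(s, 0:2), dam = factor(d, 0:2),
                            offspring = factor(o, 0:2)),
                      stringsAsFactors = FALSE)
  names(mt)[4] <- "n"
  mt <- mt[mt$n > 0, , drop = FALSE]
  rownames(mt) <- NULL

  list(counts = transmission_counts(
         n_a_dam = n_a_d, n_b_dam = n_b_d, n_a_sire = n_a_s,
         n_b_sire = n_b_s, stratum = stratum, n_ambiguous = n_amb,
         n_het_sires = length(unique(het_s)),
         n_het_dams = length(unique(het_d)), n_inconsistent = n_inc),
       mating_table = mt)
}

#' Recessive-pattern category counts (heterosomal, female offspring)
#'
#' Tallies female-offspring genotypes per mating class for the genotypic
#' (recessive) TRD model on the heterosomal region: hemizygous-A sires by
#' heterozygous dams yield AA or AB daughters; hemizygous-B sires by
#' heterozygous dams yield AB or BB daughters. A fully recessive-lethal A
#' haplotype shows up as a missing AA category.
#'
#' @inheritParams dam_transmissions_heterosomal
#' @return A `data.frame` of class `mating_genotype_table` with columns
#'   `mating` (`"AAxAB"`, `"BBxAB"`), `offspring` (`"AA"`, `"AB"`, `"BB"`)
#'   and `n`, plus attributes `n_het_dams` and `n_inconsistent`.
#' @export
recessive_category_counts <- function(trioset, marker, label = "heterosomal") {
  if (!identical(label, "heterosomal"))
    stop("marker is not labeled heterosomal")
  tc <- trio_calls(trioset, marker)
  f <- which(tc$sex == "female" & !is.na(tc$sire) & tc$sire %in% c(0L, 2L) &
               !is.na(tc$dam) & tc$dam == 1L & !is.na(tc$off))
  s <- tc$sire[f]; o <- tc$off[f]
  cons <- if (length(f))
    .cons_tab$hetero[cbind(s + 1L, rep(2L, length(f)), o + 1L,
                           rep(2L, length(f)))]
  else logical(0)
  n_inc <- sum(!cons)
  s <- s[cons]; o <- o[cons]; rows <- f[cons]
  tab <- data.frame(
    mating = c("AAxAB", "AAxAB", "BBxAB", "BBxAB"),
    offspring = c("AA", "AB", "AB", "BB"),
    n = c(sum(s == 0L & o == 0L), sum(s == 0L & o == 1L),
          sum(s == 2L & o == 1L), sum(s == 2L & o == 2L)),
    stringsAsFactors = FALSE)
  attr(tab, "n_het_dams") <- length(unique(trioset$trios$dam_id[rows]))
  attr(tab, "n_inconsistent") <- n_inc
  class(tab) <- c("mating_genotype_table", "data.frame")
  tab
}

#' Build a recessive mating-genotype table from category counts
#'
#' Convenience constructor matching the published table layout: AA x AB
#' matings with AA and AB daughter counts, BB x AB matings with AB and BB
#' daughter counts.
#'
#' @param aa_ab_aa,aa_ab_ab daughter counts for hemizygous-A sire matings.
#' @param bb_ab_ab,bb_ab_bb daughter counts for hemizygous-B sire matings.
#' @param n_het_dams optional number of heterozygous dams.
#' @return A `mating_genotype_table`.
#' @export
recessive_table <- function(aa_ab_aa, aa_ab_ab, bb_ab_ab, bb_ab_bb,
                            n_het_dams = NA_integer_) {
  tab <- data.frame(mating = c("AAxAB", "AAxAB", "BBxAB", "BBxAB"),
                    offspring = c("AA", "AB", "AB", "BB"),
                    n = as.integer(c(aa_ab_aa, aa_ab_ab, bb_ab_ab, bb_ab_bb)),
                    stringsAsFactors = FALSE)
  attr(tab, "n_het_dams") <- n_het_dams
  attr(tab, "n_inconsistent") <- 0L
  class(tab) <- c("mating_genotype_table", "data.frame")
  tab
}
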