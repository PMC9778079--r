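# Reading, validation and assembly of marker maps, genotypes and pedigrees
# into trio-indexed datasets.
#
# Genotype codes count copies of allele B: 0 = A/A, 1 = A/B, 2 = B/B, NA =
# missing. Hemizygous males at heterosomal markers appear as 0 or 2, the way
# SNP arrays report the X chromosome.

#' Construct a marker map
#'
#' An ordered table of biallelic markers giving the coordinate frame for all
#' downstream scans. Positions are 1-based base pairs; markers are sorted by
#' chromosome then position, and positions must be strictly increasing within
#' a chromosome.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom chromosome label (recycled if length 1).
#' @param pos integer vector of 1-based bp positions.
#' @param allele_a,allele_b single-character allele labels; `allele_b` is the
#'   allele counted by the genotype codes.
#' @return A `data.frame` of class `marker_map`.
#' @export
marker_map <- function(marker_id, chrom = "X", pos, allele_a = "A", allele_b = "B") {
  n <- length(marker_id)
  mm <- data.frame(
    marker_id = as.character(marker_id),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    allele_a = rep_len(as.character(allele_a), n),
    allele_b = rep_len(as.character(allele_b), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(mm$marker_id))
    stop("duplicate marker ids: ", paste(mm$marker_id[duplicated(mm$marker_id)][1], collapse = ", "))
  if (any(mm$allele_a == mm$allele_b))
    stop("allele_a must differ from allele_b for every marker")
  mm <- mm[order(mm$chrom, mm$pos), , drop = FALSE]
  rownames(mm) <- NULL
  for (ch in unique(mm$chrom)) {
    p <- mm$pos[mm$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' Construct a genotype table
#'
#' @param calls integer matrix, markers in rows and individuals in columns,
#'   entries in \{0, 1, 2, NA\} counting copies of allele B.
#' @param individuals `data.frame` with columns `id` and
#'   `sex` (one of `"male"`, `"female"`, `"unknown"`).
#' @param map a [marker_map()] whose rows match the rows of `calls`.
#' @return A list of class `genotype_table`.
#' @export
genotype_table <- function(calls, individuals, map) {
  stopifnot(inherits(map, "marker_map"))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (anyDuplicated(individuals$id))
    stop("duplicate individual id: ",
         individuals$id[duplicated(individuals$id)][1])
  if (nrow(calls) != nrow(map))
    stop("calls has ", nrow(calls), " rows but map has ", nrow(map), " markers")
  if (ncol(calls) != nrow(individuals))
    stop("calls has ", ncol(calls), " columns but ", nrow(individuals),
         " individuals are listed")
  bad <- calls[!is.na(calls)]
  if (length(bad) && any(bad < 0L | bad > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  individuals$sex <- as.character(individuals$sex)
  if (!all(individuals$sex %in% c("male", "female", "unknown")))
    stop("individual sex must be 'male', 'female' or 'unknown'")
  rownames(calls) <- map$marker_id
  colnames(calls) <- individuals$id
  structure(list(calls = calls, individuals = individuals, map = map),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d markers x %d individuals (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read trio genotype data
#'
#' Reads genotypes from PLINK-style PED/MAP files or from a tidy TSV of calls.
#' For `format = "ped_map"`, `path` is the common prefix of `<path>.ped` and
#' `<path>.map`; the allele pair `"0 0"` is treated as missing, individual sex
#' is taken from the PED sex column (1 = male, 2 = female) and the parental
#' columns are kept as a pedigree attribute. For `format = "tsv"`, `path` is a
#' tab-separated file with columns `marker_id`, `individual_id`, `code`
#' (0/1/2/NA), and `map` supplies marker coordinates (defaulting to the order
#' of first appearance on chromosome "X").
#'
#' Allele labels in PED files are oriented so that `allele_a` is the
#' lexicographically smaller observed allele; a marker with more than two
#' observed alleles is an error.
#'
#' @param path file path or PED/MAP prefix.
#' @param format `"ped_map"` or `"tsv"`.
#' @param map optional [marker_map()] for `format = "tsv"`.
#' @param sex optional named character vector of sexes for `format = "tsv"`.
#' @return A `genotype_table`; for PED/MAP input the pedigree rows
#'   (offspring_id, sire_id, dam_id, offspring_sex) are attached as
#'   `attr(, "pedigree")`.
#' @export
read_genotypes <- function(path, format = c("ped_map", "tsv"), map = NULL,
                           sex = NULL) {
  format <- match.arg(format)
  gt <- if (format == "ped_map") read_ped_map(path) else read_tidy_tsv(path, map, sex)
  xtrd_msg("read %d individuals x %d markers, missing rate %.4f",
           ncol(gt$calls), nrow(gt$calls), mean(is.na(gt$calls)))
  gt
}

read_ped_map <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4L))
    stop("malformed MAP line ", which(nf != 4L)[1], ": expected 4 fields")
  mdat <- do.call(rbind, map_fields)
  n_mark <- nrow(mdat)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * n_mark
  nf <- lengths(fields)
  if (any(nf != want))
    stop("malformed PED line ", which(nf != want)[1], ": expected ", want,
         " fields, found ", nf[nf != want][1])
  ped <- do.call(rbind, fields)
  ids <- ped[, 2L]
  if (anyDuplicated(ids))
    stop("duplicate individual id: ", ids[duplicated(ids)][1])
  sex_code <- ped[, 5L]
  sexes <- ifelse(sex_code == "1", "male",
                  ifelse(sex_code == "2", "female", "unknown"))

  a1 <- ped[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(n_mark), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  # half-missing pairs are treated as missing calls
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA
  a2[miss] <- NA

  calls <- matrix(NA_integer_, nrow = n_mark, ncol = length(ids))
  allele_a <- character(n_mark)
  allele_b <- character(n_mark)
  for (m in seq_len(n_mark)) {
    obs <- sort(unique(stats::na.omit(c(a1[, m], a2[, m]))))
    if (length(obs) > 2L)
      stop("marker ", mdat[m, 2L], " has ", length(obs),
           " observed alleles; biallelic markers required")
    if (length(obs) == 0L) obs <- c("A", "B")
    if (length(obs) == 1L) obs <- c(obs, if (obs == "B") "b" else "B")
    allele_a[m] <- obs[1L]
    allele_b[m] <- obs[2L]
    calls[m, ] <- (a1[, m] == obs[2L]) + (a2[, m] == obs[2L])
  }

  mm <- marker_map(marker_id = mdat[, 2L], chrom = mdat[, 1L],
                   pos = as.integer(mdat[, 4L]),
                   allele_a = allele_a, allele_b = allele_b)
  ord <- match(mm$marker_id, mdat[, 2L])
  gt <- genotype_table(calls[ord, , drop = FALSE],
                       data.frame(id = ids, sex = sexes,
                                  stringsAsFactors = FALSE), mm)
  ped_df <- data.frame(offspring_id = ids, sire_id = ped[, 3L],
                       dam_id = ped[, 4L], offspring_sex = sexes,
                       stringsAsFactors = FALSE)
  ped_df <- ped_df[ped_df$sire_id != "0" & ped_df$dam_id != "0", , drop = FALSE]
  attr(gt, "pedigree") <- ped_df
  gt
}

read_tidy_tsv <- function(path, map = NULL, sex = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("malformed line ", which(nf != 3L)[1], ": expected 3 tab-separated fields")
  hdr <- fields[[1]]
  need <- c("marker_id", "individual_id", "code")
  if (!all(need %in% hdr))
    stop("tidy TSV needs columns: ", paste(need, collapse = ", "))
  if (length(fields) < 2L) stop("tidy TSV has no data rows")
  body <- do.call(rbind, fields[-1])
  dat <- data.frame(marker_id = body[, match("marker_id", hdr)],
                    individual_id = body[, match("individual_id", hdr)],
                    stringsAsFactors = FALSE)
  raw_code <- body[, match("code", hdr)]
  # anything other than 0/1/2 is a missing call
  dat$code <- suppressWarnings(as.integer(raw_code))
  dat$code[!(dat$code %in% 0:2)] <- NA_integer_
  if (is.null(map)) {
    mk <- unique(dat$marker_id)
    map <- marker_map(mk, chrom = "X", pos = seq_along(mk))
  }
  ids <- unique(dat$individual_id)
  calls <- matrix(NA_integer_, nrow = nrow(map), ncol = length(ids),
                  dimnames = list(map$marker_id, ids))
  mi <- match(dat$marker_id, map$marker_id)
  if (anyNA(mi))
    stop("marker ", dat$marker_id[which(is.na(mi))[1]], " absent from map")
  calls[cbind(mi, match(dat$individual_id, ids))] <- dat$code
  sexes <- if (is.null(sex)) rep("unknown", length(ids)) else {
    s <- unname(sex[ids]); s[is.na(s)] <- "unknown"; s
  }
  genotype_table(calls, data.frame(id = ids, sex = sexes,
                                   stringsAsFactors = FALSE), map)
}

#' Assemble sire-dam-offspring trios
#'
#' Joins a pedigree onto a genotype table, dropping trios with any ungenotyped
#' member, and precomputes per-marker counts of complete (all three members
#' called) trios. Trios are stored sorted by offspring id, so assembly does
#' not depend on pedigree row order.
#'
#' @param gt a [genotype_table()].
#' @param pedigree `data.frame` with columns `offspring_id`, `sire_id`,
#'   `dam_id` and optionally `offspring_sex`; defaults to the pedigree
#'   attached by [read_genotypes()] for PED input.
#' @return A list of class `trio_set` with elements `trios` (the retained
#'   pedigree rows plus column indices into the call matrix), `gt`, and
#'   `n_complete` (per-marker complete-trio counts).
#' @export
assemble_trios <- function(gt, pedigree = attr(gt, "pedigree")) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(pedigree)) stop("no pedigree supplied or attached")
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  if (is.null(ped$offspring_sex)) {
    ped$offspring_sex <- gt$individuals$sex[match(ped$offspring_id,
                                                  gt$individuals$id)]
    ped$offspring_sex[is.na(ped$offspring_sex)] <- "unknown"
  }
  self <- ped$offspring_id == ped$sire_id | ped$offspring_id == ped$dam_id
  if (any(self))
    stop("offspring listed as its own parent: ", ped$offspring_id[self][1])

  ids <- gt$individuals$id
  oi <- match(ped$offspring_id, ids)
  si <- match(ped$sire_id, ids)
  di <- match(ped$dam_id, ids)
  keep <- !is.na(oi) & !is.na(si) & !is.na(di)
  if (any(!keep))
    xtrd_msg("dropped %d of %d trios with an ungenotyped member",
             sum(!keep), nrow(ped))
  ped <- ped[keep, , drop = FALSE]
  trios <- data.frame(offspring_id = ped$offspring_id, sire_id = ped$sire_id,
                      dam_id = ped$dam_id, offspring_sex = ped$offspring_sex,
                      off_col = oi[keep], sire_col = si[keep],
                      dam_col = di[keep], stringsAsFactors = FALSE)
  trios <- trios[order(trios$offspring_id), , drop = FALSE]
  rownames(trios) <- NULL

  cc <- gt$calls
  complete <- !is.na(cc[, trios$off_col, drop = FALSE]) &
    !is.na(cc[, trios$sire_col, drop = FALSE]) &
    !is.na(cc[, trios$dam_col, drop = FALSE])
  structure(list(trios = trios, gt = gt,
                 n_complete = as.integer(rowSums(complete))),
            class = "trio_set")
}

#' @export
print.trio_set <- function(x, ...) {
  cat(sprintf("trio_set: %d trios, %d markers (complete trios/marker: %d-%d)\n",
              nrow(x$trios), nrow(x$gt$calls),
              if (length(x$n_complete)) min(x$n_complete) else 0L,
              if (length(x$n_complete)) max(x$n_complete) else 0L))
  invisible(x)
}

# per-trio call matrices at one marker (row) as a list of vectors
trio_calls <- function(trioset, marker) {
  i <- marker_row(trioset, marker)
  cc <- trioset$gt$calls
  list(sire = cc[i, trioset$trios$sire_col],
       dam = cc[i, trioset$trios$dam_col],
       off = cc[i, trioset$trios$off_col],
       sex = trioset$trios$offspring_sex)
}

marker_row <- function(trioset, marker) {
  if (is.character(marker)) {
    i <- match(marker, trioset$gt$map$marker_id)
    if (is.na(i)) stop("unknown marker: ", marker)
    i
  } else as.integer(marker)
}

#' Write and read TRD result tables
#'
#' Results are written tab-separated, one row per marker/window and parameter,
#' preceded by comment lines recording a configuration hash and seed so a run
#' can be tied to its outputs. `read_results()` inverts `write_results()`.
#'
#' @param results a `data.frame` of results (see [as.data.frame.trd_result()])
#'   or a list of `trd_result` objects.
#' @param path output file path.
#' @param config optional configuration object hashed into the header.
#' @param seed optional seed recorded in the header.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the results `data.frame`.
#' @export
write_results <- function(results, path, config = NULL, seed = NULL) {
  if (!is.data.frame(results)) results <- results_table(results)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(sprintf("# xtrd results; config_hash=%s; seed=%s",
                     config_hash(config), seed %||% "NA"), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

#' Flatten TRD results into a table
#'
#' One row per estimated parameter, carrying the supporting transmission
#' counts, Bayes factor and empirical-null class alongside the posterior
#' summary.
#'
#' @param results a list of `trd_result` objects (a single object is
#'   accepted).
#' @return A `data.frame`.
#' @export
results_table <- function(results) {
  if (inherits(results, "trd_result")) results <- list(results)
  if (length(results) == 0L) {
    return(data.frame(id = character(), region = character(),
                      stratum = character(), param = character(),
                      post_mean = numeric(), post_sd = numeric(),
                      log10_bf = numeric(), n_a = integer(), n_b = integer(),
                      n_ambiguous = integer(), n_informative = integer(),
                      n_het_sires = integer(), n_het_dams = integer(),
                      n_underrepresented = integer(),
                      random_trd_class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(results, as.data.frame))
}
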