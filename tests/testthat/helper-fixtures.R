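# Small in-code fixtures shared across tests.

# build a trio_set directly from a call matrix (markers x individuals)
make_trioset <- function(calls, sexes, ped, pos = NULL) {
  n_mark <- nrow(calls)
  mm <- marker_map(sprintf("m%03d", seq_len(n_mark)), chrom = "X",
                   pos = pos %||% seq_len(n_mark) * 1000L)
  gt <- genotype_table(calls, data.frame(id = colnames(calls), sex = sexes,
                                         stringsAsFactors = FALSE), mm)
  assemble_trios(gt, ped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random trio genotypes at one marker: n trios with arbitrary codes/missing
random_trio_calls <- function(n, miss = 0.1) {
  draw <- function() {
    x <- sample(0:2, n, replace = TRUE)
    x[runif(n) < miss] <- NA_integer_
    x
  }
  list(sire = draw(), dam = draw(), off = draw(),
       sex = sample(c("male", "female"), n, replace = TRUE))
}

# trio_set holding a single marker with explicit per-trio calls
trioset_one_marker <- function(sire, dam, off, sex) {
  n <- length(off)
  ids <- c(sprintf("s%03d", seq_len(n)), sprintf("d%03d", seq_len(n)),
           sprintf("o%03d", seq_len(n)))
  calls <- matrix(c(sire, dam, off), nrow = 1)
  colnames(calls) <- ids
  ped <- data.frame(offspring_id = sprintf("o%03d", seq_len(n)),
                    sire_id = sprintf("s%03d", seq_len(n)),
                    dam_id = sprintf("d%03d", seq_len(n)),
                    offspring_sex = sex, stringsAsFactors = FALSE)
  make_trioset(calls, c(rep("male", n), rep("female", n), sex), ped)
}

short_cfg <- function(seed = 1L, iterations = 15000L, burn_in = 3000L)
  mcmc_config(iterations = iterations, burn_in = burn_in, seed = seed)

extdata <- function(name) {
  p <- system.file("extdata", name, package = "xtrd")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", name)
  p
}

read_published <- function(name)
  utils::read.table(extdata(name), header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
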