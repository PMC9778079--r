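# Reading, validation, trio assembly and result-table round trips.

test_that("tidy TSV reading is a round-trip identity on calls", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(marker_id = rep(c("m1", "m2"), each = 3),
                   individual_id = rep(c("a", "b", "c"), 2),
                   code = c(0L, 1L, 2L, 2L, NA, 0L))
  writeLines(c("marker_id\tindividual_id\tcode",
               sprintf("%s\t%s\t%s", df$marker_id, df$individual_id,
                       ifelse(is.na(df$code), "NA", df$code))), tmp)
  gt <- suppressMessages(read_genotypes(tmp, format = "tsv"))
  expect_equal(dim(gt$calls), c(2L, 3L))
  expect_equal(unname(gt$calls["m1", ]), c(0L, 1L, 2L))
  # unknown characters are missing calls
  expect_equal(unname(gt$calls["m2", "b"]), NA_integer_)
  expect_equal(sum(!is.na(gt$calls)), 5L)
})

test_that("malformed tidy TSV lines are reported by line number", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tindividual_id\tcode", "m1\ta\t0", "m1\tb"), tmp)
  expect_error(read_genotypes(tmp, format = "tsv"), "line 3")
})

test_that("PED/MAP reading honours the 0-allele missing convention", {
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "toy")
  writeLines(c("X\tm1\t0\t1000", "X\tm2\t0\t2000"), paste0(prefix, ".map"))
  writeLines(c("F1 kid sire dam 2 -9 A C A A",
               "F1 sire 0 0 1 -9 A A 0 0",
               "F1 dam 0 0 2 -9 C C A A"),
             paste0(prefix, ".ped"))
  gt <- suppressMessages(read_genotypes(prefix, format = "ped_map"))
  expect_equal(unname(gt$calls["m1", c("kid", "sire", "dam")]), c(1L, 0L, 2L))
  expect_true(is.na(gt$calls["m2", "sire"]))
  ped <- attr(gt, "pedigree")
  expect_equal(ped$offspring_id, "kid")
  expect_equal(ped$offspring_sex, "female")
})

test_that("non-biallelic and duplicated-id inputs are rejected", {
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "bad")
  writeLines("X\tm1\t0\t1000", paste0(prefix, ".map"))
  writeLines(c("F1 a 0 0 1 -9 A C", "F1 b 0 0 1 -9 A G"),
             paste0(prefix, ".ped"))
  expect_error(read_genotypes(prefix, format = "ped_map"), "3 observed alleles")
  writeLines(c("F1 a 0 0 1 -9 A C", "F1 a 0 0 1 -9 A A"),
             paste0(prefix, ".ped"))
  expect_error(read_genotypes(prefix, format = "ped_map"), "duplicate")
})

test_that("trio assembly drops ungenotyped members and rejects self-parents", {
  calls <- matrix(sample(0:2, 2 * 12, replace = TRUE), nrow = 2)
  colnames(calls) <- c(paste0("s", 1:4), paste0("d", 1:4), paste0("o", 1:4))
  mm <- marker_map(c("m1", "m2"), pos = c(1000L, 2000L))
  gt <- genotype_table(calls, data.frame(id = colnames(calls),
                                         sex = c(rep("male", 4),
                                                 rep("female", 4),
                                                 rep("female", 4))), mm)
  ped <- data.frame(offspring_id = paste0("o", 1:5),
                    sire_id = c(paste0("s", 1:4), "s_missing"),
                    dam_id = paste0("d", c(1:4, 1)),
                    offspring_sex = "female")
  ts <- suppressMessages(assemble_trios(gt, ped))
  expect_equal(nrow(ts$trios), 4L)

  bad <- ped[1, ]
  bad$sire_id <- bad$offspring_id
  expect_error(assemble_trios(gt, bad), "own parent")
})

test_that("per-marker complete-trio counts match a nested-loop join", {
  set.seed(31)
  n <- 100L
  ids <- c(sprintf("s%03d", 1:20), sprintf("d%03d", 1:n), sprintf("o%03d", 1:n))
  calls <- matrix(sample(c(0:2, NA), 5 * length(ids), replace = TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)), nrow = 5)
  colnames(calls) <- ids
  mm <- marker_map(sprintf("m%d", 1:5), pos = (1:5) * 1e4)
  sex <- c(rep("male", 20), rep("female", n),
           sample(c("male", "female"), n, replace = TRUE))
  gt <- genotype_table(calls, data.frame(id = ids, sex = sex), mm)
  ped <- data.frame(offspring_id = sprintf("o%03d", 1:n),
                    sire_id = sprintf("s%03d", sample(1:20, n, TRUE)),
                    dam_id = sprintf("d%03d", 1:n),
                    offspring_sex = sex[(20 + n + 1):(20 + 2 * n)])
  ts <- assemble_trios(gt, ped)

  brute <- integer(5)
  for (m in 1:5) for (r in seq_len(nrow(ped))) {
    g <- calls[m, c(ped$sire_id[r], ped$dam_id[r], ped$offspring_id[r])]
    if (!anyNA(g)) brute[m] <- brute[m] + 1L
  }
  expect_equal(ts$n_complete, brute)
})

test_that("trio assembly is invariant to pedigree row order", {
  set.seed(7)
  calls <- matrix(sample(0:2, 3 * 9, replace = TRUE), nrow = 3)
  colnames(calls) <- c("s1", "s2", "s3", "d1", "d2", "d3", "o1", "o2", "o3")
  mm <- marker_map(c("m1", "m2", "m3"), pos = c(1, 2, 3) * 1000)
  gt <- genotype_table(calls,
                       data.frame(id = colnames(calls),
                                  sex = rep(c("male", "female", "female"),
                                            each = 3)), mm)
  ped <- data.frame(offspring_id = c("o1", "o2", "o3"),
                    sire_id = c("s1", "s2", "s3"),
                    dam_id = c("d1", "d2", "d3"),
                    offspring_sex = c("male", "female", "male"))
  t1 <- assemble_trios(gt, ped)
  t2 <- assemble_trios(gt, ped[c(3, 1, 2), ])
  expect_identical(t1$trios, t2$trios)
  expect_identical(t1$n_complete, t2$n_complete)
})

test_that("result tables survive a write/read round trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # empty result list -> header-only file
  write_results(results_table(list()), tmp)
  rb <- read_results(tmp)
  expect_equal(nrow(rb), 0L)

  set.seed(5)
  res <- lapply(1:100, function(i)
    fit_allelic(transmission_counts(n_a_dam = rpois(1, 50),
                                    n_b_dam = rpois(1, 50),
                                    n_het_dams = 40L),
                trd_model_spec("alpha_d", "heterosomal"),
                id = sprintf("w%03d", i)))
  tab <- results_table(res)
  expect_equal(nrow(tab), 100L)
  write_results(tab, tmp, config = list(a = 1), seed = 42)
  rb <- read_results(tmp)
  expect_equal(rb$id, tab$id)
  expect_equal(rb$post_mean, tab$post_mean, tolerance = 1e-12)
  expect_equal(rb$n_a, tab$n_a)
  # a single result writes a single data row
  one <- withr::local_tempfile(fileext = ".tsv")
  write_results(results_table(res[1]), one)
  expect_equal(nrow(read_results(one)), 1L)
})
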