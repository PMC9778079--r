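# Trio phasing, biallelic window recoding, scanning, consolidation.

test_that("phasing rules resolve the textbook cases", {
  # pseudoautosomal AB offspring with homozygous parents
  ts <- trioset_one_marker(0L, 2L, 1L, "female")
  ph <- phase_trios(ts, "pseudoautosomal")
  expect_equal(ph$paternal[1, 1], 0L)
  expect_equal(ph$maternal[1, 1], 1L)
  # heterosomal male: call 0 is a maternal A, no paternal X
  ts <- trioset_one_marker(2L, 1L, 0L, "male")
  ph <- phase_trios(ts, "heterosomal")
  expect_equal(ph$maternal[1, 1], 0L)
  expect_true(is.na(ph$paternal[1, 1]))
  # pseudoautosomal AB x AB with AB offspring stays unresolved
  ts <- trioset_one_marker(1L, 1L, 1L, "female")
  ph <- phase_trios(ts, "pseudoautosomal")
  expect_true(is.na(ph$maternal[1, 1]))
})

test_that("error-free simulated trios phase to the simulator's truth", {
  cfg <- sim_config(n_sires = 30, n_trios = 800, n_het_markers = 40,
                    n_par_markers = 20)
  sim <- simulate_trios(cfg, seed = 13)
  ph <- phase_trios(sim$trioset, sim$truth$labels)
  resolved <- !is.na(ph$maternal)
  expect_gt(mean(resolved), 0.8)
  expect_equal(ph$maternal[resolved], sim$truth$maternal[resolved])
  pat_resolved <- !is.na(ph$paternal)
  expect_equal(ph$paternal[pat_resolved], sim$truth$paternal[pat_resolved])
})

test_that("each window haplotype above the floor becomes one pseudo-marker", {
  # 2-marker window, dams carrying haplotypes AB, BA, AA
  n <- 60L
  hap_pairs <- list(c("01", "10"), c("01", "00"), c("10", "00"))
  m <- matrix(NA_integer_, 2, n)
  o <- matrix(NA_integer_, 2, n)
  set.seed(3)
  for (i in seq_len(n)) {
    hp <- hap_pairs[[sample(3, 1)]]
    m[, i] <- as.integer(strsplit(hp[1], "")[[1]])
    o[, i] <- as.integer(strsplit(hp[2], "")[[1]])
  }
  dam <- m + o
  sire <- matrix(0L, 2, n)
  off <- m                       # male offspring: maternal hemizygous
  ids <- c(sprintf("s%03d", 1:n), sprintf("d%03d", 1:n), sprintf("o%03d", 1:n))
  calls <- cbind(2L * sire, dam, 2L * off)
  colnames(calls) <- ids
  ped <- data.frame(offspring_id = sprintf("o%03d", 1:n),
                    sire_id = sprintf("s%03d", 1:n),
                    dam_id = sprintf("d%03d", 1:n),
                    offspring_sex = "male", stringsAsFactors = FALSE)
  ts <- make_trioset(calls, c(rep("male", n), rep("female", n),
                              rep("male", n)), ped)
  ph <- phase_trios(ts, rep("heterosomal", 2))
  res <- scan_windows(ph, sizes = 2, min_het_dams = 1, min_informative = 1,
                      method = "exact")
  expect_setequal(res$haplotype, c("01", "10", "00"))
  expect_equal(nrow(res), 3L)
  # biallelic conservation: each pseudo-marker's A+B equals the dams
  # heterozygous for it, tallied independently
  for (h in res$haplotype) {
    km <- apply(m, 2, paste, collapse = "")
    ko <- apply(o, 2, paste, collapse = "")
    expect_equal(res$n_a[res$haplotype == h] + res$n_b[res$haplotype == h],
                 sum(xor(km == h, ko == h)))
  }
})

test_that("window retention filters discard under-supported windows", {
  cfg <- sim_config(n_sires = 10, n_trios = 60, n_het_markers = 10,
                    n_par_markers = 5)
  sim <- simulate_trios(cfg, seed = 21)
  ph <- phase_trios(sim$trioset, sim$truth$labels)
  # with 60 trios no haplotype can reach 200 informative offspring
  res <- scan_windows(ph, sizes = 2, min_het_dams = 10,
                      min_informative = 200, method = "exact")
  expect_equal(nrow(res), 0L)
  res2 <- scan_windows(ph, sizes = 2, min_het_dams = 1, min_informative = 1,
                       method = "exact")
  expect_gt(nrow(res2), 0L)
  expect_true(all(res2$n_a + res2$n_b >= 1))
})

test_that("a 2-SNP window in perfect LD reproduces the single-SNP result", {
  set.seed(33)
  n <- 300L
  dam <- sample(0:2, n, replace = TRUE)
  off <- vapply(dam, function(g) {
    if (g == 1L) sample(0:1, 1) * 2L else g
  }, 0L)
  sire <- rep(0L, n)
  calls <- rbind(c(2L * sire, dam, off), c(2L * sire, dam, off))
  colnames(calls) <- c(sprintf("s%03d", 1:n), sprintf("d%03d", 1:n),
                       sprintf("o%03d", 1:n))
  ped <- data.frame(offspring_id = sprintf("o%03d", 1:n),
                    sire_id = sprintf("s%03d", 1:n),
                    dam_id = sprintf("d%03d", 1:n),
                    offspring_sex = "male", stringsAsFactors = FALSE)
  ts <- make_trioset(calls, c(rep("male", n), rep("female", n),
                              rep("male", n)), ped)
  single <- dam_transmissions_heterosomal(ts, 1L, "male")
  ph <- phase_trios(ts, rep("heterosomal", 2))
  res <- scan_windows(ph, sizes = 2, min_het_dams = 1, min_informative = 1,
                      method = "exact")
  hap_a <- res[res$haplotype == "00", ]
  expect_equal(hap_a$n_a, single$n_a_dam)
  expect_equal(hap_a$n_b, single$n_b_dam)
  expect_equal(hap_a$post_mean,
               fit_allelic(single,
                           trd_model_spec("alpha_d", "heterosomal"))$params$post_mean)
})

test_that("consolidation groups overlapping significant windows around the smoothed peak", {
  mk <- function(id, start, end, bf, size = 4L)
    data.frame(id = id, size = size, start_index = start, end_index = end,
               log10_bf = bf, stringsAsFactors = FALSE)
  # one isolated significant window is its own region
  res <- mk("w1", 10, 13, 5)
  out <- consolidate(res, class_max = NULL)
  expect_equal(nrow(out), 1L)
  expect_equal(out$representative, "w1")
  # two overlapping significant windows merge into one region
  res <- rbind(mk("w1", 10, 13, 5), mk("w2", 12, 15, 7))
  out <- consolidate(res, class_max = NULL)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_windows, 2L)
  # three well-separated peaks give three regions; sub-threshold noise ignored
  res <- rbind(mk("a1", 10, 13, 6), mk("a2", 11, 14, 8),
               mk("b1", 40, 43, 5), mk("c1", 80, 83, 9),
               mk("n1", 60, 63, 0.5))
  out <- consolidate(res, class_max = NULL)
  expect_equal(nrow(out), 3L)
  expect_true("a2" %in% out$representative)
  # empty input, empty output
  expect_equal(nrow(consolidate(res[0, , drop = FALSE])), 0L)
})

test_that("a lethal haplotype shows zero homozygotes and a recessive signature", {
  le <- list(markers = 12:15, haplotype = c(1L, 1L, 0L, 1L))
  cfg <- sim_config(n_sires = 40, n_trios = 2500, n_het_markers = 18,
                    n_par_markers = 5, lethal = le, carrier_freq = 0.35,
                    freq_range = c(0.35, 0.65))
  sim <- simulate_trios(cfg, seed = 19)
  ph <- phase_trios(sim$trioset, sim$truth$labels)
  res <- recessive_scan(ph, sizes = 4,
                        cfg = short_cfg(seed = 4, iterations = 6000,
                                        burn_in = 1500),
                        min_het_dams = 5, min_informative = 30,
                        freq_floor = 0.1)
  hit <- res[res$haplotype == "1101" & res$start_index == 12 &
               res$param == "alpha_g", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$observed_hom, 0L)
  expect_gt(hit$expected_hom, 5)
  expect_lt(hit$post_mean, 0)
  dg <- res[res$haplotype == "1101" & res$start_index == 12 &
              res$param == "delta_g", ]
  expect_gt(dg$post_mean, 0)
})
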