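test_that("benchmark_size reproduces all seven published benchmark rows", {
  sites <- c(97, 90, 80, 54, 58, 70, 76)
  promoters <- c(138, 128, 114, 77, 82, 100, 108)
  expect_equal(vapply(sites, benchmark_size, integer(1)), promoters)
  # IEEE guard: 70 / 0.7 must floor to 100, not 99
  expect_equal(benchmark_size(70), 100L)
  expect_equal(benchmark_size(10, fraction = 1), 10L)
})

test_that("random_promoters is seed-reproducible with the right shape", {
  a <- random_promoters(5, 30, seed = 3)
  b <- random_promoters(5, 30, seed = 3)
  expect_identical(a, b)
  expect_equal(length(a), 5)
  expect_true(all(nchar(a) == 30))
  expect_true(all(grepl("^[ACGT]+$", a)))
  expect_false(identical(a, random_promoters(5, 30, seed = 4)))
})

test_that("sample_sites draws from the PWM columns", {
  p <- acceptance_true_pwm()
  s <- sample_sites(p, 500, seed = 5)
  expect_true(all(nchar(s) == 8))
  # consensus letter frequency per column close to 0.91/0.88
  m <- do.call(rbind, strsplit(s, ""))
  cons <- strsplit(pwm_consensus(p), "")[[1]]
  freq <- vapply(1:8, function(j) mean(m[, j] == cons[j]), numeric(1))
  want <- unclass(p)[cbind(match(cons, ALPHA), 1:8)]
  expect_true(all(abs(freq - want) < 0.06))
})

test_that("implant_sites places annotated sites verbatim and is reproducible", {
  pool <- random_promoters(80, 60, seed = 11)
  sites <- sample_sites(acceptance_true_pwm(), 21, seed = 12)
  sp <- implant_spec(sites, pool, placement = "uniform", seed = 13)
  pair <- implant_sites(sp)
  expect_equal(length(pair$target), benchmark_size(21))   # 30
  expect_equal(length(pair$control), 30)
  expect_equal(nrow(pair$truth), 21)
  expect_true(all(table(pair$truth$seq_id) == 1))          # one site per carrier
  # every annotated site is present verbatim at its coordinates, with
  # reverse-strand sites planted as their reverse complement
  for (i in seq_len(nrow(pair$truth))) {
    tr <- pair$truth[i, ]
    planted <- substr(pair$target[[tr$seq_id]], tr$start, tr$end)
    want <- if (tr$strand == "+") tr$site else reverse_complement(tr$site)
    expect_equal(planted, want)
  }
  # controls are untouched members of the pool; lengths preserved
  expect_true(all(pair$control == pool[names(pair$control)]))
  expect_true(all(nchar(pair$target) == 60))
  # target and control draws are disjoint
  expect_equal(length(intersect(names(pair$target), names(pair$control))), 0)
  # full reproducibility from the spec seed
  expect_identical(implant_sites(sp)$target, pair$target)
})

test_that("Gaussian placement keeps sites inside and near the mean", {
  pool <- random_promoters(200, 100, seed = 21)
  sites <- sample_sites(acceptance_true_pwm(), 56, seed = 22)
  sp <- implant_spec(sites, pool, placement = list(mean = 40, sd = 8),
                     seed = 23)
  pair <- implant_sites(sp)
  expect_true(all(pair$truth$start >= 1 & pair$truth$end <= 100))
  expect_lt(abs(mean(pair$truth$start) - 40), 5)
  expect_lt(sd(pair$truth$start), 14)
})

test_that("add_decoy plants one decoy everywhere without touching truth", {
  pool <- random_promoters(80, 60, seed = 31)
  sites <- sample_sites(acceptance_true_pwm(), 21, seed = 32)
  pair <- implant_sites(implant_spec(sites, pool, seed = 33))
  decoys <- sample_sites(acceptance_decoy_pwm(), 10, seed = 34)
  pd <- add_decoy(pair, decoys, seed = 35)
  expect_equal(nrow(pd$decoy), length(pd$target) + length(pd$control))
  # decoys present verbatim; none overlaps an annotated true site
  all_seqs <- c(pd$target, pd$control)
  for (i in seq_len(nrow(pd$decoy))) {
    dr <- pd$decoy[i, ]
    planted <- substr(all_seqs[[dr$seq_id]], dr$start, dr$end)
    want <- if (dr$strand == "+") dr$site else reverse_complement(dr$site)
    expect_equal(planted, want)
    tr <- pd$truth[pd$truth$seq_id == dr$seq_id, ]
    if (nrow(tr) > 0)
      expect_true(all(dr$end < tr$start | dr$start > tr$end))
  }
  # true sites still present after decoy insertion
  for (i in seq_len(nrow(pd$truth))) {
    tr <- pd$truth[i, ]
    planted <- substr(pd$target[[tr$seq_id]], tr$start, tr$end)
    want <- if (tr$strand == "+") tr$site else reverse_complement(tr$site)
    expect_equal(planted, want)
  }
})

test_that("sample_from_model emits sites consistent with its annotation", {
  fg <- zoops_params(0.8, acceptance_true_pwm(), c(.3, .2, .2, .3),
                     position_prior(0.2, 30, 10, 2))
  sim <- sample_from_model(fg, 150, 80, seed = 41)
  expect_equal(length(sim$seqs), 150)
  expect_true(all(nchar(sim$seqs) == 80))
  # occurrence rate close to p_occ
  expect_lt(abs(nrow(sim$truth) / 150 - 0.8), 0.1)
  # annotated windows have high consensus agreement (PWM is well conserved)
  cons <- pwm_consensus(fg$pwm)
  agree <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    s <- substr(sim$seqs[[tr$seq_id]], tr$start, tr$end)
    if (tr$strand == "-") s <- reverse_complement(s)
    mean(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]])
  }, numeric(1))
  expect_gt(mean(agree), 0.8)
  # positional law respected: starts concentrate around the prior mode
  expect_lt(abs(median(sim$truth$start) -
                  which.max(position_pmf(fg$position, 80, 8))), 12)
  expect_identical(sample_from_model(fg, 150, 80, seed = 41)$seqs, sim$seqs)
})
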