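test_that("nucleotide_pr matches a brute-force coverage oracle", {
  pred <- data.frame(seq_id = c("s1", "s1", "s2", "s3"),
                     start = c(3L, 6L, 1L, 10L),
                     end = c(8L, 12L, 5L, 14L))       # s1 rows overlap
  truth <- data.frame(seq_id = c("s1", "s2", "s4"),
                      start = c(5L, 2L, 1L),
                      end = c(10L, 4L, 6L))
  got <- nucleotide_pr(pred, truth)
  want <- oracle_nucleotide_pr(pred, truth, L = 20)
  expect_equal(got, want)
  # hand numbers: TP = |5..10| + |2..4| = 9; truth = 6+3+6 = 15;
  # predicted (s1 merged to 3..12) = 10+5+5 = 20
  expect_equal(unname(got), c(9 / 15, 9 / 20))
  # empty prediction: precision defined as 1 (with a message)
  expect_message(pr0 <- nucleotide_pr(pred[0, ], truth), "precision")
  expect_equal(unname(pr0), c(0, 1))
  expect_error(nucleotide_pr(pred, truth[0, ]), "empty truth")
})

test_that("pr_curve equals the prefix oracle and has monotone recall", {
  set.seed(41)
  truth <- data.frame(seq_id = paste0("s", 1:6),
                      start = c(5L, 8L, 2L, 11L, 3L, 7L))
  truth$end <- truth$start + 4L
  # predictions with noisy positions and distinct p-values
  pred <- data.frame(
    seq_id = sample(paste0("s", 1:6), 12, replace = TRUE),
    start = sample(1:12, 12, replace = TRUE))
  pred$end <- pred$start + 4L
  pred$p_value <- sort(runif(12))
  curve <- pr_curve(pred, truth)
  expect_equal(nrow(curve), 12)
  for (i in c(1, 5, 12)) {
    want <- oracle_nucleotide_pr(pred[1:i, ], truth, L = 30)
    expect_equal(c(curve$rn[i], curve$pn[i]), unname(want))
  }
  expect_true(!is.unsorted(curve$rn))
  # tied p-values collapse to one curve point per distinct threshold
  pred2 <- pred; pred2$p_value <- rep(c(0.01, 0.5), each = 6)
  expect_equal(nrow(pr_curve(pred2, truth)), 2)
})

test_that("precision_at_recall interpolates and returns NA when unreached", {
  curve <- data.frame(threshold = c(.01, .1, .5),
                      rn = c(0.2, 0.4, 0.8), pn = c(0.9, 0.7, 0.3))
  expect_equal(precision_at_recall(curve, 0.4), 0.7)
  expect_equal(precision_at_recall(curve, 0.6), 0.5)   # midpoint of .4->.8
  expect_true(is.na(precision_at_recall(curve, 0.9)))
  expect_true(is.na(precision_at_recall(curve[0, ], 0.5)))
})

test_that("information_content and border trimming follow the 0.25-bit rule", {
  expect_equal(information_content(rep(0.25, 4)), 0)
  expect_equal(information_content(c(1, 0, 0, 0)), 2)
  expect_equal(information_content(c(.5, .5, 0, 0)), 1)
  flat <- c(.28, .26, .24, .22)             # ~0.0026 bits, below threshold
  sharp <- c(.85, .05, .05, .05)            # ~1.1 bits
  p <- new_pwm(cbind(flat, sharp, flat, sharp, flat))
  tr <- trim_low_ic_borders(p, 0.25)
  # outer flats removed; the interior flat column is protected
  expect_equal(unclass(tr), unclass(p)[, 2:4], ignore_attr = TRUE)
  expect_error(trim_low_ic_borders(new_pwm(cbind(flat, flat)), 0.25),
               "all columns")
})

test_that("normalized_euclidean_distance: identity, bounds, rc, offsets", {
  set.seed(43)
  a <- rand_pwm(8)
  expect_equal(normalized_euclidean_distance(a, a), 0)
  expect_equal(normalized_euclidean_distance(a, reverse_complement_pwm(a)), 0)
  expect_gt(normalized_euclidean_distance(a, reverse_complement_pwm(a),
                                          allow_rc = FALSE), 0)
  # shifting by one column is distance 0 under offset alignment
  shifted <- new_pwm(cbind(unclass(a)[, 2:8], rand_simplex(4)))
  expect_equal(normalized_euclidean_distance(a, shifted, min_overlap = 7), 0)
  # hand-computable two-column case, alignment forced to full overlap
  p1 <- new_pwm(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  p2 <- new_pwm(cbind(c(0, 1, 0, 0), c(0, 1, 0, 0)))
  # column distances sqrt(2) and 0 -> mean(1, 0) = 0.5; rc of p2 is
  # (G,T columns) and is farther, so the direct alignment wins
  expect_equal(normalized_euclidean_distance(p1, p2, min_overlap = 2), 0.5)
  # maximal distance: disjoint one-hot letters everywhere
  p3 <- new_pwm(cbind(c(0, 0, 1, 0), c(1, 0, 0, 0)))
  expect_equal(normalized_euclidean_distance(p1, p3, allow_rc = FALSE,
                                             min_overlap = 2), 1)
})

test_that("scan_consensus honors IUPAC codes, strands and the window", {
  seqs <- c(s1 = "AAAATGACGTCAAAAA",   # TGACGTCA at 5..12
            s2 = "AAAATGACGTGAAAAA",   # TGACGTGA at 5..12 (variant)
            s3 = "AAAAAAAAAAAAAAAA")
  # TGACGTCA's reverse complement is itself; use pattern TGACGTVA
  # (V = A, C or G) matching s1 and s2 forward
  sc <- scan_consensus(seqs, "TGACGTVA", tss_offset = -16L)
  expect_equal(unname(sc$match), c(TRUE, TRUE, FALSE))
  expect_true(all(sc$positions$start == 5 & sc$positions$end == 12))
  # reverse-strand detection: plant only the reverse complement
  seqs_rc <- c(r1 = paste0("AAAA", reverse_complement("TGCCGTAA"), "AAAA"))
  expect_true(unname(scan_consensus(seqs_rc, "TGCCGTAA",
                                    tss_offset = -16L)$match))
  expect_false(unname(scan_consensus(seqs_rc, "TGCCGTAA",
                                     both_strands = FALSE,
                                     tss_offset = -16L)$match))
  # window: footprint must lie fully inside the TSS-relative interval
  expect_true(unname(scan_consensus(seqs[1], "TGACGTCA", window = c(-12, -4),
                                    tss_offset = -16L)$match))
  expect_false(unname(scan_consensus(seqs[1], "TGACGTCA", window = c(-12, -6),
                                     tss_offset = -16L)$match))
  expect_error(scan_consensus(seqs, "TGACGTXA"), "IUPAC")
})

test_that("contingency_stats reproduces hand-derived rates and rounding", {
  t <- contingency_2x2(20, 42, 131, 437)
  s <- contingency_stats(t)
  expect_equal(s$Sn, 20 / 62)
  expect_equal(s$FPR, 131 / 568)
  expect_equal(s$precision, 20 / 151)
  expect_equal(s$F, 2 * (20 / 151) * (20 / 62) / (20 / 151 + 20 / 62))
  expect_equal(s$Sn_pct, 32)
  expect_equal(s$FPR_pct, 23)
  # degenerate: no matches anywhere
  s0 <- contingency_stats(contingency_2x2(0, 10, 0, 10))
  expect_equal(c(s0$Sn, s0$FPR, s0$precision, s0$F), c(0, 0, 0, 0))
  expect_error(contingency_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("fisher_exact_onesided matches dhyper tail summation", {
  cases <- list(c(20, 42, 131, 437), c(5, 5, 5, 5), c(0, 10, 10, 0),
                c(3, 0, 1, 7), c(12, 8, 4, 16))
  for (cs in cases) {
    t <- contingency_2x2(cs[1], cs[2], cs[3], cs[4])
    expect_equal(fisher_exact_onesided(t),
                 oracle_fisher_greater(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
})

test_that("binomial proportion test matches prop.test without correction", {
  cases <- list(c(20, 62, 131, 568), c(10, 50, 5, 50), c(3, 8, 7, 9))
  for (cs in cases) {
    got <- binomial_proportion_test_onesided(cs[1], cs[2], cs[3], cs[4],
                                             direction = "greater")
    want <- suppressWarnings(
      prop.test(c(cs[1], cs[3]), c(cs[2], cs[4]),
                alternative = "greater", correct = FALSE)$p.value)
    expect_equal(got, want, tolerance = 1e-12)
    # direction aliases and complementarity of the two tails
    expect_equal(binomial_proportion_test_onesided(cs[1], cs[2], cs[3], cs[4],
                                                   direction = "increase"),
                 got)
    expect_equal(got + binomial_proportion_test_onesided(
      cs[1], cs[2], cs[3], cs[4], direction = "less"), 1, tolerance = 1e-12)
  }
  expect_message(
    p <- binomial_proportion_test_onesided(0, 10, 0, 10, "greater"),
    "degenerate")
  expect_equal(p, 1)
})

test_that("consensus_enrichment wires scanning and testing together", {
  set.seed(47)
  fg <- setNames(replicate(20, rand_seq(30)), paste0("f", 1:20))
  bg <- setNames(replicate(20, rand_seq(30)), paste0("b", 1:20))
  for (i in 1:12) substr(fg[i], 11, 18) <- "TGACGTCA"
  res <- consensus_enrichment(fg, bg, "TGACGTCA", tss_offset = -30L)
  expect_gte(res$table$a, 12)
  expect_equal(res$table$a + res$table$b, 20)
  expect_lt(res$fisher_p, 0.01)
  expect_lt(res$binomial_p, 0.01)
  expect_equal(res$stats$Sn, res$table$a / 20)
})
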