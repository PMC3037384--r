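# Assessment machinery: nucleotide-level precision/recall and PR curves,
# information-content border trimming, PWM comparison by normalized
# Euclidean distance, IUPAC consensus scanning, and 2x2 contingency
# statistics.

# coerce a per-sequence interval table (seq_id, start, end; 1-based closed)
# to an IRangesList keyed by sequence id
intervals_by_seq <- function(df) {
  if (nrow(df) == 0L) return(list())
  split(IRanges::IRanges(start = df$start, end = df$end), df$seq_id)
}

#' Nucleotide-level recall and precision
#'
#' `TP` is the number of nucleotides covered by both a prediction and an
#' annotated site; recall is `TP` over all annotated-site nucleotides and
#' precision `TP` over all predicted nucleotides. When nothing is predicted,
#' precision is defined as 1 (logged convention).
#'
#' @param predicted data frame with `seq_id`, `start`, `end` (1-based
#'   closed), e.g. from [call_sites()].
#' @param truth data frame with `seq_id`, `start`, `end` of annotated sites.
#' @return named numeric vector `c(rn, pn)`.
#' @export
nucleotide_pr <- function(predicted, truth) {
  if (is.null(truth) || nrow(truth) == 0L)
    stop("empty truth annotation: recall undefined")
  tr <- intervals_by_seq(truth)
  pr <- intervals_by_seq(predicted)
  tr <- lapply(tr, IRanges::reduce)
  pr <- lapply(pr, IRanges::reduce)
  n_truth <- sum(vapply(tr, function(r) sum(IRanges::width(r)), numeric(1)))
  n_pred <- sum(vapply(pr, function(r) sum(IRanges::width(r)), numeric(1)))
  tp <- 0
  for (id in intersect(names(tr), names(pr))) {
    ov <- IRanges::intersect(tr[[id]], pr[[id]])
    tp <- tp + sum(IRanges::width(ov))
  }
  pn <- if (n_pred == 0) {
    message("no nucleotides predicted; precision defined as 1")
    1
  } else tp / n_pred
  c(rn = tp / n_truth, pn = pn)
}

#' Nucleotide precision-recall curve
#'
#' Sweeps a global threshold over the pooled, ranked prediction list (by
#' ascending p-value): each distinct p-value defines one prefix of the
#' ranking, evaluated with [nucleotide_pr()]. Recall is non-decreasing along
#' the sweep.
#'
#' @param predictions a [call_sites()]-style data frame ordered by the
#'   ranking score, with a `p_value` column.
#' @param truth annotated sites (data frame `seq_id`, `start`, `end`).
#' @return data frame with `threshold`, `rn`, `pn` (one row per distinct
#'   threshold).
#' @export
pr_curve <- function(predictions, truth) {
  if (nrow(predictions) == 0L)
    return(data.frame(threshold = numeric(0), rn = numeric(0), pn = numeric(0)))
  o <- order(predictions$p_value)
  predictions <- predictions[o, , drop = FALSE]
  thresholds <- unique(predictions$p_value)
  out <- lapply(thresholds, function(t) {
    prefix <- predictions[predictions$p_value <= t, , drop = FALSE]
    pr <- nucleotide_pr(prefix, truth)
    data.frame(threshold = t, rn = pr[["rn"]], pn = pr[["pn"]])
  })
  do.call(rbind, out)
}

#' Precision at a fixed recall from a PR curve
#'
#' Linear interpolation between curve points; used to compare settings at a
#' common operating point. Returns `NA` if the curve never reaches the
#' requested recall.
#'
#' @param curve a [pr_curve()] data frame.
#' @param recall target nucleotide recall.
#' @return interpolated nucleotide precision.
#' @export
precision_at_recall <- function(curve, recall = 0.5) {
  if (nrow(curve) == 0L || max(curve$rn) < recall) return(NA_real_)
  if (nrow(curve) == 1L) return(curve$pn[1])
  stats::approx(curve$rn, curve$pn, xout = recall, ties = "ordered")$y
}

#' Information content of a PWM column
#'
#' `2 + sum(p * log2(p))` bits, with `0 * log(0) := 0`; ranges from 0
#' (uniform) to 2 (deterministic).
#'
#' @param column probability vector over the 4 letters.
#' @return bits.
#' @export
information_content <- function(column) {
  p <- column[column > 0]
  2 + sum(p * log2(p))
}

#' Trim uninformative border columns of a PWM
#'
#' Iteratively removes outermost columns with information content below the
#' threshold from both ends; interior columns are never removed.
#'
#' @param pwm a [new_pwm()].
#' @param ic_threshold bits (default 0.25).
#' @return trimmed `pwm`.
#' @export
trim_low_ic_borders <- function(pwm, ic_threshold = 0.25) {
  m <- unclass(as.matrix(pwm))
  ic <- apply(m, 2, information_content)
  keep <- which(ic >= ic_threshold)
  if (length(keep) == 0L) stop("all columns below the information-content threshold")
  new_pwm(m[, keep[1]:keep[length(keep)], drop = FALSE])
}

#' Normalized Euclidean distance between two PWMs
#'
#' Minimum over all relative column offsets with at least `min_overlap`
#' aligned columns — and optionally over the reverse complement of `pwm_b` —
#' of the mean, over aligned columns, of the Euclidean distance between the
#' column vectors divided by `sqrt(2)`. Bounded by \[0, 1\]; 0 iff some
#' admissible alignment matches all aligned columns exactly.
#'
#' @param pwm_a,pwm_b PWMs ([new_pwm()] or 4 x w matrices).
#' @param allow_rc also consider the reverse complement of `pwm_b`.
#' @param min_overlap minimum number of aligned columns (default
#'   `min(w_a, w_b, 5)`).
#' @return distance in \[0, 1\].
#' @export
normalized_euclidean_distance <- function(pwm_a, pwm_b, allow_rc = TRUE,
                                          min_overlap = NULL) {
  a <- unclass(as.matrix(pwm_a)); b <- unclass(as.matrix(pwm_b))
  wa <- ncol(a); wb <- ncol(b)
  if (is.null(min_overlap)) min_overlap <- min(wa, wb, 5L)
  if (wa < min_overlap || wb < min_overlap)
    stop("no admissible alignment: motifs shorter than min_overlap")
  cand <- list(b)
  if (allow_rc) cand <- c(cand, list(unclass(reverse_complement_pwm(b))))
  best <- Inf
  for (bb in cand) {
    for (off in (-(wb - min_overlap)):(wa - min_overlap)) {
      ia <- max(1, 1 + off):min(wa, wb + off)
      ib <- ia - off
      d <- mean(sqrt(colSums((a[, ia, drop = FALSE] - bb[, ib, drop = FALSE])^2)) /
                  sqrt(2))
      if (d < best) best <- d
    }
  }
  best
}

#' Scan sequences for an IUPAC consensus pattern
#'
#' A sequence matches iff the pattern occurs with its full footprint inside
#' the given TSS-relative window, on the forward strand or (if
#' `both_strands`) with a reverse-strand site (i.e. the reverse complement
#' of the pattern occurs on the given strand).
#'
#' @param seqs character vector or `DNAStringSet` of equal-length sequences.
#' @param pattern IUPAC consensus string (codes `ACGTRYSWKMBDHVN`).
#' @param window TSS-relative closed interval `c(from, to)` (e.g.
#'   `c(-250, -1)`), or `NULL` for the whole sequence.
#' @param both_strands also accept reverse-strand matches.
#' @param tss_offset TSS-relative coordinate of the first residue.
#' @return list with `match` (logical per sequence) and `positions`
#'   (data frame `seq_id`, `start`, `end`, `strand`, internal 1-based).
#' @export
scan_consensus <- function(seqs, pattern, window = NULL, both_strands = TRUE,
                           tss_offset = -500L) {
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pattern))
    stop("invalid IUPAC letter in pattern: ", pattern)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  L <- unique(Biostrings::width(seqs))
  if (length(L) != 1L) stop("sequences must all have the same length")
  if (is.null(window)) {
    lo <- 1L; hi <- L
  } else {
    lo <- window[1] - tss_offset + 1L
    hi <- window[2] - tss_offset + 1L
    if (lo < 1L || hi > L || lo > hi) stop("window outside the sequence span")
  }
  pats <- list(`+` = Biostrings::DNAString(pattern))
  if (both_strands)
    pats$`-` <- Biostrings::reverseComplement(pats$`+`)
  hits <- list()
  for (strand in names(pats)) {
    m <- Biostrings::vmatchPattern(pats[[strand]], seqs, fixed = FALSE)
    for (i in seq_along(seqs)) {
      r <- m[[i]]
      r <- r[IRanges::start(r) >= lo & IRanges::end(r) <= hi]
      if (length(r) > 0L)
        hits[[length(hits) + 1L]] <- data.frame(
          seq_id = names(seqs)[i], start = IRanges::start(r),
          end = IRanges::end(r), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  positions <- if (length(hits)) do.call(rbind, hits)
  else data.frame(seq_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0))
  list(match = setNames(names(seqs) %in% positions$seq_id, names(seqs)),
       positions = positions)
}

#' 2x2 contingency table of consensus matches
#'
#' @param a foreground match count.
#' @param b foreground no-match count.
#' @param c background match count.
#' @param d background no-match count.
#' @return a `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != floor(v))) stop("counts must be non-negative integers")
  if (a + b < 1 || c + d < 1) stop("each class needs at least one observation")
  structure(as.list(v), class = "contingency_2x2")
}

#' Sensitivity, false positive rate, precision, and F-measure
#'
#' `Sn = a/(a+b)`, `FPR = c/(c+d)`, `precision = a/(a+c)` (0 when nothing
#' matches), and `F` the harmonic mean of precision and `Sn` (0 when both
#' are 0). The `*_pct` entries apply the report rounding: half-up to integer
#' percent, F to three decimals.
#'
#' @param t a [contingency_2x2()].
#' @return named list with `Sn`, `FPR`, `precision`, `F`, `Sn_pct`,
#'   `FPR_pct`, `F_rounded`.
#' @export
contingency_stats <- function(t) {
  sn <- t$a / (t$a + t$b)
  fpr <- t$c / (t$c + t$d)
  prec <- if (t$a + t$c == 0) 0 else t$a / (t$a + t$c)
  f <- if (prec + sn == 0) 0 else 2 * prec * sn / (prec + sn)
  list(Sn = sn, FPR = fpr, precision = prec, F = f,
       Sn_pct = round_half_up(100 * sn),
       FPR_pct = round_half_up(100 * fpr),
       F_rounded = round_half_up(f, 3))
}

#' One-sided Fisher's exact test for foreground enrichment
#'
#' Hypergeometric tail probability that matches are enriched in the
#' foreground row of the 2x2 table.
#'
#' @param t a [contingency_2x2()].
#' @return p-value in (0, 1\].
#' @export
fisher_exact_onesided <- function(t) {
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  fisher.test(m, alternative = "greater")$p.value
}

#' One-sided two-proportion z-test (pooled variance)
#'
#' Normal-approximation test of `p1` vs `p2` with the pooled estimate
#' `p = (k1 + k2) / (n1 + n2)`:
#' `z = (p1_hat - p2_hat) / sqrt(p (1 - p) (1/n1 + 1/n2))`.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param direction `"greater"` tests `p1 > p2` (alias `"increase"`),
#'   `"less"` tests `p1 < p2` (alias `"decrease"`).
#' @return p-value.
#' @export
binomial_proportion_test_onesided <- function(k1, n1, k2, n2,
                                              direction = c("greater", "less",
                                                            "increase", "decrease")) {
  direction <- match.arg(direction)
  direction <- switch(direction, increase = "greater", decrease = "less",
                      direction)
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1) {
    message("degenerate pooled proportion; p-value defined as 1")
    return(1)
  }
  z <- (k1 / n1 - k2 / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  pnorm(z, lower.tail = (direction == "less"))
}

#' Consensus-enrichment report for a foreground/background pair
#'
#' Scans both sets with [scan_consensus()], builds the 2x2 match table and
#' reports [contingency_stats()], [fisher_exact_onesided()] and the
#' one-sided binomial proportion test of match rates.
#'
#' @inheritParams scan_consensus
#' @param fg,bg foreground and background sequence sets.
#' @return list with `table` ([contingency_2x2()]), `stats`, `fisher_p`,
#'   `binomial_p`.
#' @export
consensus_enrichment <- function(fg, bg, pattern, window = NULL,
                                 both_strands = TRUE, tss_offset = -500L) {
  mf <- scan_consensus(fg, pattern, window, both_strands, tss_offset)$match
  mb <- scan_consensus(bg, pattern, window, both_strands, tss_offset)$match
  t <- contingency_2x2(sum(mf), sum(!mf), sum(mb), sum(!mb))
  list(table = t, stats = contingency_stats(t),
       fisher_p = fisher_exact_onesided(t),
       binomial_p = binomial_proportion_test_onesided(
         sum(mf), length(mf), sum(mb), length(mb), direction = "greater"))
}
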