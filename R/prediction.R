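# Binding-site calling from the trained model: per-position joint
# posteriors, a control-derived empirical score distribution, and
# thresholded site prediction.

#' Empirical PWM from posterior-expected site counts
#'
#' The motif as observed in the predicted binding sites: expected letter
#' counts per motif column under the joint binding posterior
#' `P(c = 1, u, strand | x)` (reverse-strand sites contribute their reverse
#' complement), accumulated over the given sequences and normalized with a
#' small pseudo-count. This is the motif a sequence logo of the predictions
#' displays, and it is typically sharper than the discriminatively fitted
#' PWM parameters, which only grow as crisp as the classification margins
#' require.
#'
#' With `min_posterior > 0` (default 0.5), each sequence contributes the
#' hard-assigned letters of its best site — the position maximizing the
#' strand-summed joint posterior, read on the strand with the larger share —
#' if that posterior exceeds the cutoff; uncertain sequences contribute
#' nothing. Summing the strands matters for near-palindromic motifs, whose
#' posterior mass splits evenly between the two strand components. With
#' `min_posterior = 0`, soft posterior-expected counts over all positions
#' are used instead (these are slightly blurred by the residual mass on
#' non-site positions).
#'
#' @param model `trained_posmotif` or [zoops_params()].
#' @param x sequences whose predicted sites define the motif (typically the
#'   foreground set).
#' @param pseudo pseudo-count added per letter and column.
#' @param min_posterior joint-posterior cutoff for hard site assignment;
#'   0 switches to soft expected counts.
#' @return a [new_pwm()].
#' @export
predicted_site_pwm <- function(model, x, pseudo = 0.5, min_posterior = 0.5) {
  fg <- if (inherits(model, "zoops_params")) model else model$fg
  enc <- as_enc(x)
  w <- ncol(fg$pwm)
  f <- zoops_forward(enc, fg)
  if (min_posterior > 0) {
    m <- matrix(pseudo, 4, w)
    for (i in seq_len(nrow(enc))) {
      rf <- f$r_fwd[i, ]; rr <- f$r_rev[i, ]
      u <- which.max(rf + rr)
      if (rf[u] + rr[u] <= min_posterior) next
      site <- if (rf[u] >= rr[u]) enc[i, u:(u + w - 1L)]
      else 5L - rev(enc[i, u:(u + w - 1L)])   # reverse complement
      m[cbind(site, seq_len(w))] <- m[cbind(site, seq_len(w))] + 1
    }
  } else {
    gc <- zoops_grad_counts_cpp(enc - 1L, f$r_fwd, f$r_rev,
                                numeric(nrow(enc)), w)
    m <- gc$G_M + pseudo
  }
  new_pwm(sweep(m, 2, colSums(m), "/"))
}

# strand-summed per-position scores plus argmax strand, for a sequence set
position_scores <- function(x, fg) {
  f <- zoops_forward(as_enc(x), fg)
  list(score = f$r_fwd + f$r_rev,
       strand = ifelse(f$r_fwd >= f$r_rev, "+", "-"))
}

#' Control-derived background score distribution
#'
#' Computes the strand-summed joint binding posterior `P(c = 1, u | x)` for
#' every valid start position of every control sequence, yielding the
#' empirical score distribution against which p-values are calibrated.
#'
#' @param control control sequences (character, `DNAStringSet`, or encoded
#'   matrix).
#' @param model a `trained_posmotif` or [zoops_params()].
#' @return a `background_scores` object: sorted ascending numeric vector
#'   with attribute `w`.
#' @export
background_distribution <- function(control, model) {
  fg <- if (inherits(model, "zoops_params")) model else model$fg
  enc <- as_enc(control)
  if (nrow(enc) == 0L) stop("empty control set")
  sc <- position_scores(enc, fg)$score
  structure(sort(as.numeric(sc)), w = ncol(fg$pwm),
            class = "background_scores")
}

#' Empirical p-value of a binding score
#'
#' The fraction of control-position scores that strictly exceed the given
#' score.
#'
#' @param score numeric vector of posterior scores.
#' @param bg a [background_distribution()].
#' @return p-values in \[0,1\], one per score.
#' @export
empirical_pvalue <- function(score, bg) {
  n <- length(bg)
  if (n == 0L) stop("empty background distribution")
  (n - findInterval(score, unclass(bg))) / n
}

#' Call binding sites below an empirical p-value threshold
#'
#' Scores every position of every sequence under the foreground model,
#' assigns empirical p-values from the control distribution, and returns
#' exactly the positions with `p_value < threshold` (strict, so threshold 0
#' returns nothing). The reported strand is the one with the larger
#' strand-specific posterior. Overlapping predictions are all reported.
#'
#' @param x sequences to scan (named character vector or `DNAStringSet`).
#' @param model `trained_posmotif` or [zoops_params()].
#' @param bg a [background_distribution()].
#' @param threshold p-value threshold (default 1e-3).
#' @param tss_offset TSS-relative coordinate of the first residue, used for
#'   the reported `start_tss` column.
#' @return data frame of class `site_predictions`, sorted by ascending
#'   p-value, then sequence id, then position, with columns `seq_id`,
#'   `start` (1-based internal), `end`, `start_tss`, `strand`, `score`,
#'   `p_value`.
#' @export
call_sites <- function(x, model, bg, threshold = 1e-3, tss_offset = -500L) {
  fg <- if (inherits(model, "zoops_params")) model else model$fg
  if (!inherits(model, "zoops_params") && !is.null(model$tss_offset))
    tss_offset <- model$tss_offset
  if (is.character(x) && is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  ids <- if (inherits(x, "XStringSet")) names(x) else names(x)
  enc <- as_enc(x)
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(enc)))
  w <- ncol(fg$pwm)
  ps <- position_scores(enc, fg)
  S <- ncol(ps$score)
  df <- data.frame(
    seq_id = rep(ids, each = S),
    start = rep(seq_len(S), times = nrow(enc)),
    score = as.numeric(t(ps$score)),
    strand = as.character(t(ps$strand)),
    stringsAsFactors = FALSE)
  df$p_value <- empirical_pvalue(df$score, bg)
  df <- df[df$p_value < threshold, , drop = FALSE]
  df$end <- df$start + w - 1L
  df$start_tss <- df$start - 1L + as.integer(tss_offset)
  df <- df[order(df$p_value, df$seq_id, df$start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df <- df[, c("seq_id", "start", "end", "start_tss", "strand", "score",
               "p_value")]
  class(df) <- c("site_predictions", "data.frame")
  df
}

#' Write site predictions as BED6
#'
#' The chrom column carries the sequence id; intervals are 0-based
#' half-open; name is the rank in the p-value ordering; score is
#' `round(1000 * (1 - p_value))`. A sidecar TSV (`<path>.tsv`) adds
#' TSS-relative coordinates, the raw posterior and the p-value at full
#' precision.
#'
#' @param sites a [call_sites()] data frame.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$seq_id,
    ranges = IRanges::IRanges(start = sites$start, end = sites$end),
    strand = sites$strand)
  gr$name <- as.character(seq_len(nrow(sites)))
  gr$score <- round(1000 * (1 - sites$p_value))
  rtracklayer::export(gr, path, format = "BED")
  utils::write.table(
    data.frame(sites, rank = seq_len(nrow(sites))),
    file = paste0(path, ".tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Read annotated site intervals from BED
#'
#' The chrom column is interpreted as the sequence id. Returns 1-based
#' closed intervals as used internally.
#'
#' @param path BED file path.
#' @return data frame with `seq_id`, `start`, `end`, `strand`.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
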