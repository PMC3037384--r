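#' Construct a position weight matrix
#'
#' @param mat 4 x w numeric matrix of letter probabilities (rows A,C,G,T) or
#'   a w x 4 matrix, which is transposed.
#' @return a `pwm` object: a 4 x w matrix with row names A,C,G,T.
#' @export
new_pwm <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4 && ncol(mat) == 4) mat <- t(mat)
  if (nrow(mat) != 4) stop("a PWM needs 4 letter rows")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) stop("PWM columns must sum to 1 (within 1e-9)")
  rownames(mat) <- DNA_LETTERS
  structure(mat, class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM, %d columns; consensus %s\n", ncol(x), pwm_consensus(x)))
  print(unclass(round(x, 3)))
  invisible(x)
}

#' Majority-letter consensus string of a PWM
#'
#' @param pwm a `pwm` or 4 x w probability matrix.
#' @return single character string, one majority letter per column.
#' @export
pwm_consensus <- function(pwm) paste(DNA_LETTERS[apply(pwm, 2, which.max)], collapse = "")

#' Reverse complement of a PWM
#'
#' Reverses the column order and swaps complementary letter rows.
#'
#' @param pwm a `pwm` or a 4 x w probability matrix.
#' @return the reverse-complement `pwm`.
#' @export
reverse_complement_pwm <- function(pwm) {
  m <- unclass(as.matrix(pwm))
  new_pwm(m[4:1, rev(seq_len(ncol(m))), drop = FALSE])
}

#' Positional prior over motif start positions
#'
#' A mixture of a uniform distribution over all valid starts and a
#' discretized skew normal. The skew normal is parameterized by location
#' `xi` (in internal 1-based start coordinates), scale `omega` (bp) and
#' shape `alpha_shape`; shape 0 recovers a Gaussian. The uniform component
#' has weight `gamma`; `gamma = 1` is a flat prior.
#'
#' @param gamma mixture weight of the uniform component, in \[0,1\].
#' @param xi skew-normal location (bp, internal start coordinates).
#' @param omega skew-normal scale (bp), > 0.
#' @param alpha_shape skew-normal shape (dimensionless).
#' @return a `position_prior` object.
#' @export
position_prior <- function(gamma = 1, xi = 0, omega = 1, alpha_shape = 0) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0,1]")
  if (omega <= 0) stop("omega must be positive")
  structure(list(gamma = gamma, xi = xi, omega = omega,
                 alpha_shape = alpha_shape),
            class = "position_prior")
}

# log skew-normal density at points y (unnormalized over the lattice)
log_skew_normal <- function(y, xi, omega, alpha) {
  z <- (y - xi) / omega
  log(2) - log(omega) + dnorm(z, log = TRUE) + pnorm(alpha * z, log.p = TRUE)
}

#' Discretized positional prior over valid motif starts
#'
#' Evaluates the skew-normal density at the integer start positions
#' `1..L-w+1`, renormalizes it over that lattice, and mixes it with the
#' uniform distribution: `gamma * uniform + (1-gamma) * skew`.
#'
#' @param prior a [position_prior()].
#' @param L sequence length (bp).
#' @param w motif width (bp), `w <= L`.
#' @return probability vector of length `L - w + 1` over start positions.
#' @export
position_pmf <- function(prior, L, w) {
  if (w > L) stop("motif width exceeds sequence length")
  S <- L - w + 1L
  u <- seq_len(S)
  unif <- rep(1 / S, S)
  if (prior$gamma >= 1) return(unif)
  lf <- log_skew_normal(u, prior$xi, prior$omega, prior$alpha_shape)
  m <- max(lf)
  sk <- exp(lf - m)
  sk <- sk / sum(sk)
  prior$gamma * unif + (1 - prior$gamma) * sk
}

#' Full ZOOPS foreground model
#'
#' @param p_occ probability that a sequence contains a binding site.
#' @param pwm a [new_pwm()] motif model.
#' @param flanking length-4 probability vector (A,C,G,T) of the order-0
#'   flanking model.
#' @param position a [position_prior()].
#' @param strand_weight probability that a site lies on the forward strand.
#' @return a `zoops_params` object.
#' @export
zoops_params <- function(p_occ, pwm, flanking, position, strand_weight = 0.5) {
  if (p_occ < 0 || p_occ > 1) stop("p_occ must lie in [0,1]")
  if (strand_weight < 0 || strand_weight > 1) stop("strand_weight must lie in [0,1]")
  flanking <- as.numeric(flanking)
  if (length(flanking) != 4 || any(flanking < 0) || abs(sum(flanking) - 1) > 1e-9)
    stop("flanking must be a probability vector over {A,C,G,T}")
  if (!inherits(pwm, "pwm")) pwm <- new_pwm(pwm)
  structure(list(p_occ = p_occ, strand_weight = strand_weight, pwm = pwm,
                 flanking = setNames(flanking, DNA_LETTERS), position = position),
            class = "zoops_params")
}

#' @export
print.zoops_params <- function(x, ...) {
  cat(sprintf("ZOOPS model: w = %d, p_occ = %.3f, strand_weight = %.2f\n",
              ncol(x$pwm), x$p_occ, x$strand_weight))
  cat(sprintf("  position prior: gamma = %.3f, xi = %.1f, omega = %.1f, shape = %.2f\n",
              x$position$gamma, x$position$xi, x$position$omega,
              x$position$alpha_shape))
  cat(sprintf("  consensus: %s\n", pwm_consensus(x$pwm)))
  invisible(x)
}

#' Homogeneous Markov background model
#'
#' Order-`d` homogeneous Markov chain over `{A,C,G,T}` with ascending-order
#' start conditionals: position 1 uses an order-0 distribution, position 2 an
#' order-1 conditional, ..., position `d` an order-`d-1` conditional, and all
#' later positions the order-`d` conditionals.
#'
#' @param order Markov order `d >= 0`.
#' @param blocks list of `d + 1` matrices; block `k` (1-based) is a
#'   `4 x 4^(k-1)` matrix of conditional letter probabilities given the
#'   `k-1` preceding letters. Context column index is
#'   `1 + sum(code(x[l-j]) * 4^(j-1))` with the most recent letter at the
#'   lowest digit. If missing, uniform distributions are used.
#' @return a `background_model` object.
#' @export
background_model <- function(order = 3L, blocks = NULL) {
  order <- as.integer(order)
  if (order < 0) stop("order must be >= 0")
  if (is.null(blocks)) {
    blocks <- lapply(0:order, function(k) matrix(0.25, 4, 4^k))
  }
  if (length(blocks) != order + 1L) stop("need order + 1 conditional blocks")
  for (k in seq_along(blocks)) {
    b <- as.matrix(blocks[[k]])
    if (nrow(b) != 4 || ncol(b) != 4^(k - 1))
      stop("block ", k, " must be 4 x 4^", k - 1)
    if (any(b < 0) || any(abs(colSums(b) - 1) > 1e-9))
      stop("conditional distributions in block ", k, " must sum to 1")
    blocks[[k]] <- b
  }
  structure(list(order = order, blocks = blocks), class = "background_model")
}

# flatten log conditional probabilities to the cell layout used by
# markov_count_matrix_cpp (block-wise, cell = context*4 + letter)
bg_log_cells <- function(bg) {
  unlist(lapply(bg$blocks, function(b) as.numeric(log(b))), use.names = FALSE)
}

#' Class priors of the two-class mixture
#'
#' @param pi_fg prior probability of the foreground class.
#' @return a `class_priors` object with `pi_fg` and `pi_bg`.
#' @export
class_priors <- function(pi_fg = 0.5) {
  if (pi_fg <= 0 || pi_fg >= 1) stop("pi_fg must lie strictly in (0,1)")
  structure(list(pi_fg = pi_fg, pi_bg = 1 - pi_fg), class = "class_priors")
}

# shared forward-pass plumbing: x may be character vector / DNAStringSet /
# encoded integer matrix
as_enc <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  encode_seqs(x)
}

zoops_forward <- function(enc, params) {
  w <- ncol(params$pwm)
  L <- ncol(enc)
  if (w > L) stop("motif width exceeds sequence length")
  logT <- log(position_pmf(params$position, L, w))
  zoops_forward_cpp(enc - 1L, log(unclass(params$pwm)), log(params$flanking),
                    logT, params$p_occ, params$strand_weight)
}

#' ZOOPS log-likelihood of sequences under the foreground model
#'
#' Computes `log P(x | theta)` under the zero-or-one-occurrence mixture: with
#' probability `1 - p_occ` the whole sequence is emitted by the flanking
#' model; with probability `p_occ` a start `u` is drawn from the positional
#' prior, a strand from `strand_weight`, the site window from the PWM (or its
#' reverse complement) and the flanks from the flanking model. All
#' computation is in log space with log-sum-exp.
#'
#' @param x sequences: character vector, `DNAStringSet`, or encoded matrix.
#' @param params a [zoops_params()] model.
#' @return numeric vector of per-sequence log-likelihoods.
#' @export
zoops_log_likelihood <- function(x, params) {
  zoops_forward(as_enc(x), params)$loglik
}

#' Log-likelihood under the background Markov model
#'
#' @param x sequences (character vector, `DNAStringSet`, or encoded matrix).
#' @param bg a [background_model()].
#' @return numeric vector of per-sequence log-likelihoods.
#' @export
background_log_likelihood <- function(x, bg) {
  enc <- as_enc(x)
  C <- markov_count_matrix_cpp(enc - 1L, bg$order)
  as.numeric(C %*% bg_log_cells(bg))
}

#' Posterior probability of the foreground class
#'
#' Bayes rule over the two class models: foreground ZOOPS vs background
#' Markov chain, with class priors. Computed via log-sum-exp.
#'
#' @param x sequences.
#' @param fg foreground [zoops_params()].
#' @param bg [background_model()].
#' @param priors [class_priors()].
#' @return vector of `P(foreground | x)` in \[0,1\].
#' @export
class_posterior <- function(x, fg, bg, priors) {
  enc <- as_enc(x)
  sfg <- log(priors$pi_fg) + zoops_log_likelihood(enc, fg)
  sbg <- log(priors$pi_bg) + background_log_likelihood(enc, bg)
  1 / (1 + exp(sbg - sfg))
}

#' Joint posterior of site occurrence and start position
#'
#' For each sequence, returns `P(c = 1, u, strand | x)` for every valid start
#' `u` and both strands, plus the no-site posterior `P(c = 0 | x)`. These per
#' (position, strand) probabilities are the binding-site scores used for
#' prediction.
#'
#' @param x sequences.
#' @param params a [zoops_params()].
#' @return list with `fwd` and `rev` (N x (L-w+1) matrices of joint
#'   posteriors) and `no_site` (length-N vector); rows sum to 1 with
#'   `no_site`.
#' @export
joint_binding_posterior <- function(x, params) {
  f <- zoops_forward(as_enc(x), params)
  list(fwd = f$r_fwd, rev = f$r_rev, no_site = f$r0)
}
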