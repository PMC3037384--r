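# Independent reference implementations ("oracles") used to cross-check the
# package. They share no code with the package internals: everything is
# written directly from the model definition in plain R.

ALPHA <- c("A", "C", "G", "T")

rand_seq <- function(L, freqs = rep(0.25, 4)) {
  paste(sample(ALPHA, L, replace = TRUE, prob = freqs), collapse = "")
}

rand_pwm <- function(w, conc = 1) {
  m <- matrix(rgamma(4 * w, conc), 4, w)
  new_pwm(sweep(m, 2, colSums(m), "/"))
}

rand_simplex <- function(k, conc = 1) {
  p <- rgamma(k, conc)
  p / sum(p)
}

str_to_code <- function(s) match(strsplit(s, "")[[1]], ALPHA)

rc_codes <- function(codes) rev(5L - codes)

# discretized skew-normal / uniform positional law, straight from the formula
oracle_position_pmf <- function(gamma, xi, omega, alpha, L, w) {
  S <- L - w + 1
  u <- seq_len(S)
  if (gamma >= 1) return(rep(1 / S, S))
  z <- (u - xi) / omega
  f <- (2 / omega) * dnorm(z) * pnorm(alpha * z)
  gamma / S + (1 - gamma) * f / sum(f)
}

# exhaustive ZOOPS likelihood: sum over occurrence c, start u and strand
oracle_zoops_lik <- function(codes, params) {
  w <- ncol(params$pwm)
  L <- length(codes)
  Tm <- oracle_position_pmf(params$position$gamma, params$position$xi,
                            params$position$omega, params$position$alpha_shape,
                            L, w)
  M <- unclass(params$pwm)
  Fp <- as.numeric(params$flanking)
  flank_all <- prod(Fp[codes])
  lik <- (1 - params$p_occ) * flank_all
  for (u in seq_len(L - w + 1)) {
    site <- codes[u:(u + w - 1)]
    flanks <- prod(Fp[codes[setdiff(seq_len(L), u:(u + w - 1))]])
    m_fwd <- prod(M[cbind(site, seq_len(w))])
    m_rev <- prod(M[cbind(rc_codes(site), seq_len(w))])
    lik <- lik + params$p_occ * Tm[u] * flanks *
      (params$strand_weight * m_fwd + (1 - params$strand_weight) * m_rev)
  }
  lik
}

# exhaustive joint posterior P(c = 1, u, strand | x)
oracle_joint_posterior <- function(codes, params) {
  w <- ncol(params$pwm)
  L <- length(codes)
  Tm <- oracle_position_pmf(params$position$gamma, params$position$xi,
                            params$position$omega, params$position$alpha_shape,
                            L, w)
  M <- unclass(params$pwm)
  Fp <- as.numeric(params$flanking)
  S <- L - w + 1
  fwd <- rev <- numeric(S)
  for (u in seq_len(S)) {
    site <- codes[u:(u + w - 1)]
    flanks <- prod(Fp[codes[setdiff(seq_len(L), u:(u + w - 1))]])
    fwd[u] <- params$p_occ * Tm[u] * flanks * params$strand_weight *
      prod(M[cbind(site, seq_len(w))])
    rev[u] <- params$p_occ * Tm[u] * flanks * (1 - params$strand_weight) *
      prod(M[cbind(rc_codes(site), seq_len(w))])
  }
  none <- (1 - params$p_occ) * prod(Fp[codes])
  z <- none + sum(fwd) + sum(rev)
  list(fwd = fwd / z, rev = rev / z, no_site = none / z)
}

# order-d homogeneous Markov chain likelihood with ascending-order starts
oracle_markov_lik <- function(codes, bg) {
  ll <- 0
  for (l in seq_along(codes)) {
    k <- min(l - 1, bg$order)           # context length available
    b <- bg$blocks[[k + 1]]
    ctx <- 1
    if (k > 0) {
      prev <- codes[(l - 1):(l - k)]     # most recent letter first
      ctx <- 1 + sum((prev - 1) * 4^(seq_len(k) - 1))
    }
    ll <- ll + log(b[codes[l], ctx])
  }
  ll
}

# one-sided Fisher's exact p by hypergeometric tail summation
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b          # foreground size
  n <- c + d          # background size
  k <- a + c          # total matches
  sum(dhyper(a:min(m, k), m, n, k))
}

# nucleotide precision/recall by brute-force coverage vectors
oracle_nucleotide_pr <- function(pred, truth, L = 1000) {
  ids <- unique(c(pred$seq_id, truth$seq_id))
  cov <- function(df, id) {
    v <- logical(L)
    rows <- df[df$seq_id == id, , drop = FALSE]
    for (i in seq_len(nrow(rows))) v[rows$start[i]:rows$end[i]] <- TRUE
    v
  }
  tp <- np <- nt <- 0
  for (id in ids) {
    pv <- cov(pred, id); tv <- cov(truth, id)
    tp <- tp + sum(pv & tv); np <- np + sum(pv); nt <- nt + sum(tv)
  }
  c(rn = tp / nt, pn = if (np == 0) 1 else tp / np)
}

# central finite difference of a scalar function
fd_gradient <- function(fn, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps
    (fn(x + e) - fn(x - e)) / (2 * eps)
  }, numeric(1))
}

# deterministic well-conserved 8-column test motif (consensus AGTACGTA)
# and a clearly different decoy (consensus GGCCTCGG); both ~1.4 bits/col
acceptance_true_pwm <- function() {
  new_pwm(matrix(c(
    .91, .03, .03, .03,   .03, .03, .91, .03,   .03, .03, .03, .91,
    .88, .06, .03, .03,   .03, .91, .03, .03,   .06, .03, .88, .03,
    .03, .03, .03, .91,   .91, .03, .03, .03), nrow = 4))
}

acceptance_decoy_pwm <- function() {
  new_pwm(matrix(c(
    .03, .03, .91, .03,   .03, .03, .91, .03,   .03, .91, .03, .03,
    .03, .91, .03, .03,   .03, .03, .03, .91,   .03, .91, .03, .03,
    .03, .03, .91, .03,   .03, .03, .91, .03), nrow = 4))
}

# the synthetic benchmark pair shared by acceptance criteria 6 and 7:
# 140 true sites -> 200 target + 200 control promoters, L = 250,
# Gaussian placement (mean 100, sd 30)
acceptance_benchmark_pair <- function() {
  L <- 250
  pool <- random_promoters(500, L, seed = 21)
  sites <- sample_sites(acceptance_true_pwm(), 140, seed = 22)
  implant_sites(implant_spec(sites, pool,
                             placement = list(mean = 100, sd = 30),
                             seed = 23))
}
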