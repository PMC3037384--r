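# Unconstrained parameterization used by the numerical optimizer.
#
# Probability simplexes are represented as log-odds against the first letter
# (A, or the first cell of a block), omega via log, and gamma / p_occ / pi_fg
# via logit. Priors are evaluated on the natural-parameter scale (no
# transform Jacobians).

softmax4 <- function(eta3) {
  e <- c(0, eta3)
  e <- exp(e - max(e))
  e / sum(e)
}

logodds4 <- function(p) log(p[2:4] / p[1])

logit <- function(p) log(p / (1 - p))
inv_logit <- function(eta) 1 / (1 + exp(-eta))

# gradient wrt the 3 free log-odds from a gradient G wrt the 4 log
# probabilities: d/deta_j = G_j - sum(G) * p_j  (j = letters 2..4)
softmax_grad <- function(G, p) G[2:4] - sum(G) * p[2:4]

# A parameter layout for given motif width / background order. Blocks:
#   pwm       3 * w
#   flank     3
#   bg        3 * (#conditional vectors) over blocks of order 0..d
#   p_occ     1
#   pi_fg     1
#   position  4 (logit gamma, xi, log omega, alpha)   [if learn_position]
param_spec <- function(w, bg_order, learn_position = TRUE) {
  n_bg_vec <- sum(4^(0:bg_order))
  sizes <- c(pwm = 3L * w, flank = 3L, bg = 3L * n_bg_vec,
             p_occ = 1L, pi_fg = 1L,
             position = if (learn_position) 4L else 0L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  list(w = w, bg_order = bg_order, learn_position = learn_position,
       n_bg_vec = n_bg_vec, sizes = sizes, starts = starts, ends = ends,
       n = sum(sizes))
}

pack_theta <- function(theta, spec) {
  eta <- numeric(spec$n)
  idx <- function(nm) seq.int(spec$starts[[nm]], spec$ends[[nm]])
  eta[idx("pwm")] <- as.numeric(apply(unclass(theta$fg$pwm), 2, logodds4))
  eta[idx("flank")] <- logodds4(theta$fg$flanking)
  eta[idx("bg")] <- as.numeric(unlist(lapply(theta$bg$blocks, function(b)
    apply(b, 2, logodds4)), use.names = FALSE))
  eta[idx("p_occ")] <- logit(theta$fg$p_occ)
  eta[idx("pi_fg")] <- logit(theta$priors$pi_fg)
  if (spec$learn_position) {
    pos <- theta$fg$position
    eta[idx("position")] <- c(logit(pos$gamma), pos$xi, log(pos$omega),
                              pos$alpha_shape)
  }
  eta
}

unpack_theta <- function(eta, spec, strand_weight = 0.5) {
  idx <- function(nm) seq.int(spec$starts[[nm]], spec$ends[[nm]])
  pwm <- apply(matrix(eta[idx("pwm")], nrow = 3), 2, softmax4)
  flank <- softmax4(eta[idx("flank")])
  bg_eta <- matrix(eta[idx("bg")], nrow = 3)
  blocks <- vector("list", spec$bg_order + 1L)
  off <- 0L
  for (k in 0:spec$bg_order) {
    nc <- 4^k
    blocks[[k + 1L]] <- apply(bg_eta[, off + seq_len(nc), drop = FALSE], 2, softmax4)
    off <- off + nc
  }
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  p_occ <- clamp(inv_logit(eta[idx("p_occ")]))
  pi_fg <- clamp(inv_logit(eta[idx("pi_fg")]))
  if (spec$learn_position) {
    pe <- eta[idx("position")]
    pos <- position_prior(gamma = inv_logit(pe[1]), xi = pe[2],
                          omega = exp(pe[3]), alpha_shape = pe[4])
  } else {
    pos <- position_prior(gamma = 1)
  }
  list(fg = zoops_params(p_occ = p_occ, pwm = new_pwm(pwm), flanking = flank,
                         position = pos, strand_weight = strand_weight),
       bg = background_model(order = spec$bg_order, blocks = blocks),
       priors = class_priors(pi_fg))
}
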