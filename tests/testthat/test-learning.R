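# small dataset reused by several learning tests: a strong 5-bp motif
# (consensus ACGCA) implanted in every foreground sequence
tiny_dataset <- function(n = 25, L = 40, seed = 42) {
  withr::with_seed(seed, {
    fg <- replicate(n, rand_seq(L))
    for (i in seq_len(n)) {
      u <- sample(L - 4, 1)
      substr(fg[i], u, u + 4) <- "ACGCA"
    }
    bg <- replicate(n, rand_seq(L))
    build_dataset(setNames(fg, paste0("f", 1:n)),
                  setNames(bg, paste0("b", 1:n)), tss_offset = -L)
  })
}

test_that("log_prior equals the hand-written sum of its terms", {
  set.seed(5)
  fg <- zoops_params(0.6, rand_pwm(3), rand_simplex(4),
                     position_prior(0.4, 10, 5, 1))
  bg <- background_model(order = 1, blocks = list(
    matrix(rand_simplex(4), 4),
    matrix(sapply(1:4, function(i) rand_simplex(4)), 4)))
  pri <- class_priors(0.45)
  h <- hyperparams(L = 40)
  ldir <- function(p, a) lgamma(length(p) * a) - length(p) * lgamma(a) +
    (a - 1) * sum(log(p))
  want <- sum(apply(unclass(fg$pwm), 2, ldir, a = 2)) +     # ess 4 / 4 cells
    ldir(as.numeric(fg$flanking), 2) +
    sum(vapply(bg$blocks, function(b) sum(apply(b, 2, ldir, a = 2)),
               numeric(1))) +
    ldir(c(0.45, 0.55), 3) +                                # ess 4 / 2 cells
    ldir(c(0.6, 0.4), 3) +
    dbeta(0.4, 2, 2, log = TRUE) +
    dnorm(10, (40 + 1) / 2, 20, log = TRUE) +
    dnorm(1, 0, 4, log = TRUE) +
    dgamma(5, shape = 2, rate = 8 / 40, log = TRUE)
  expect_equal(log_prior(fg, bg, pri, h), want, tolerance = 1e-12)
  # position terms drop out when excluded
  expect_lt(abs(log_prior(fg, bg, pri, h, include_position = FALSE) -
                  (want - dbeta(0.4, 2, 2, log = TRUE) -
                     dnorm(10, 20.5, 20, log = TRUE) -
                     dnorm(1, 0, 4, log = TRUE) -
                     dgamma(5, 2, rate = 0.2, log = TRUE))), 1e-12)
})

test_that("msp_objective decomposes into conditional likelihood and prior", {
  d <- tiny_dataset()
  set.seed(6)
  fg <- zoops_params(0.5, rand_pwm(5), rand_simplex(4),
                     position_prior(0.5, 20, 10, 0))
  bg <- background_model(order = 0, blocks = list(matrix(rand_simplex(4), 4)))
  pri <- class_priors(0.5)
  h <- hyperparams(d$L)
  obj <- msp_objective(fg, bg, pri, d, h)
  # conditional part recomputed from first principles via the class models
  ll_fg <- log(0.5) + zoops_log_likelihood(d$enc, fg)
  ll_bg <- log(0.5) + background_log_likelihood(d$enc, bg)
  y <- d$labels == "foreground"
  cond <- sum(ifelse(y, ll_fg, ll_bg) - log(exp(ll_fg) + exp(ll_bg)))
  expect_equal(obj, cond + log_prior(fg, bg, pri, h), tolerance = 1e-9)
})

test_that("analytic MSP gradient matches central finite differences", {
  d <- tiny_dataset(n = 8, L = 20)
  h <- hyperparams(d$L)
  for (lp in c(TRUE, FALSE)) {
    spec <- posmotif:::param_spec(3L, 1L, learn_position = lp)
    cl <- posmotif:::make_msp_closure(d, h, spec)
    set.seed(11)
    eta <- rnorm(spec$n, sd = 0.5)
    g <- cl$gr(eta)
    g_fd <- fd_gradient(cl$fn, eta)
    expect_equal(g, g_fd, tolerance = 1e-5)
  }
})

test_that("pack/unpack of the unconstrained parameters round-trips", {
  set.seed(13)
  spec <- posmotif:::param_spec(4L, 2L, learn_position = TRUE)
  th <- list(fg = zoops_params(0.37, rand_pwm(4), rand_simplex(4),
                               position_prior(0.21, 17.3, 6.2, -0.8)),
             bg = background_model(order = 2, blocks = list(
               matrix(rand_simplex(4), 4),
               matrix(sapply(1:4, function(i) rand_simplex(4)), 4),
               matrix(sapply(1:16, function(i) rand_simplex(4)), 4))),
             priors = class_priors(0.62))
  back <- posmotif:::unpack_theta(posmotif:::pack_theta(th, spec), spec)
  expect_equal(unclass(back$fg$pwm), unclass(th$fg$pwm), tolerance = 1e-12)
  expect_equal(as.numeric(back$fg$flanking), as.numeric(th$fg$flanking),
               tolerance = 1e-12)
  expect_equal(back$fg$p_occ, th$fg$p_occ, tolerance = 1e-12)
  expect_equal(back$priors$pi_fg, th$priors$pi_fg, tolerance = 1e-12)
  expect_equal(back$fg$position[c("gamma", "xi", "omega", "alpha_shape")],
               th$fg$position[c("gamma", "xi", "omega", "alpha_shape")],
               tolerance = 1e-12)
  for (k in 1:3) expect_equal(back$bg$blocks[[k]], th$bg$blocks[[k]],
                              tolerance = 1e-12)
})

test_that("apply_modification edits the window and shifts the prior location", {
  set.seed(17)
  p <- zoops_params(0.5, rand_pwm(6), rand_simplex(4),
                    position_prior(0.3, 40, 10, 0))
  sr <- apply_modification(p, modification("shift_right", k = 2))
  expect_equal(unclass(sr$pwm)[, 1:4], unclass(p$pwm)[, 3:6])
  expect_equal(unclass(sr$pwm)[, 5:6], matrix(0.25, 4, 2),
               ignore_attr = TRUE)
  expect_equal(sr$position$xi, 42)
  tr <- apply_modification(p, modification("truncate", left = 1, right = 2))
  expect_equal(unclass(tr$pwm), unclass(p$pwm)[, 2:4])
  expect_equal(tr$position$xi, 41)
  ex <- apply_modification(p, modification("expand"))
  expect_equal(ncol(ex$pwm), 8)
  expect_equal(ex$position$xi, 39)
  # spec composition property: shift right 2 then left 2 restores columns
  # 3..6 in place, with uniform new borders
  back <- apply_modification(sr, modification("shift_left", k = 2))
  expect_equal(unclass(back$pwm)[, 3:6], unclass(p$pwm)[, 3:6])
  expect_equal(unclass(back$pwm)[, 1:2], matrix(0.25, 4, 2),
               ignore_attr = TRUE)
  expect_equal(back$position$xi, 40)
})

test_that("propose_modification implements the rule table with history", {
  cfg <- optimizer_config(min_motif_length = 4, max_motif_length = 20)
  # left-only insignificance -> shift right by that amount
  m <- propose_modification(2, 0, 10, character(0), cfg)
  expect_equal(m$type, "shift_right"); expect_equal(m$k, 2L)
  # right-only -> shift left
  m <- propose_modification(0, 3, 10, character(0), cfg)
  expect_equal(m$type, "shift_left"); expect_equal(m$k, 3L)
  # both sides -> truncate
  m <- propose_modification(1, 2, 10, character(0), cfg)
  expect_equal(m$type, "truncate")
  expect_equal(c(m$left, m$right), c(1L, 2L))
  # neither -> expand (within the length cap)
  m <- propose_modification(0, 0, 10, character(0), cfg)
  expect_equal(m$type, "expand")
  expect_null(propose_modification(0, 0, 19, character(0), cfg))
  # truncation respects the minimum width by trimming the proposal
  m <- propose_modification(3, 3, 8, character(0), cfg)
  expect_equal(8 - m$left - m$right, 4)
  # a proposal recreating a visited (width, offset) state is suppressed
  expect_null(propose_modification(2, 0, 10, "10@2", cfg, offset = 0L))
  expect_equal(propose_modification(2, 0, 10, "10@1", cfg, offset = 0L)$k, 2L)
})

test_that("optimize_msp never decreases the objective and improves the fit", {
  d <- tiny_dataset()
  h <- hyperparams(d$L)
  cfg <- optimizer_config(bg_order = 0, restarts = 1)
  set.seed(19)
  fg0 <- zoops_params(0.5, rand_pwm(5, conc = 5), rand_simplex(4, conc = 20),
                      position_prior(0.9, (d$L + 1) / 2, d$L / 4, 0))
  bg0 <- background_model(order = 0)
  pri0 <- class_priors(0.5)
  obj0 <- msp_objective(fg0, bg0, pri0, d, h)
  fit <- optimize_msp(fg0, bg0, pri0, d, h, cfg)
  expect_gte(fit$objective, obj0)
  expect_equal(msp_objective(fit$fg, fit$bg, fit$priors, d, h),
               fit$objective, tolerance = 1e-8)
})

test_that("count_predicted_promoters control mode thresholds p-values", {
  d <- tiny_dataset()
  fg <- zoops_params(0.7, new_pwm(posmotif:::seed_pwm(str_to_code("ACGCA"))),
                     rand_simplex(4, conc = 50),
                     position_prior(gamma = 1))
  n_all <- count_predicted_promoters(fg, posmotif:::fg_enc(d),
                                     control = posmotif:::bg_enc(d),
                                     p_threshold = 1)
  n_strict <- count_predicted_promoters(fg, posmotif:::fg_enc(d),
                                        control = posmotif:::bg_enc(d),
                                        p_threshold = 1e-4)
  expect_equal(n_all, 25)          # threshold 1 accepts everything
  expect_lte(n_strict, n_all)      # nesting in the threshold
})

test_that("train_posmotif learns an implanted motif on a small dataset", {
  d <- tiny_dataset(n = 30, L = 40, seed = 7)
  cfg <- optimizer_config(restarts = 2, seed = 1, init_motif_length = 5,
                          adjust_length = FALSE, bg_order = 0)
  fit <- train_posmotif(d, config = cfg)
  expect_s3_class(fit, "trained_posmotif")
  expect_equal(ncol(fit$fg$pwm), 5)
  rec <- predicted_site_pwm(fit, posmotif:::fg_enc(d))
  target <- new_pwm(diag(4)[, str_to_code("ACGCA")])   # one-hot consensus
  # the fixed-width window may sit one column off the implant; allow a
  # 4-of-5-column alignment when comparing
  expect_lt(normalized_euclidean_distance(rec, target, min_overlap = 4), 0.25)
  expect_equal(length(fit$restart_objectives), 2)
  expect_true(fit$selected_restart %in% 1:2)
  expect_true(all(c("restart", "step", "modification", "width", "objective")
                  %in% names(fit$heuristic_history)))
})
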