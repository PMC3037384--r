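# Benchmark and fixture generation: implanting annotated binding sites into
# promoter pools under uniform or Gaussian positional laws, decoy-motif
# injection, and sampling from a known ZOOPS model.

#' Number of target promoters for a benchmark
#'
#' `floor(n_sites / fraction)`: the rounding under which a fraction
#' (default 70%) of the target promoters carries exactly one implanted site.
#' A tiny epsilon guards the IEEE representation of the fraction
#' (`70 / 0.7` must give 100).
#'
#' @param n_sites number of binding sites to implant.
#' @param fraction fraction of target promoters carrying a site.
#' @return integer promoter count.
#' @export
benchmark_size <- function(n_sites, fraction = 0.7) {
  stopifnot(n_sites >= 1, fraction > 0, fraction <= 1)
  as.integer(floor(n_sites / fraction + 1e-9))
}

#' Random promoter pool
#'
#' Draws iid sequences from an order-0 letter distribution; a stand-in for a
#' database promoter pool in simulations and tests.
#'
#' @param n number of sequences.
#' @param L sequence length (bp).
#' @param freqs letter probabilities (A,C,G,T); default mildly AT-rich, as
#'   in plant promoters.
#' @param seed RNG seed (optional).
#' @return named character vector of sequences.
#' @export
random_promoters <- function(n, L, freqs = c(0.3, 0.2, 0.2, 0.3), seed = NULL) {
  draw <- function() {
    m <- matrix(sample(DNA_LETTERS, n * L, replace = TRUE, prob = freqs), n, L)
    setNames(apply(m, 1, paste, collapse = ""), paste0("prom_", seq_len(n)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Sample binding-site instances from a PWM
#'
#' Draws independent site strings column-wise from a letter-probability
#' matrix; used to build implantation site lists for benchmark pairs.
#'
#' @param pwm a [new_pwm()] or 4 x w probability matrix.
#' @param n number of site strings.
#' @param seed RNG seed (optional).
#' @return character vector of length `n`.
#' @export
sample_sites <- function(pwm, n, seed = NULL) {
  m <- unclass(as.matrix(pwm))
  draw <- function() {
    vapply(seq_len(n), function(i)
      paste(vapply(seq_len(ncol(m)), function(j)
        sample(DNA_LETTERS, 1L, prob = m[, j]), character(1)), collapse = ""),
      character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Implantation specification
#'
#' @param sites character vector of binding-site strings over `{A,C,G,T}`.
#' @param promoter_pool named character vector or `DNAStringSet` of
#'   equal-length promoters.
#' @param placement `"uniform"`, or `list(mean =, sd =)` for Gaussian
#'   placement of site starts (internal 1-based coordinates).
#' @param containment_fraction fraction of target promoters that receive a
#'   site (default 0.7).
#' @param seed RNG seed.
#' @return an `implant_spec` object.
#' @export
implant_spec <- function(sites, promoter_pool, placement = "uniform",
                         containment_fraction = 0.7, seed = 1L) {
  if (inherits(promoter_pool, "XStringSet"))
    promoter_pool <- setNames(as.character(promoter_pool), names(promoter_pool))
  if (any(grepl("[^ACGT]", sites)))
    stop("sites must be strings over {A,C,G,T}")
  L <- unique(nchar(promoter_pool))
  if (length(L) != 1L) stop("promoter pool must be equal-length")
  if (any(nchar(sites) > L)) stop("sites longer than the promoters")
  if (is.list(placement)) stopifnot(placement$sd > 0)
  stopifnot(containment_fraction > 0, containment_fraction <= 1)
  structure(list(sites = sites, promoter_pool = promoter_pool, L = L,
                 placement = placement,
                 containment_fraction = containment_fraction,
                 seed = as.integer(seed)),
            class = "implant_spec")
}

# draw one valid 1-based start for a site of length len in a promoter of
# length L; Gaussian placement resamples out-of-range draws
draw_start <- function(placement, L, len) {
  smax <- L - len + 1L
  if (identical(placement, "uniform")) return(sample.int(smax, 1L))
  repeat {
    s <- as.integer(round(rnorm(1, placement$mean, placement$sd)))
    if (s >= 1L && s <= smax) return(s)
  }
}

splice_site <- function(seq, site, start) {
  len <- nchar(site)
  paste0(substr(seq, 1, start - 1), site,
         substr(seq, start + len, nchar(seq)))
}

#' Implant binding sites into a promoter pool
#'
#' Draws `N = benchmark_size(|sites|, fraction)` target promoters and `N`
#' control promoters from the pool without replacement. Each site is
#' implanted into exactly one target promoter by substitution (preserving
#' sequence length), on a uniformly chosen strand, at a start drawn from the
#' placement law (resampled until inside the valid range). Control
#' promoters receive no implant. Fully reproducible from the seed.
#'
#' @param spec an [implant_spec()].
#' @return a `benchmark_pair`: list with `target` (named character vector),
#'   `control`, `truth` (data frame `seq_id`, `start`, `end`, `strand`,
#'   `site` with 1-based closed internal coordinates), and `spec`.
#' @export
implant_sites <- function(spec) {
  withr::with_seed(spec$seed, {
    n_sites <- length(spec$sites)
    N <- benchmark_size(n_sites, spec$containment_fraction)
    pool <- spec$promoter_pool
    if (length(pool) < 2L * N)
      stop(sprintf("promoter pool too small: need %d, have %d", 2L * N,
                   length(pool)))
    picked <- sample(names(pool), 2L * N)
    target <- pool[picked[seq_len(N)]]
    control <- pool[picked[N + seq_len(N)]]
    carriers <- sample(names(target), n_sites)
    truth <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      site <- spec$sites[i]
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") site else reverse_complement(site)
      s <- draw_start(spec$placement, spec$L, nchar(site))
      id <- carriers[i]
      target[[id]] <- splice_site(target[[id]], planted, s)
      truth[[i]] <- data.frame(seq_id = id, start = s,
                               end = s + nchar(site) - 1L, strand = strand,
                               site = site, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    structure(list(target = target, control = control, truth = truth,
                   spec = spec),
              class = "benchmark_pair")
  })
}

#' Implant a decoy motif into target and control sets
#'
#' Plants one randomly chosen decoy site, uniformly placed on a uniformly
#' chosen strand, into every target and every control promoter. Decoy
#' placements overlapping an annotated true site are resampled (bounded
#' retries). True-site annotations are unchanged.
#'
#' @param pair a [implant_sites()] benchmark pair.
#' @param decoy_sites character vector of decoy site strings.
#' @param seed RNG seed.
#' @param max_retries placement retries per promoter before giving up.
#' @return the modified `benchmark_pair`, with a `decoy` annotation table.
#' @export
add_decoy <- function(pair, decoy_sites, seed = 1L, max_retries = 1000L) {
  if (any(grepl("[^ACGT]", decoy_sites))) stop("decoy sites must be over {A,C,G,T}")
  L <- nchar(pair$target[[1]])
  if (any(nchar(decoy_sites) > L)) stop("decoy sites longer than the promoters")
  withr::with_seed(seed, {
    truth_by_id <- split(pair$truth, pair$truth$seq_id)
    place_one <- function(id, seq) {
      site <- sample(decoy_sites, 1L)
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") site else reverse_complement(site)
      len <- nchar(site)
      smax <- L - len + 1L
      tr <- truth_by_id[[id]]
      for (try in seq_len(max_retries)) {
        s <- sample.int(smax, 1L)
        if (is.null(tr) ||
            all(s + len - 1L < tr$start | s > tr$end)) {
          return(list(seq = splice_site(seq, planted, s),
                      row = data.frame(seq_id = id, start = s,
                                       end = s + len - 1L, strand = strand,
                                       site = site, stringsAsFactors = FALSE)))
        }
      }
      stop("no non-overlapping decoy placement found for ", id)
    }
    decoy_rows <- list()
    for (set in c("target", "control")) {
      ss <- pair[[set]]
      for (id in names(ss)) {
        res <- place_one(id, ss[[id]])
        ss[[id]] <- res$seq
        decoy_rows[[length(decoy_rows) + 1L]] <- res$row
      }
      pair[[set]] <- ss
    }
    pair$decoy <- do.call(rbind, decoy_rows)
    pair
  })
}

#' Sample sequences from a known ZOOPS model
#'
#' Generator for parameter-recovery experiments: each sequence carries a
#' site with probability `p_occ`; the start is drawn from the discretized
#' positional prior, the strand from `strand_weight`, the site letters from
#' the PWM (reverse-complemented on the minus strand) and the flanks from
#' the flanking model.
#'
#' @param fg a [zoops_params()].
#' @param n number of sequences.
#' @param L sequence length (bp).
#' @param seed RNG seed.
#' @return list with `seqs` (named character vector) and `truth` (data
#'   frame of implanted-site annotations: `seq_id`, `start`, `end`,
#'   `strand`).
#' @export
sample_from_model <- function(fg, n, L, seed = 1L) {
  w <- ncol(fg$pwm)
  stopifnot(w <= L)
  withr::with_seed(seed, {
    pmf <- position_pmf(fg$position, L, w)
    pwm <- unclass(fg$pwm)
    seqs <- character(n)
    truth <- list()
    for (i in seq_len(n)) {
      letters_i <- sample(DNA_LETTERS, L, replace = TRUE, prob = fg$flanking)
      if (runif(1) < fg$p_occ) {
        u <- sample.int(length(pmf), 1L, prob = pmf)
        strand <- if (runif(1) < fg$strand_weight) "+" else "-"
        site <- vapply(seq_len(w), function(j)
          sample(DNA_LETTERS, 1L, prob = pwm[, j]), character(1))
        site <- paste(site, collapse = "")
        if (strand == "-") site <- reverse_complement(site)
        letters_i[u:(u + w - 1L)] <- strsplit(site, "")[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = paste0("sim_", i), start = u, end = u + w - 1L,
          strand = strand, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(letters_i, collapse = "")
    }
    names(seqs) <- paste0("sim_", seq_len(n))
    truth <- if (length(truth)) do.call(rbind, truth)
    else data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), strand = character(0))
    list(seqs = seqs, truth = truth)
  })
}
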