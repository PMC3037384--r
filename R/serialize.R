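# Model serialization to/from JSON. Numbers are written with 17 significant
# digits, so a write/read round trip is bit-stable.

#' Write a trained model to JSON
#'
#' Stores the alphabet, PWM columns, flanking probabilities, positional
#' prior (both internal and TSS-relative location), occurrence and strand
#' probabilities, background conditionals, class priors, and training
#' metadata.
#'
#' @param model a `trained_posmotif` (or a list with at least `fg`, `bg`,
#'   `priors`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  fg <- model$fg
  tss_offset <- model$tss_offset %||% NA_integer_
  doc <- list(
    alphabet = DNA_LETTERS,
    pwm = lapply(seq_len(ncol(fg$pwm)), function(j) unname(unclass(fg$pwm)[, j])),
    flanking = unname(fg$flanking),
    p_occ = fg$p_occ,
    strand_weight = fg$strand_weight,
    position = list(gamma = fg$position$gamma,
                    xi = fg$position$xi,
                    xi_tss = if (!is.na(tss_offset))
                      fg$position$xi - 1 + tss_offset else NULL,
                    omega = fg$position$omega,
                    alpha_shape = fg$position$alpha_shape),
    background = list(order = model$bg$order,
                      blocks = lapply(model$bg$blocks, function(b)
                        lapply(seq_len(ncol(b)), function(cc) unname(b[, cc])))),
    class_priors = list(pi_fg = model$priors$pi_fg,
                        pi_bg = model$priors$pi_bg),
    metadata = list(objective = model$objective %||% NULL,
                    restart_objectives = model$restart_objectives %||% NULL,
                    tss_offset = if (!is.na(tss_offset)) tss_offset else NULL,
                    L = model$L %||% NULL))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path a [write_model()] JSON file.
#' @return a `trained_posmotif` object (metadata fields may be `NULL` if
#'   absent from the file).
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  # pwm is stored as a list of length-4 columns; simplifyVector yields a
  # w x 4 matrix (rows = motif positions)
  pwm_rows <- if (is.matrix(doc$pwm)) doc$pwm else do.call(rbind, doc$pwm)
  pwm <- new_pwm(t(pwm_rows))
  pos <- position_prior(gamma = doc$position$gamma, xi = doc$position$xi,
                        omega = doc$position$omega,
                        alpha_shape = doc$position$alpha_shape)
  fg <- zoops_params(p_occ = doc$p_occ, pwm = pwm, flanking = doc$flanking,
                     position = pos, strand_weight = doc$strand_weight)
  blocks <- lapply(doc$background$blocks, function(b) {
    if (is.matrix(b)) t(b) else matrix(unlist(b), nrow = 4)
  })
  bg <- background_model(order = doc$background$order, blocks = blocks)
  structure(list(fg = fg, bg = bg,
                 priors = class_priors(doc$class_priors$pi_fg),
                 objective = doc$metadata$objective,
                 restart_objectives = doc$metadata$restart_objectives,
                 tss_offset = doc$metadata$tss_offset,
                 L = doc$metadata$L),
            class = "trained_posmotif")
}

#' Write the learned PWM and positional prior as a text report
#'
#' Tab-separated probability matrix (one motif column per row) followed by
#' the positional-prior parameters reported TSS-relative.
#'
#' @param model a `trained_posmotif`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(model, path) {
  fg <- model$fg
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# consensus: %s", pwm_consensus(fg$pwm)), con)
  writeLines(paste(c("pos", DNA_LETTERS), collapse = "\t"), con)
  m <- unclass(fg$pwm)
  for (j in seq_len(ncol(m)))
    writeLines(paste(c(j, format(m[, j], digits = 6)), collapse = "\t"), con)
  off <- model$tss_offset %||% NA_integer_
  writeLines(sprintf("# p_occ\t%.6f", fg$p_occ), con)
  writeLines(sprintf("# position gamma\t%.6f", fg$position$gamma), con)
  writeLines(sprintf("# position xi (TSS-relative)\t%.2f",
                     fg$position$xi - 1 + (if (is.na(off)) 0 else off)), con)
  writeLines(sprintf("# position omega\t%.2f", fg$position$omega), con)
  writeLines(sprintf("# position shape\t%.3f", fg$position$alpha_shape), con)
  invisible(path)
}

#' Read a reference PWM from a tab-separated matrix file
#'
#' Accepts probability or count matrices with 4 columns (A,C,G,T), one motif
#' position per row, with or without a header / position column; count
#' matrices are normalized.
#'
#' @param path TSV path.
#' @return a [new_pwm()].
#' @export
read_pwm_tsv <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("[ACGTacgt]", strsplit(first, "\t")[[1]][2] %||% "") &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  tab <- read.table(path, sep = "\t", header = header,
                    stringsAsFactors = FALSE, comment.char = "#")
  num <- tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) == 5) num <- num[, -1, drop = FALSE]   # leading position col
  if (ncol(num) != 4) stop("expected 4 letter columns in ", path)
  m <- t(as.matrix(num))
  m <- sweep(m, 2, colSums(m), "/")
  new_pwm(m)
}
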