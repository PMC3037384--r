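#' Read a FASTA file of DNA sequences
#'
#' Reads promoter sequences with [Biostrings::readDNAStringSet()]. Residues
#' are uppercased; multi-line records are concatenated. In strict mode
#' (the default, required for training because the likelihood model has no
#' emission for ambiguous letters) any residue outside `{A,C,G,T}` raises an
#' error naming the record and offset. In lenient mode offending sequences
#' are dropped with a warning.
#'
#' gzip-compressed files are handled transparently by Biostrings.
#'
#' @param path path to a FASTA file.
#' @param strict reject non-ACGT residues (`TRUE`) or drop the offending
#'   sequences with a warning (`FALSE`).
#' @return a named [Biostrings::DNAStringSet] (names are record ids).
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0L) stop("no FASTA records in ", path)
  # keep only the id part of the header, as downstream ids must be words
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(names(x)))) stop("malformed FASTA header: empty record id")
  chars <- as.character(x)
  bad <- gregexpr("[^ACGTacgt]", chars)
  offending <- vapply(bad, function(b) b[1] != -1L, logical(1))
  if (any(offending)) {
    first <- which(offending)[1]
    if (strict) {
      stop(sprintf("non-ACGT residue in record '%s' at offset %d",
                   names(x)[first], bad[[first]][1]))
    }
    warning(sprintf("dropping %d sequence(s) with non-ACGT residues (first: '%s')",
                    sum(offending), names(x)[first]))
    x <- x[!offending]
    if (length(x) == 0L) stop("all sequences dropped in lenient mode")
  }
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta")
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param s a character vector of strings over `{A,C,G,T}` (or a
#'   `DNAStringSet`).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  if (inherits(s, "XStringSet")) s <- as.character(s)
  if (any(grepl("[^ACGT]", s))) stop("reverse_complement: letters outside {A,C,G,T}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Build a labeled, equal-length promoter dataset
#'
#' Bundles a foreground (target) and a background (control) sequence set into
#' one labeled dataset for discriminative training. All sequences must share
#' one length `L`: the positional prior is defined over absolute start
#' positions, which is only meaningful when sequences are aligned to a common
#' anchor (typically the TSS). The length invariant is checked eagerly.
#'
#' Coordinates are 0-based half-open BED-style externally and 1-based
#' internally; `tss_offset` is the TSS-relative coordinate of the first
#' residue (e.g. -500 for promoters spanning \[-500, -1\]).
#'
#' @param fg,bg named `DNAStringSet`s or named character vectors.
#' @param tss_offset integer, TSS-relative coordinate of the first residue.
#' @return an object of class `labeled_dataset` with elements `seqs`
#'   (DNAStringSet), `labels` (factor with levels foreground/background),
#'   `tss_offset`, `enc` (integer matrix of base codes) and `L`.
#' @export
build_dataset <- function(fg, bg, tss_offset = -500L) {
  if (is.character(fg)) fg <- Biostrings::DNAStringSet(fg)
  if (is.character(bg)) bg <- Biostrings::DNAStringSet(bg)
  if (length(fg) < 1L || length(bg) < 1L)
    stop("both classes need at least one sequence")
  if (is.null(names(fg))) names(fg) <- paste0("fg_", seq_along(fg))
  if (is.null(names(bg))) names(bg) <- paste0("bg_", seq_along(bg))
  lens <- c(Biostrings::width(fg), Biostrings::width(bg))
  if (length(unique(lens)) != 1L) {
    ids <- c(names(fg), names(bg))
    off <- ids[lens != stats::median(lens)]
    stop("sequences differ in length; offending ids: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  seqs <- c(fg, bg)
  labels <- factor(rep(c("foreground", "background"), c(length(fg), length(bg))),
                   levels = c("foreground", "background"))
  structure(
    list(seqs = seqs, labels = labels, tss_offset = as.integer(tss_offset),
         enc = encode_seqs(seqs), L = unique(lens)),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d foreground + %d background sequences, L = %d bp (TSS offset %d)\n",
              sum(x$labels == "foreground"), sum(x$labels == "background"),
              x$L, x$tss_offset))
  invisible(x)
}

# class-specific views used throughout learning/prediction
fg_enc <- function(data) data$enc[data$labels == "foreground", , drop = FALSE]
bg_enc <- function(data) data$enc[data$labels == "background", , drop = FALSE]
fg_seqs <- function(data) data$seqs[data$labels == "foreground"]
bg_seqs <- function(data) data$seqs[data$labels == "background"]
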