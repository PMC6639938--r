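#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over plain character vectors. Accepts the
#' bases `A`, `C`, `G`, `T` plus `N` (which maps to `N`); anything else is an
#' error. Sequences must be non-empty and uppercase.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp("GGCCGGGCGC")
#' @export
revcomp <- function(seq) {
  check_dna(seq, allow_n = TRUE)
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(seq))
}

#' Canonical form of a k-mer
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement. Counting canonical k-mers makes all
#' k-mer bookkeeping strand-independent.
#'
#' @param kmer Character vector of ACGT k-mers.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer("AAAA") # "AAAA": revcomp "TTTT" sorts later
#' @export
canonical_kmer <- function(kmer) {
  check_dna(kmer, allow_n = FALSE)
  rc <- chartr("ACGT", "TGCA", stringi::stri_reverse(kmer))
  ifelse(kmer <= rc, kmer, rc)
}

#' GC fraction of DNA sequences
#'
#' @param seq Character vector of DNA sequences (ACGT, `N` allowed; `N` counts
#'   toward the length but not toward GC).
#' @return Numeric vector of G+C fractions in `[0, 1]`.
#' @examples
#' gc_fraction(c("GGCC", "AATT"))
#' @export
gc_fraction <- function(seq) {
  check_dna(seq, allow_n = TRUE)
  stringr::str_count(seq, "[GC]") / stringr::str_length(seq)
}

check_dna <- function(seq, allow_n = FALSE, arg = deparse(substitute(seq))) {
  if (!is.character(seq)) {
    abort(sprintf("`%s` must be a character vector", arg))
  }
  if (length(seq) == 0L) return(invisible(seq))
  if (any(!nzchar(seq))) {
    abort(sprintf("`%s` contains an empty string", arg))
  }
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- stringr::str_detect(seq, pat)
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains non-ACGT%s characters (first offender: %s)",
      arg, if (allow_n) "/N" else "", seq[which(bad)[1L]]
    ))
  }
  invisible(seq)
}

#' Coordinate system converters
#'
#' All coordinates inside this package are 1-based inclusive (the R and
#' Bioconductor convention). These converters map to and from 0-based
#' half-open start coordinates for interoperability with BED-style tools;
#' they are exact inverses of each other.
#'
#' @param pos Integer vector of positions.
#' @return Integer vector of converted positions.
#' @examples
#' to_zero_based(1L)  # 0
#' to_one_based(to_zero_based(42L))  # 42
#' @export
to_zero_based <- function(pos) {
  stopifnot(is.numeric(pos), all(pos >= 1))
  as.integer(pos) - 1L
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(pos) {
  stopifnot(is.numeric(pos), all(pos >= 0))
  as.integer(pos) + 1L
}

# substring over a single sequence, vectorised over start/end
subseq_chr <- function(seq, start, end) {
  substring(seq, start, end)
}

# random genome helper: base composition roughly human-like (41% GC)
random_dna <- function(n, gc = 0.41) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}
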