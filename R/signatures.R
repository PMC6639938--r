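#' Build the Alu signature sequence set
#'
#' Alu elements carry a highly conserved 10 bp sequence at their 5' end
#' (consensus `GGCCGGGCGC`). The signature set is this consensus plus every
#' sequence at Hamming distance exactly 1 from it, giving `3L + 1` members for
#' a consensus of length `L` (31 for the default 10-mer). Scanning reads or a
#' genome for membership in this set detects intact Alu 5' ends while
#' tolerating one substitution.
#'
#' @param consensus Uppercase ACGT string (default the Alu 5' consensus).
#' @return An object of class `signature_set` with fields `consensus` and
#'   `members` (sorted character vector).
#' @examples
#' sigs <- build_signature_set()
#' length(sigs$members) # 31
#' @export
build_signature_set <- function(consensus = "GGCCGGGCGC") {
  if (length(consensus) != 1L) abort("`consensus` must be a single string")
  check_dna(consensus, allow_n = FALSE, arg = "consensus")
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  variants <- unlist(lapply(seq_len(L), function(i) {
    vapply(bases, function(b) {
      s <- consensus
      substr(s, i, i) <- b
      s
    }, character(1))
  }), use.names = FALSE)
  members <- sort(unique(c(consensus, variants)))
  structure(list(consensus = consensus, members = members),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> consensus %s, %d members (Hamming <= 1)\n",
              x$consensus, length(x$members)))
  invisible(x)
}

as_signature_set <- function(x) {
  if (inherits(x, "signature_set")) return(x)
  if (is.character(x) && length(x) == 1L) return(build_signature_set(x))
  abort("expected a `signature_set` or a single consensus string")
}

# Match a fixed-width pattern set against one subject string.
# Returns tibble(pos, member_index). Windows containing N never match.
pdict_hits <- function(subject, members) {
  subj <- Biostrings::DNAString(subject)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(members))
  m <- Biostrings::matchPDict(pd, subj)
  starts <- Biostrings::startIndex(m)
  lens <- lengths(starts)
  tibble(
    pos = as.integer(unlist(starts, use.names = FALSE)),
    member_index = rep.int(seq_along(members), lens)
  )
}

#' Scan a sequence for Alu signature occurrences
#'
#' Reports every position where a member of the signature set occurs, read
#' 5' to 3' on the reported strand. Minus-strand hits are reported at the
#' position where the reverse complement of the signature starts on the given
#' sequence (its leftmost base in forward coordinates). Matching is O(1) per
#' window via precomputed-set membership; windows containing `N` never match.
#'
#' @param seq A single DNA string (may contain `N`).
#' @param sigs A `signature_set` (or consensus string).
#' @param both_strands Scan the reverse complement too? Default `TRUE`.
#' @return Tibble with columns `pos` (1-based), `strand` (`"+"`/`"-"`) and
#'   `signature` (the matched member, on the hit strand).
#' @examples
#' scan_signatures("TTGGCCGGGCGCTT")
#' @export
scan_signatures <- function(seq, sigs = build_signature_set(),
                            both_strands = TRUE) {
  sigs <- as_signature_set(sigs)
  stopifnot(is.character(seq), length(seq) == 1L)
  w <- nchar(sigs$consensus)
  empty <- tibble(pos = integer(), strand = character(),
                  signature = character())
  if (nchar(seq) < w) return(empty)

  fwd <- pdict_hits(seq, sigs$members)
  fwd$strand <- "+"
  fwd$signature <- sigs$members[fwd$member_index]
  out <- fwd
  if (both_strands) {
    rc_members <- revcomp(sigs$members)
    rev <- pdict_hits(seq, rc_members)
    rev$strand <- "-"
    rev$signature <- sigs$members[rev$member_index]
    out <- bind_rows(fwd, rev)
  }
  out |>
    select("pos", "strand", "signature") |>
    arrange(.data$pos, .data$strand)
}

#' Scan a whole genome for Alu signature occurrences
#'
#' [scan_signatures()] applied per sequence of a genome, with genomic
#' coordinates. This is the first stage of the REF+ discovery cascade.
#'
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @inheritParams scan_signatures
#' @return Tibble with columns `chrom`, `pos`, `strand`, `signature`.
#' @export
scan_reference <- function(genome, sigs = build_signature_set(),
                           both_strands = TRUE) {
  genome <- as_genome(genome)
  sigs <- as_signature_set(sigs)
  map_dfr(names(genome), function(chrom) {
    hits <- scan_signatures(genome[[chrom]], sigs, both_strands = both_strands)
    if (nrow(hits)) hits$chrom <- chrom
    hits
  }) |>
    (\(d) if (nrow(d)) select(d, "chrom", "pos", "strand", "signature")
     else tibble(chrom = character(), pos = integer(),
                 strand = character(), signature = character()))()
}
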