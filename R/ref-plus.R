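# REF+ discovery: Alu elements present in the reference genome that may be
# absent from other individuals. A candidate must carry an intact 5'
# signature, a target site duplication (TSD) of at least 5 bp on both ends
# with the downstream copy 270-350 bp from the signature start, local
# alignment homology above 100 bits to an Alu consensus, and (optionally)
# absence of its 5'-junction 32-mer from an outgroup genome.

#' Packaged Alu consensus sequence
#'
#' Returns the packaged AluY-like consensus used as the default homology
#' reference and simulation insert backbone. The sequence is synthetic: an
#' approximately 290 bp AluY-style consensus (canonical 5' signature
#' `GGCCGGGCGC`, two-arm body, A-rich linker) constructed for this package,
#' not a curated repeat-library record. Users can supply their own Alu
#' library wherever this default is accepted.
#'
#' @return Named character vector with one record, `AluY_synthetic`.
#' @export
alu_consensus <- function() {
  read_fasta(system.file("extdata", "alu_consensus_synthetic.fa",
                         package = "aluscan", mustWork = TRUE))
}

#' Find a target site duplication for a signature hit
#'
#' Takes the 5-mer immediately 5' of the signature (on the element's strand)
#' and searches for its exact copy starting at each distance `d` in
#' `tsd_window` downstream of the signature start; the nearest match wins.
#' On success the TSD match is extended in both directions to its maximal
#' exact length. Coordinates in and out are forward-strand 1-based; for
#' minus-strand hits `pos` is the leftmost base of the reverse-complemented
#' signature window, as reported by [scan_reference()].
#'
#' @param genome Reference genome.
#' @param chrom,pos,strand A signature hit.
#' @param tsd_window Inclusive distance window, default `c(270, 350)`.
#' @param tsd_min Minimum reported TSD length (seed is 5).
#' @return One-row tibble (`chrom`, `start`, `end`, `strand`, `tsd`,
#'   `tsd_len`, `tsd_dist`) where `start`/`end` span signature start to the
#'   last base of the downstream TSD copy, or `NULL` when no TSD is found.
#' @export
find_tsd <- function(genome, chrom, pos, strand = "+",
                     tsd_window = c(270L, 350L), tsd_min = 5L) {
  genome <- as_genome(genome)
  seq <- genome[[chrom]]
  L <- nchar(seq)
  sig_w <- 10L
  seed_w <- 5L

  # work on the element's strand
  es <- if (strand == "+") seq else revcomp(seq)
  s <- if (strand == "+") pos else L - pos - sig_w + 2L

  if (s - seed_w < 1L) return(NULL)
  seed <- substr(es, s - seed_w, s - 1L)
  if (stringr::str_detect(seed, "[^ACGT]")) return(NULL)

  found_d <- NA_integer_
  for (d in seq.int(tsd_window[1L], tsd_window[2L])) {
    a <- s + d
    b <- a + seed_w - 1L
    if (b > L) break
    if (substr(es, a, b) == seed) {
      found_d <- d
      break
    }
  }
  if (is.na(found_d)) return(NULL)

  a <- s + found_d
  # maximal exact extension of the duplication, left then right
  l <- 0L
  while (s - seed_w - l - 1L >= 1L &&
         substr(es, s - seed_w - l - 1L, s - seed_w - l - 1L) ==
         substr(es, a - l - 1L, a - l - 1L) &&
         grepl("[ACGT]", substr(es, a - l - 1L, a - l - 1L))) {
    l <- l + 1L
  }
  r <- 0L
  while (a + seed_w + r <= L &&
         substr(es, s - 1L + r + 1L, s - 1L + r + 1L) ==
         substr(es, a + seed_w + r, a + seed_w + r) &&
         grepl("[ACGT]", substr(es, a + seed_w + r, a + seed_w + r))) {
    r <- r + 1L
  }
  tsd <- substr(es, s - seed_w - l, s - 1L + r)
  tsd2_end <- a + seed_w - 1L + r
  if (nchar(tsd) < tsd_min) return(NULL)

  span <- c(s, tsd2_end)
  if (strand == "-") span <- c(L - span[2L] + 1L, L - span[1L] + 1L)
  tibble(chrom = chrom, start = span[1L], end = span[2L], strand = strand,
         tsd = tsd, tsd_len = nchar(tsd), tsd_dist = found_d)
}

#' Local-alignment homology score in bits
#'
#' Smith-Waterman local alignment (match +1, mismatch -2, gap open -5, gap
#' extend -2; a gap of length `g` costs `gap_open + g * gap_ext`) of each
#' sequence against every record of an Alu library; the best raw score `S`
#' per sequence is converted to bits with the ungapped Karlin-Altschul
#' parameters for the +1/-2 scheme: `bits = (lambda * S - ln K) / ln 2` with
#' `lambda = 1.28`, `K = 0.46`.
#'
#' @param seqs Character vector of candidate sequences (element strand).
#' @param library Alu consensus library (named character vector, FASTA path
#'   or `DNAStringSet`); default the packaged synthetic consensus.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring scheme.
#' @param lambda,k_param Karlin-Altschul parameters for the bit conversion.
#' @return Tibble with columns `score` (raw) and `bits`.
#' @export
score_homology <- function(seqs, library = alu_consensus(),
                           match = 1, mismatch = -2,
                           gap_open = 5, gap_ext = 2,
                           lambda = 1.28, k_param = 0.46) {
  if (length(library) == 0L) abort("empty Alu consensus library")
  library <- as_genome(library)
  if (any(!nzchar(library))) abort("empty Alu consensus library")
  stopifnot(length(seqs) >= 1L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  best <- rep(-Inf, length(seqs))
  for (rec in library) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(seqs),
      subject = Biostrings::DNAString(rec),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE
    )
    best <- pmax(best, sc)
  }
  tibble(score = best, bits = (lambda * best - log(k_param)) / log(2))
}

#' Is a junction 32-mer absent from an outgroup genome?
#'
#' The coarse outgroup (e.g. chimpanzee) comparison: the allele-with-element
#' junction 32-mer (25 bp flank + first 7 signature bases) is looked up in
#' the outgroup genome on both strands; the candidate passes iff it is
#' absent. With no outgroup the stage is skipped and `NA` returned.
#'
#' @param junction32 Character vector of 32-mers.
#' @param outgroup Outgroup genome, or `NULL` to skip.
#' @return Logical vector (`NA` when skipped).
#' @export
outgroup_absent <- function(junction32, outgroup = NULL) {
  if (is.null(outgroup)) {
    warn("no outgroup genome supplied; outgroup stage skipped (flag NA)")
    return(rep(NA, length(junction32)))
  }
  outgroup <- as_genome(outgroup)
  check_dna(junction32)
  pats <- c(junction32, revcomp(junction32))
  counts <- rep(0L, length(pats))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
  for (chromseq in outgroup) {
    counts <- counts +
      Biostrings::countPDict(pd, Biostrings::DNAString(chromseq))
  }
  n <- length(junction32)
  (counts[seq_len(n)] + counts[n + seq_len(n)]) == 0L
}

#' Discover potentially polymorphic REF+ Alu elements in a reference
#'
#' Runs the four-stage REF+ cascade: signature scan of the reference, TSD
#' search, homology against an Alu library, and (optionally) absence of the
#' insertion junction from an outgroup genome. Each stage only removes
#' candidates, so the per-stage counts in `cascade()` are monotone.
#'
#' @param genome Reference genome.
#' @param library Alu consensus library for homology scoring.
#' @param outgroup Optional outgroup genome; when `NULL` the outgroup flag is
#'   `NA` and candidates are retained.
#' @param sigs Signature set.
#' @param tsd_window,tsd_min TSD search parameters (see [find_tsd()]).
#' @param min_bits Homology retention threshold (default 100 bits).
#' @param flank_len,junction_tail Junction 32-mer geometry (25 + 7).
#' @return Tibble (`chrom`, `start`, `end`, `strand`, `tsd`, `tsd_len`,
#'   `homology_bits`, `outgroup_absent`) with a `cascade` attribute.
#' @export
discover_ref_plus <- function(genome, library = alu_consensus(),
                              outgroup = NULL, sigs = build_signature_set(),
                              tsd_window = c(270L, 350L), tsd_min = 5L,
                              min_bits = 100, flank_len = 25L,
                              junction_tail = 7L) {
  genome <- as_genome(genome)
  hits <- scan_reference(genome, sigs)

  with_tsd <- map_dfr(seq_len(nrow(hits)), function(i) {
    find_tsd(genome, hits$chrom[i], hits$pos[i], hits$strand[i],
             tsd_window = tsd_window, tsd_min = tsd_min) %||% tibble()
  })

  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), tsd = character(),
                  tsd_len = integer(), homology_bits = double(),
                  outgroup_absent = logical())
  n_tsd <- nrow(with_tsd)
  out <- empty
  n_hom <- 0L

  if (n_tsd > 0L) {
    span_seq <- element_strand_seq(genome, with_tsd)
    with_tsd$homology_bits <- score_homology(span_seq, library)$bits
    hom <- with_tsd |> filter(.data$homology_bits > min_bits)
    n_hom <- nrow(hom)
    if (n_hom > 0L) {
      junction <- junction_kmer(genome, hom, flank_len, junction_tail)
      keepable <- !is.na(junction)
      hom <- hom[keepable, ]
      junction <- junction[keepable]
      og <- if (nrow(hom)) outgroup_absent(junction, outgroup) else logical()
      hom$outgroup_absent <- og
      out <- hom |>
        filter(is.na(.data$outgroup_absent) | .data$outgroup_absent) |>
        select("chrom", "start", "end", "strand", "tsd", "tsd_len",
               "homology_bits", "outgroup_absent") |>
        arrange(.data$chrom, .data$start)
    }
  }

  attr(out, "cascade") <- tibble(
    stage = c("signature hits in reference", "with 5 bp TSD in window",
              "homology above threshold", "REF+ candidates reported"),
    n = c(nrow(hits), n_tsd, n_hom, nrow(out))
  )
  attr(out, "ref") <- ref_tag(genome)
  class(out) <- c("alu_ref_plus", class(out))
  out
}

# element-strand sequence of each candidate span
element_strand_seq <- function(genome, cand) {
  s <- substring(genome[cand$chrom], cand$start, cand$end)
  minus <- cand$strand == "-"
  if (any(minus)) s[minus] <- revcomp(s[minus])
  unname(s)
}

# allele-with-element junction 32-mer: flank + first `tail` signature bases,
# on the element strand; NA when the flank runs off the chromosome
junction_kmer <- function(genome, cand, flank_len = 25L, tail = 7L) {
  L <- unname(nchar(genome)[cand$chrom])
  plus <- cand$strand == "+"
  from <- ifelse(plus, cand$start - flank_len, cand$end - tail + 1L)
  to <- ifelse(plus, cand$start + tail - 1L, cand$end + flank_len)
  ok <- from >= 1L & to <= L
  out <- rep(NA_character_, nrow(cand))
  if (any(ok)) {
    s <- substring(genome[cand$chrom[ok]], from[ok], to[ok])
    min_ok <- !plus[ok]
    if (any(min_ok)) s[min_ok] <- revcomp(s[min_ok])
    bad <- stringr::str_detect(s, "[^ACGT]")
    s[bad] <- NA_character_
    out[ok] <- s
  }
  out
}
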