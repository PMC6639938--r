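# REF- discovery: Alu insertions present in an individual's reads but absent
# from the reference. A read that spans the 5' insertion junction contains
# 25 bp of genomic flank followed by the 10 bp Alu signature; the 35-mer
# (flank + signature) is the discovery unit. Discovery is alignment-free:
# the flank is placed by exact 25-mer lookup, and an insertion is called when
# the reference continues differently after the flank.

# concatenate reads with '+' separators so one PDict pass covers them all;
# matches cannot span the separator because patterns are ACGT-only
concat_reads <- function(reads) {
  starts <- cumsum(c(1L, head(nchar(reads), -1L) + 1L))
  list(
    subject = paste(reads, collapse = "+"),
    starts = starts,
    widths = nchar(reads)
  )
}

empty_ref_minus <- function() {
  tibble(chrom = character(), pos = integer(), strand = character(),
         flank25 = character(), signature10 = character(),
         ref_next10 = character(), support = integer())
}

#' Scan reads for Alu signature junctions
#'
#' Finds every signature occurrence in the reads (both orientations) that has
#' at least `flank_len` bases 5' of it on the hit's strand, and returns the
#' flank+signature 35-mer for each, with exact aggregated counts. Junctions
#' containing non-ACGT characters are dropped. Reads shorter than
#' `flank_len + 10` cannot contribute and are skipped.
#'
#' @param reads Read input: character vector of sequences, FASTQ/BAM/SAM
#'   path(s), or a read-pair tibble from [simulate_reads()].
#' @param sigs A `signature_set`.
#' @param flank_len Flank length recorded 5' of the signature (default 25).
#' @return Tibble with columns `junction` (35-mer) and `support` (read count).
#' @export
scan_read_junctions <- function(reads, sigs = build_signature_set(),
                                flank_len = 25L) {
  reads <- as_reads(reads)
  sigs <- as_signature_set(sigs)
  w <- nchar(sigs$consensus)
  flank_len <- as.integer(flank_len)
  jlen <- flank_len + w

  reads <- reads[nchar(reads) >= jlen]
  if (length(reads) == 0L) {
    return(tibble(junction = character(), support = integer()))
  }
  cc <- concat_reads(reads)

  fwd <- pdict_hits(cc$subject, sigs$members)
  rev <- pdict_hits(cc$subject, revcomp(sigs$members))

  extract <- function(hits, minus) {
    if (nrow(hits) == 0L) return(character())
    ri <- findInterval(hits$pos, cc$starts)
    o <- hits$pos - cc$starts[ri] + 1L
    if (!minus) {
      # forward: flank lies 5' (left) of the signature window
      keep <- o > flank_len
      ri <- ri[keep]; o <- o[keep]
      substring(reads[ri], o - flank_len, o + w - 1L)
    } else {
      # minus strand: flank lies right of the rc window in read coordinates
      keep <- (o + w - 1L + flank_len) <= cc$widths[ri]
      ri <- ri[keep]; o <- o[keep]
      if (length(ri) == 0L) return(character())
      revcomp(substring(reads[ri], o, o + w - 1L + flank_len))
    }
  }

  junc <- c(extract(fwd, minus = FALSE), extract(rev, minus = TRUE))
  junc <- junc[!stringr::str_detect(junc, "[^ACGT]")]
  if (length(junc) == 0L) {
    return(tibble(junction = character(), support = integer()))
  }
  tibble(junction = junc) |>
    count(.data$junction, name = "support") |>
    arrange(dplyr::desc(.data$support), .data$junction)
}

#' Call REF- insertion candidates from counted junctions
#'
#' Keeps junction 35-mers within the support window, requires the 25 bp flank
#' to have a unique location in the reference, and reports a candidate iff
#' the 10 bp that follow the flank in the reference differ from the observed
#' signature 10-mer (if they match, the signature is part of the reference
#' and no insertion is implied). The breakpoint `pos` is the 1-based
#' reference position before which the element inserts.
#'
#' @param junctions Tibble from [scan_read_junctions()].
#' @param index `kmer_index` built from `genome` with `k = flank_len`.
#' @param genome The reference genome (same build as `index`).
#' @param min_support,max_support Support window for a junction to be
#'   considered (defaults 3 and 100; suppress sequencing-error 35-mers and
#'   repeat-derived artifacts respectively at 20-40x coverage).
#' @param flank_len Flank length (default 25; must match the index `k`).
#' @return Tibble of candidates (`chrom`, `pos`, `strand`, `flank25`,
#'   `signature10`, `ref_next10`, `support`), sorted by coordinate, with a
#'   `cascade` attribute of per-stage counts mirroring the filtering cascade.
#' @export
ref_minus_candidates <- function(junctions, index, genome,
                                 min_support = 3L, max_support = 100L,
                                 flank_len = 25L) {
  genome <- as_genome(genome)
  flank_len <- as.integer(flank_len)
  stopifnot(index$k == flank_len)

  insupp <- junctions |>
    filter(.data$support >= min_support, .data$support <= max_support)

  n_located <- 0L
  n_unique <- 0L
  out <- empty_ref_minus()

  if (nrow(insupp) > 0L) {
    w <- nchar(insupp$junction[1L]) - flank_len
    cand <- insupp |>
      mutate(
        flank25 = substr(.data$junction, 1L, flank_len),
        signature10 = substr(.data$junction, flank_len + 1L, flank_len + w)
      )
    loc <- unique_location(index, cand$flank25)
    cand$chrom <- loc$chrom
    cand$pos_flank <- loc$pos
    cand$strand <- loc$strand
    cand$n_total <- loc$n_total
    n_located <- sum(cand$n_total >= 1L)
    uniq <- cand |> filter(.data$n_total == 1L)
    n_unique <- nrow(uniq)

    if (nrow(uniq) > 0L) {
      chrom_len <- unname(nchar(genome)[uniq$chrom])
      plus <- uniq$strand == "+"
      nx_start <- ifelse(plus, uniq$pos_flank + flank_len, uniq$pos_flank - w)
      nx_end <- nx_start + w - 1L
      uniq <- uniq[nx_start >= 1L & nx_end <= chrom_len, ]
    }
    if (nrow(uniq) > 0L) {
      plus <- uniq$strand == "+"
      nx_start <- ifelse(plus, uniq$pos_flank + flank_len, uniq$pos_flank - w)
      nx <- substring(genome[uniq$chrom], nx_start, nx_start + w - 1L)
      nx[!plus] <- revcomp(nx[!plus])
      uniq$ref_next10 <- nx
      uniq$pos <- as.integer(
        ifelse(plus, uniq$pos_flank + flank_len, uniq$pos_flank)
      )
      uniq <- uniq |>
        filter(!stringr::str_detect(.data$ref_next10, "[^ACGT]"),
               .data$ref_next10 != .data$signature10)
      if (nrow(uniq) > 0L) {
        out <- uniq |>
          select("chrom", "pos", "strand", "flank25", "signature10",
                 "ref_next10", "support") |>
          arrange(.data$chrom, .data$pos)
      }
    }
  }

  attr(out, "cascade") <- tibble(
    stage = c("junctions observed", "within support window",
              "flank located in reference", "flank unique in reference",
              "REF- candidates reported"),
    n = c(nrow(junctions), nrow(insupp), n_located, n_unique, nrow(out))
  )
  attr(out, "ref") <- index$ref
  class(out) <- c("alu_ref_minus", class(out))
  out
}

#' Discover REF- Alu insertions from raw reads
#'
#' End-to-end REF- discovery: scan reads for signature junctions, then call
#' candidates against the reference. Alignment-free throughout.
#'
#' @inheritParams scan_read_junctions
#' @inheritParams ref_minus_candidates
#' @param index Optional prebuilt `kmer_index`; built from `genome` when
#'   `NULL`.
#' @return Candidate tibble as from [ref_minus_candidates()].
#' @export
discover_ref_minus <- function(reads, genome, sigs = build_signature_set(),
                               index = NULL, min_support = 3L,
                               max_support = 100L, flank_len = 25L) {
  genome <- as_genome(genome)
  if (is.null(index)) index <- build_kmer_index(genome, k = flank_len)
  junctions <- scan_read_junctions(reads, sigs, flank_len = flank_len)
  ref_minus_candidates(junctions, index, genome,
                       min_support = min_support, max_support = max_support,
                       flank_len = flank_len)
}

#' Per-stage counts of a discovery cascade
#'
#' Discovery and pair-filtering functions attach a per-stage count table
#' (how many items survived each filter) mirroring the classic cascade
#' summary. This accessor retrieves it.
#'
#' @param x A result object carrying a `cascade` attribute.
#' @return Tibble with columns `stage` and `n`.
#' @export
cascade <- function(x) {
  attr(x, "cascade") %||% tibble(stage = character(), n = integer())
}
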