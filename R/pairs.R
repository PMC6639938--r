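# Bipartite 32-mer pairs: each polymorphic element is represented by two
# 32-mers sharing the 25 bp genomic flank 5' of the breakpoint and differing
# in the last 7 bases. Allele A always carries the reference-genome state,
# allele B the alternative: for a REF- element B ends with the first 7 Alu
# signature bases (insertion present in the individual), for a REF+ element
# A does (element present in the reference) and B ends with the 7 bases that
# follow the downstream TSD copy (element absent).

#' Build allele-specific 32-mer pairs from discovery candidates
#'
#' Constructs one `kmerA`/`kmerB` pair per candidate. Candidates whose pair
#' would be degenerate (`kmerA == kmerB`), would run off the chromosome, or
#' would contain non-ACGT characters are dropped; the dropped ids are
#' recorded in the `dropped` attribute.
#'
#' @param candidates A REF- candidate tibble ([discover_ref_minus()]) or a
#'   REF+ candidate tibble ([discover_ref_plus()]).
#' @param genome Reference genome (required for REF+ candidates).
#' @param flank_len,tail_len The 32-mer split (default 25 + 7).
#' @return Tibble with columns `element_id`, `class`, `chrom`, `pos`,
#'   `strand`, `kmerA`, `kmerB`; class `alu_pairs`.
#' @export
build_pairs <- function(candidates, genome = NULL, flank_len = 25L,
                        tail_len = 7L) {
  if (nrow(candidates) == 0L) {
    return(new_alu_pairs(empty_pairs(), attr(candidates, "ref") %||% "unnamed",
                         dropped = character()))
  }
  if ("flank25" %in% names(candidates)) {
    pairs <- pairs_from_ref_minus(candidates, tail_len)
  } else if (all(c("start", "end", "tsd") %in% names(candidates))) {
    if (is.null(genome)) abort("`genome` is required to build REF+ pairs")
    pairs <- pairs_from_ref_plus(candidates, as_genome(genome),
                                 flank_len, tail_len)
  } else {
    abort("unrecognised candidate table")
  }
  klen <- flank_len + tail_len
  ok <- !is.na(pairs$kmerA) & !is.na(pairs$kmerB) &
    nchar(pairs$kmerA) == klen & nchar(pairs$kmerB) == klen &
    !stringr::str_detect(pairs$kmerA, "[^ACGT]") &
    !stringr::str_detect(pairs$kmerB, "[^ACGT]") &
    pairs$kmerA != pairs$kmerB
  dropped <- pairs$element_id[!ok]
  out <- pairs[ok, ] |> arrange(.data$chrom, .data$pos)
  new_alu_pairs(out, attr(candidates, "ref") %||% "unnamed", dropped)
}

empty_pairs <- function() {
  tibble(element_id = character(), class = character(), chrom = character(),
         pos = integer(), strand = character(), kmerA = character(),
         kmerB = character())
}

new_alu_pairs <- function(df, ref, dropped = character(),
                          rejections = NULL) {
  attr(df, "ref") <- ref
  attr(df, "dropped") <- dropped
  if (!is.null(rejections)) attr(df, "rejections") <- rejections
  class(df) <- unique(c("alu_pairs", class(df)))
  df
}

pairs_from_ref_minus <- function(cand, tail_len) {
  tibble(
    element_id = sprintf("RM_%s_%d", cand$chrom, cand$pos),
    class = "REF_MINUS",
    chrom = cand$chrom,
    pos = as.integer(cand$pos),
    strand = cand$strand,
    kmerA = paste0(cand$flank25, substr(cand$ref_next10, 1L, tail_len)),
    kmerB = paste0(cand$flank25, substr(cand$signature10, 1L, tail_len))
  )
}

pairs_from_ref_plus <- function(cand, genome, flank_len, tail_len) {
  L <- unname(nchar(genome)[cand$chrom])
  plus <- cand$strand == "+"
  flank <- kA_tail <- kB_tail <- rep(NA_character_, nrow(cand))

  # plus strand: everything reads left to right in forward coordinates
  okp <- plus & cand$start - flank_len >= 1L & cand$end + tail_len <= L
  if (any(okp)) {
    flank[okp] <- substring(genome[cand$chrom[okp]],
                            cand$start[okp] - flank_len, cand$start[okp] - 1L)
    kA_tail[okp] <- substring(genome[cand$chrom[okp]],
                              cand$start[okp], cand$start[okp] + tail_len - 1L)
    kB_tail[okp] <- substring(genome[cand$chrom[okp]],
                              cand$end[okp] + 1L, cand$end[okp] + tail_len)
  }
  # minus strand: element-strand windows map to reverse-complemented
  # forward-strand intervals on the other side of the span
  okm <- !plus & cand$end + flank_len <= L & cand$start - tail_len >= 1L
  if (any(okm)) {
    flank[okm] <- revcomp(substring(genome[cand$chrom[okm]],
                                    cand$end[okm] + 1L,
                                    cand$end[okm] + flank_len))
    kA_tail[okm] <- revcomp(substring(genome[cand$chrom[okm]],
                                      cand$end[okm] - tail_len + 1L,
                                      cand$end[okm]))
    kB_tail[okm] <- revcomp(substring(genome[cand$chrom[okm]],
                                      cand$start[okm] - tail_len,
                                      cand$start[okm] - 1L))
  }
  tibble(
    element_id = sprintf("RP_%s_%d", cand$chrom, cand$start),
    class = "REF_PLUS",
    chrom = cand$chrom,
    pos = as.integer(cand$start),
    strand = cand$strand,
    kmerA = paste0(flank, kA_tail),
    kmerB = paste0(flank, kB_tail)
  )
}

# genome-wide occurrence count of each k-mer, both strands (canonical);
# a palindromic k-mer is counted once per site
genome_kmer_counts <- function(kmers, genome) {
  genome <- as_genome(genome)
  if (length(kmers) == 0L) return(integer())
  rc <- revcomp(kmers)
  pats <- c(kmers, rc)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
  counts <- rep(0L, length(pats))
  for (chromseq in genome) {
    counts <- counts +
      Biostrings::countPDict(pd, Biostrings::DNAString(chromseq))
  }
  n <- length(kmers)
  fwd <- counts[seq_len(n)]
  rev <- counts[n + seq_len(n)]
  as.integer(ifelse(kmers == rc, fwd, fwd + rev))
}

#' Filter a 32-mer pair set for genotyping reliability
#'
#' Applies the four pair-level filters. Each is a property of the pair set as
#' a whole, so the result is independent of evaluation order:
#' \itemize{
#'   \item duplicates: any canonical 32-mer shared by two or more pairs
#'     removes all pairs involved;
#'   \item closely located: two breakpoints on the same chromosome closer
#'     than `min_distance` remove all pairs involved;
#'   \item GC-rich: either 32-mer with GC fraction above `gc_max`;
#'   \item reference occurrence: `kmerA` must occur exactly once in the
#'     reference (both strands) and `kmerB` not at all.
#' }
#'
#' @param pairs An `alu_pairs` tibble.
#' @param genome Reference genome the pairs were built against.
#' @param min_distance Minimum breakpoint separation in bp (default 32, one
#'   k-mer length: closer pairs interfere with each other's k-mers).
#' @param gc_max Maximum GC fraction (default 0.80; GC-extreme k-mers show
#'   coverage bias in short-read data).
#' @return The kept pairs, with a `rejections` attribute
#'   (tibble `element_id`, `reason`) retrievable via [pair_rejections()].
#' @export
filter_pairs <- function(pairs, genome, min_distance = 32L, gc_max = 0.80) {
  genome <- as_genome(genome)
  if (nrow(pairs) == 0L) {
    return(new_alu_pairs(pairs, attr(pairs, "ref") %||% "unnamed",
                         rejections = tibble(element_id = character(),
                                             reason = character())))
  }
  long <- bind_rows(
    tibble(element_id = pairs$element_id, kmer = pairs$kmerA),
    tibble(element_id = pairs$element_id, kmer = pairs$kmerB)
  ) |> mutate(canon = canonical_kmer(.data$kmer))

  dup_canon <- long |>
    distinct(.data$element_id, .data$canon) |>
    count(.data$canon) |>
    filter(.data$n > 1L) |>
    pull(.data$canon)
  rej_dup <- long |>
    filter(.data$canon %in% dup_canon) |>
    distinct(.data$element_id) |>
    mutate(reason = "duplicate_kmer")

  close_ids <- pairs |>
    group_by(.data$chrom) |>
    arrange(.data$pos, .by_group = TRUE) |>
    mutate(
      d_prev = .data$pos - dplyr::lag(as.numeric(.data$pos),
                                      default = -Inf),
      d_next = dplyr::lead(as.numeric(.data$pos), default = Inf) - .data$pos
    ) |>
    ungroup() |>
    filter(.data$d_prev < min_distance | .data$d_next < min_distance) |>
    pull(.data$element_id)
  rej_close <- tibble(element_id = close_ids, reason = "closely_located")

  gc_bad <- gc_fraction(pairs$kmerA) > gc_max |
    gc_fraction(pairs$kmerB) > gc_max
  rej_gc <- tibble(element_id = pairs$element_id[gc_bad], reason = "gc_rich")

  nA <- genome_kmer_counts(pairs$kmerA, genome)
  nB <- genome_kmer_counts(pairs$kmerB, genome)
  occ_bad <- nA != 1L | nB != 0L
  rej_occ <- tibble(element_id = pairs$element_id[occ_bad],
                    reason = "reference_occurrence")

  rejections <- bind_rows(rej_dup, rej_close, rej_gc, rej_occ) |>
    arrange(.data$element_id, .data$reason)
  kept <- pairs |> filter(!.data$element_id %in% rejections$element_id)
  new_alu_pairs(kept, attr(pairs, "ref") %||% "unnamed",
                rejections = rejections)
}

#' @rdname filter_pairs
#' @export
pair_rejections <- function(pairs) {
  attr(pairs, "rejections") %||%
    tibble(element_id = character(), reason = character())
}

#' Merge pair databases
#'
#' Union of pair sets built against the same reference, deduplicated by
#' breakpoint coordinate and class, deterministically sorted. Conflicting
#' reference tags are an error.
#'
#' @param ... `alu_pairs` tibbles.
#' @return A single merged `alu_pairs` tibble.
#' @export
merge_pair_databases <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  refs <- unique(vapply(sets, function(s) attr(s, "ref") %||% "unnamed",
                        character(1)))
  refs <- setdiff(refs, "unnamed")
  if (length(refs) > 1L) {
    abort(sprintf("conflicting reference declarations: %s",
                  paste(refs, collapse = ", ")))
  }
  merged <- bind_rows(lapply(sets, as_tibble)) |>
    distinct(.data$class, .data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos, .data$class)
  new_alu_pairs(merged, if (length(refs)) refs else "unnamed")
}

validate_pairs <- function(pairs, flank_len = 25L, klen = 32L) {
  bad <- which(
    nchar(pairs$kmerA) != klen | nchar(pairs$kmerB) != klen |
      substr(pairs$kmerA, 1L, flank_len) !=
        substr(pairs$kmerB, 1L, flank_len) |
      pairs$kmerA == pairs$kmerB
  )
  if (length(bad)) {
    abort(sprintf("invalid k-mer pair for element %s",
                  pairs$element_id[bad[1L]]))
  }
  invisible(pairs)
}

#' Write and read a 32-mer pair database
#'
#' TSV with `#ref=` and `#k=` header lines; this file is the genotyping
#' input. Records violating the pair invariants (length 32, shared 25 bp
#' flank, distinct alleles) are refused at write time.
#'
#' @param pairs An `alu_pairs` tibble.
#' @param path File path.
#' @return `write_pairs()` returns `path` invisibly; `read_pairs()` the pair
#'   tibble.
#' @export
write_pairs <- function(pairs, path) {
  validate_pairs(pairs)
  write_tsv_headed(
    as_tibble(pairs), path,
    c(sprintf("#ref=%s", attr(pairs, "ref") %||% "unnamed"), "#k=32")
  )
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- read_tsv_headed(path, readr::cols(
    element_id = readr::col_character(), class = readr::col_character(),
    chrom = readr::col_character(), pos = readr::col_integer(),
    strand = readr::col_character(), kmerA = readr::col_character(),
    kmerB = readr::col_character()
  ))
  meta <- attr(df, "meta")
  out <- as_tibble(df)
  attr(out, "meta") <- NULL
  validate_pairs(out)
  new_alu_pairs(out, meta$ref %||% "unnamed")
}
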