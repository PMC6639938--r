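#' Exact-location index of reference 25-mers
#'
#' Builds a lookup from every ACGT-only k-mer window of the reference (both
#' strands, via canonical form) to its genomic occurrences. The discovery
#' pipeline only ever needs to distinguish "absent", "unique" and "repeated",
#' so occurrence lists are capped at `cap` entries per k-mer with the true
#' total retained; canonical-form storage halves the index and the matching
#' strand is recovered at query time. Windows containing `N` are skipped.
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param k K-mer length; default 25, the flank length used throughout.
#' @param cap Maximum stored occurrences per canonical k-mer (default 4).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(genome, k = 25L, cap = 4L) {
  genome <- as_genome(genome)
  k <- as.integer(k)
  stopifnot(k >= 1L, cap >= 1L)
  occ <- map_dfr(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    n <- nchar(seq) - k + 1L
    if (n < 1L) return(tibble())
    win <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
    ok <- !stringr::str_detect(win, "[^ACGT]")
    if (!any(ok)) return(tibble())
    win <- win[ok]
    rc <- chartr("ACGT", "TGCA", stringi::stri_reverse(win))
    fwd_is_canon <- win <= rc
    tibble(
      kmer = ifelse(fwd_is_canon, win, rc),
      chrom = chrom,
      pos = which(ok),
      fwd = fwd_is_canon
    )
  })
  if (nrow(occ) == 0L) {
    occ <- tibble(kmer = character(), chrom = character(),
                  pos = integer(), fwd = logical())
    counts <- tibble(kmer = character(), n_total = integer())
  } else {
    ord <- order(occ$kmer, occ$chrom, occ$pos)
    occ <- occ[ord, ]
    r <- rle(occ$kmer)
    counts <- tibble(kmer = r$values, n_total = r$lengths)
    within_grp <- sequence(r$lengths)
    occ <- occ[within_grp <= cap, ]
  }
  structure(
    list(k = k, cap = as.integer(cap), occ = occ, counts = counts,
         ref = ref_tag(genome)),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d distinct canonical %d-mers, ref=%s\n",
              x$k, nrow(x$counts), x$k, x$ref))
  invisible(x)
}

check_index_query <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  check_dna(kmers, allow_n = FALSE, arg = "kmers")
  if (any(nchar(kmers) != index$k)) {
    abort(sprintf("queries must be %d-mers", index$k))
  }
  invisible(kmers)
}

#' Locate k-mers in the reference
#'
#' Returns all genomic occurrences of each query (up to the index cap), with
#' forward-strand coordinates. `strand` is `"+"` when the query occurs as
#' given on the forward strand at `pos`, `"-"` when its reverse complement
#' does; for a palindromic match `"+"` is preferred. Queries absent from the
#' reference contribute no rows.
#'
#' @param index A `kmer_index`.
#' @param kmers Character vector of k-mers (length `index$k`).
#' @return Tibble with columns `query`, `chrom`, `pos`, `strand`, `n_total`
#'   (true genome-wide occurrence count) and `overflow` (`TRUE` when the
#'   stored list was truncated at the cap).
#' @export
locate_kmer <- function(index, kmers) {
  check_index_query(index, kmers)
  rc <- chartr("ACGT", "TGCA", stringi::stri_reverse(kmers))
  q <- tibble(
    query = kmers,
    kmer = ifelse(kmers <= rc, kmers, rc),
    q_fwd = kmers <= rc,
    palin = kmers == rc
  ) |> distinct()
  hits <- inner_join(q, index$occ, by = "kmer",
                     relationship = "many-to-many")
  hits <- inner_join(hits, index$counts, by = "kmer")
  hits |>
    mutate(
      strand = dplyr::if_else(.data$palin | (.data$fwd == .data$q_fwd),
                              "+", "-"),
      overflow = .data$n_total > index$cap
    ) |>
    select("query", "chrom", "pos", "strand", "n_total", "overflow") |>
    arrange(.data$query, .data$chrom, .data$pos)
}

#' Unique genomic location of k-mers
#'
#' A k-mer is "unique" when it occurs exactly once in the reference counting
#' both strands: one forward plus one reverse-complement occurrence is two
#' occurrences, hence not unique.
#'
#' @inheritParams locate_kmer
#' @return Tibble with one row per input query: `query`, `n_total`, and
#'   `chrom`/`pos`/`strand` (NA unless `n_total == 1`).
#' @export
unique_location <- function(index, kmers) {
  check_index_query(index, kmers)
  hits <- locate_kmer(index, unique(kmers))
  uniq <- hits |> filter(.data$n_total == 1L)
  out <- tibble(query = kmers) |>
    left_join(uniq, by = "query") |>
    left_join(
      hits |> distinct(.data$query, n_seen = .data$n_total),
      by = "query"
    ) |>
    mutate(n_total = dplyr::coalesce(.data$n_total, .data$n_seen, 0L)) |>
    select("query", "chrom", "pos", "strand", "n_total")
  out
}

#' Persist and reload a k-mer index
#'
#' TSV dump with a version header so one index can be reused across a cohort
#' of discovery runs.
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @return `write_kmer_index()` returns `path` invisibly; `read_kmer_index()`
#'   the restored index.
#' @export
write_kmer_index <- function(index, path) {
  df <- inner_join(index$occ, index$counts, by = "kmer") |>
    arrange(.data$kmer, .data$chrom, .data$pos)
  write_tsv_headed(
    df, path,
    std_headers("kmer_index", index$ref,
                c(sprintf("#k=%d", index$k), sprintf("#cap=%d", index$cap)))
  )
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  if (!any(grepl("^#k=", readLines(path, n = 10L)))) {
    abort("not an aluscan index file (missing #k header)")
  }
  df <- read_tsv_headed(path, readr::cols(
    kmer = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), fwd = readr::col_logical(),
    n_total = readr::col_integer()
  ))
  meta <- attr(df, "meta")
  if (is.null(meta$k)) abort("not an aluscan index file (missing #k header)")
  counts <- df |> distinct(.data$kmer, .data$n_total)
  structure(
    list(k = as.integer(meta$k), cap = as.integer(meta$cap),
         occ = df |> select("kmer", "chrom", "pos", "fwd"),
         counts = counts, ref = meta$ref %||% "unnamed"),
    class = "kmer_index"
  )
}
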