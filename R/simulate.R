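# Planted-insertion simulation: insert Alu elements (TSD + element + polyA
# structure) into a diploid copy of a reference, generate wgsim-style paired
# short reads with substitution errors, and score discovery sensitivity with
# a false-negative decomposition (FN1: flank not unique in the reference;
# FN2: insertion region overlaps unsequenced N runs).

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  L <- nchar(seq)
  k <- rbinom(1L, L, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(L, k)
  bases <- c("A", "C", "G", "T")
  orig <- match(substring(seq, pos, pos), bases)
  new <- bases[(orig + sample.int(3L, k, replace = TRUE) - 1L) %% 4L + 1L]
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ch[pos] <- new
  paste(ch, collapse = "")
}

#' Plant Alu insertions into a diploid copy of a genome
#'
#' Each insertion is placed at a uniform random non-N position and carries
#' the canonical retrotransposition structure: the `tsd_len` bases 5' of the
#' breakpoint are duplicated so that they flank the element, i.e. the
#' haplotype becomes `ref[..pos-1] + Alu + polyA + TSD + ref[pos..]` with
#' `TSD = ref[pos-tsd_len .. pos-1]`. The Alu body is mutated by i.i.d.
#' substitutions at `mutation_rate` (the signature may be hit - that is part
#' of simulated detectability); the polyA length is uniform in
#' `polya_range`. Insertions are heterozygous by default (one haplotype
#' chosen at random); `zygosity` may assign `"hom"` (both haplotypes) or
#' `"none"` (recorded in the truth set but not planted, for genotyping
#' truth). Elements are planted in forward orientation. Deterministic under
#' `seed`.
#'
#' @param genome Reference genome.
#' @param n Number of insertions.
#' @param mutation_rate Substitution rate on the Alu body, in `[0, 0.3]`.
#' @param seed Optional RNG seed. Positions, zygosity, and polyA lengths are
#'   drawn before any mutation, so two runs with the same seed and different
#'   `mutation_rate` plant at identical positions.
#' @param alu Insert backbone (single sequence; default the packaged
#'   consensus).
#' @param tsd_len Target site duplication length (default 15).
#' @param polya_range Inclusive polyA length range (default `c(5, 80)`).
#' @param zygosity `"het"`, `"hom"`, `"none"`, or a vector of these
#'   (recycled to `n`).
#' @param at Optional tibble with columns `chrom` and `pos` giving directed
#'   insertion positions (used to build targeted fixtures, e.g. insertions
#'   inside a duplicated block or next to an N run); overrides random
#'   placement. Must have `n` rows.
#' @return List with `haplotypes` (list of two named character vectors) and
#'   `truth` (tibble `chrom`, `pos`, `haplotype`, `tsd`, `polya_len`,
#'   `alu_seq`); class `alu_planted`.
#' @export
plant_insertions <- function(genome, n, mutation_rate = 0, seed = NULL,
                             alu = NULL, tsd_len = 15L,
                             polya_range = c(5L, 80L), zygosity = "het",
                             at = NULL) {
  genome <- as_genome(genome)
  stopifnot(n >= 1L, mutation_rate >= 0, mutation_rate <= 0.3)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alu)) alu <- unname(alu_consensus()[1L])
  zyg <- rep(zygosity, length.out = n)
  stopifnot(all(zyg %in% c("het", "hom", "none")))

  lens <- nchar(genome)
  n_valid <- sum(pmax(lens - tsd_len, 0L)) -
    sum(stringr::str_count(substring(genome, tsd_len + 1L, lens), "N"))
  if (n > n_valid) {
    abort(sprintf("n = %d exceeds the %d available non-N positions",
                  n, n_valid))
  }

  if (!is.null(at)) {
    stopifnot(nrow(at) == n, all(at$pos > tsd_len),
              all(at$chrom %in% names(genome)))
    chroms <- at$chrom
    poss <- as.integer(at$pos)
  } else {
    # rejection-sample distinct non-N positions with a full TSD window
    chroms <- character(0)
    poss <- integer(0)
    while (length(poss) < n) {
      need <- n - length(poss)
      ci <- sample(names(genome), need, replace = TRUE,
                   prob = pmax(lens - tsd_len, 0L))
      pp <- tsd_len + 1L +
        floor(runif(need) * (lens[ci] - tsd_len))
      pp <- as.integer(pp)
      ok <- substring(genome[ci], pp, pp) != "N" &
        !duplicated(paste(ci, pp)) &
        !(paste(ci, pp) %in% paste(chroms, poss))
      chroms <- c(chroms, ci[ok])
      poss <- c(poss, pp[ok])
    }
  }
  hap_of <- ifelse(zyg == "het", as.character(sample(1:2, n, replace = TRUE)),
                   ifelse(zyg == "hom", "both", "none"))
  polya <- sample(seq.int(polya_range[1L], polya_range[2L]), n,
                  replace = TRUE)
  alu_mut <- vapply(seq_len(n), function(i) mutate_seq(alu, mutation_rate),
                    character(1))

  truth <- tibble(
    chrom = chroms, pos = poss, haplotype = hap_of,
    tsd = unname(substring(genome[chroms], poss - tsd_len, poss - 1L)),
    polya_len = as.integer(polya),
    alu_seq = alu_mut
  ) |> arrange(.data$chrom, .data$pos)

  payload <- paste0(truth$alu_seq, strrep("A", truth$polya_len), truth$tsd)
  haps <- lapply(c("1", "2"), function(h) {
    out <- genome
    for (chrom in unique(truth$chrom)) {
      rows <- which(truth$chrom == chrom &
                      truth$haplotype %in% c(h, "both"))
      if (!length(rows)) next
      pos <- truth$pos[rows]
      L <- nchar(genome[[chrom]])
      pieces <- substring(genome[[chrom]], c(1L, pos), c(pos - 1L, L))
      merged <- character(2L * length(pos) + 1L)
      merged[seq_along(pos) * 2L - 1L] <- pieces[seq_along(pos)]
      merged[seq_along(pos) * 2L] <- payload[rows]
      merged[2L * length(pos) + 1L] <- pieces[length(pos) + 1L]
      out[[chrom]] <- paste(merged, collapse = "")
    }
    names(out) <- names(genome)
    out
  })
  structure(
    list(haplotypes = setNames(haps, c("hap1", "hap2")), truth = truth,
         ref = ref_tag(genome)),
    class = "alu_planted"
  )
}

#' @export
print.alu_planted <- function(x, ...) {
  cat(sprintf("<alu_planted> %d insertions over %d chromosome(s)\n",
              nrow(x$truth), length(x$haplotypes$hap1)))
  invisible(x)
}

#' Simulate wgsim-style paired-end reads
#'
#' Uniform fragment sampling across all supplied haplotype sequences;
#' fragment (outer) length is Normal(`outer_dist`, `insert_sd`) truncated to
#' `[read_len, chromosome length]`; mate 1 is the fragment's 5' end, mate 2
#' the reverse complement of its 3' end; substitution errors are applied
#' per base at `error_rate`. Deterministic under `seed`.
#'
#' @param haplotypes An `alu_planted` object, a list of named character
#'   vectors, or a single named character vector.
#' @param coverage Target mean depth per locus (total over haplotypes).
#'   Exactly one of `coverage`/`n_pairs` must be given.
#' @param n_pairs Number of read pairs to draw.
#' @param read_len Read length (default 151).
#' @param outer_dist,insert_sd Fragment length mean 500 and sd 50.
#' @param error_rate Per-base substitution error rate (default 0.005).
#' @param seed Optional RNG seed.
#' @return Tibble `read_id`, `mate1`, `mate2`.
#' @export
simulate_reads <- function(haplotypes, coverage = NULL, n_pairs = NULL,
                           read_len = 151L, outer_dist = 500L,
                           insert_sd = 50L, error_rate = 0.005,
                           seed = NULL) {
  if (inherits(haplotypes, "alu_planted")) haplotypes <- haplotypes$haplotypes
  if (is.character(haplotypes)) haplotypes <- list(haplotypes)
  frame <- unlist(lapply(seq_along(haplotypes), function(i) {
    h <- haplotypes[[i]]
    setNames(unname(h), paste0("h", i, ".", names(h)))
  }))
  stopifnot(error_rate >= 0, error_rate < 1, read_len >= 1)
  if (!is.null(seed)) set.seed(seed)

  lens <- nchar(frame)
  usable <- lens >= read_len
  if (!all(usable)) {
    warn("sequences shorter than the read length were skipped")
    frame <- frame[usable]
    lens <- lens[usable]
  }
  if (length(frame) == 0L) abort("no sequence long enough to sample from")
  haploid_len <- sum(lens) / length(haplotypes)
  if (is.null(n_pairs)) {
    if (is.null(coverage)) abort("supply `coverage` or `n_pairs`")
    n_pairs <- ceiling(coverage * haploid_len / (2 * read_len))
  }
  n_pairs <- as.integer(n_pairs)

  ci <- sample.int(length(frame), n_pairs, replace = TRUE, prob = lens)
  frag <- pmin(pmax(as.integer(round(rnorm(n_pairs, outer_dist, insert_sd))),
                    read_len), lens[ci])
  start <- 1L + as.integer(floor(runif(n_pairs) * (lens[ci] - frag + 1L)))
  seqs <- frame[ci]
  mate1 <- substring(seqs, start, start + read_len - 1L)
  mate2 <- revcomp(substring(seqs, start + frag - read_len, start + frag - 1L))

  # substitution errors
  total <- 2L * n_pairs * read_len
  k <- rbinom(1L, total, error_rate)
  if (k > 0L) {
    reads <- c(mate1, mate2)
    ri <- sample.int(2L * n_pairs, k, replace = TRUE)
    rp <- sample.int(read_len, k, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    # apply in rounds so several errors on one read all take effect
    round_of <- stats::ave(seq_len(k), ri, FUN = seq_along)
    for (r in seq_len(max(round_of))) {
      sel <- round_of == r
      i <- ri[sel]; p <- rp[sel]
      orig <- match(substr(reads[i], p, p) |>
                      substring(1L, 1L), bases)
      ok <- !is.na(orig)  # leave N bases untouched
      i <- i[ok]; p <- p[ok]; orig <- orig[ok]
      if (!length(i)) next
      new <- bases[(orig + sample.int(3L, length(i), replace = TRUE) - 1L)
                   %% 4L + 1L]
      x <- reads[i]
      substr(x, p, p) <- new
      reads[i] <- x
    }
    mate1 <- reads[seq_len(n_pairs)]
    mate2 <- reads[n_pairs + seq_len(n_pairs)]
  }
  tibble(
    read_id = sprintf("sim%d", seq_len(n_pairs)),
    mate1 = unname(mate1),
    mate2 = unname(mate2)
  )
}

#' Evaluate REF- discovery against a planted truth set
#'
#' Matches each planted insertion to the nearest discovered breakpoint on
#' the same chromosome within `tol` bp (one discovery matches at most one
#' truth record). Unmatched insertions are decomposed into FN2 when the
#' reference region the method must read - the `flank_len` bases 5' of the
#' breakpoint plus the 10 reference bases the junction is compared against -
#' overlaps an `N` run (unsequenced, hence invisible to any sequencing-based
#' method; this is a property of the reference alone, so it does not depend
#' on the element's mutation load), FN1 when that
#' flank is not reference-unique (repeat structure defeats flank
#' localisation), and "missed_other" otherwise (e.g. the signature itself
#' was mutated away or read support fell short). Discovered candidates
#' matching no truth record are counted as false discoveries.
#'
#' @param truth Truth tibble from [plant_insertions()] (rows with haplotype
#'   `"none"` are ignored: nothing was planted).
#' @param discovered REF- candidate tibble.
#' @param index `kmer_index` of the original reference.
#' @param genome The original reference genome.
#' @param tol Breakpoint match tolerance in bp (default 5; the TSD makes the
#'   exact reported base convention-dependent).
#' @param flank_len Flank length (default 25).
#' @return The truth tibble with a `status` column
#'   (`detected`/`FN1`/`FN2`/`missed_other`); class `alu_eval`, carrying a
#'   `false_discoveries` attribute. Use [glance()] for rates.
#' @export
evaluate_discovery <- function(truth, discovered, index, genome, tol = 5L,
                               flank_len = 25L) {
  genome <- as_genome(genome)
  planted <- truth |> filter(.data$haplotype != "none")
  disc <- as_tibble(discovered) |>
    mutate(.disc_id = dplyr::row_number())

  cand_match <- planted |>
    mutate(.truth_id = dplyr::row_number()) |>
    inner_join(disc |> select(".disc_id", "chrom", disc_pos = "pos"),
               by = "chrom", relationship = "many-to-many") |>
    filter(abs(.data$disc_pos - .data$pos) <= tol) |>
    arrange(abs(.data$disc_pos - .data$pos)) |>
    distinct(.data$.truth_id, .keep_all = TRUE) |>
    distinct(.data$.disc_id, .keep_all = TRUE)

  status <- rep("missed_other", nrow(planted))
  status[cand_match$.truth_id] <- "detected"

  un <- which(status != "detected")
  if (length(un)) {
    win <- substring(genome[planted$chrom[un]],
                     pmax(planted$pos[un] - flank_len, 1L),
                     pmin(planted$pos[un] + 9L,
                          nchar(genome)[planted$chrom[un]]))
    has_n <- stringr::str_detect(win, "N")
    status[un[has_n]] <- "FN2"
    rest <- un[!has_n]
    if (length(rest)) {
      fl <- substring(genome[planted$chrom[rest]],
                      planted$pos[rest] - flank_len,
                      planted$pos[rest] - 1L)
      valid <- !stringr::str_detect(fl, "[^ACGT]") & nchar(fl) == flank_len
      nonuniq <- rep(FALSE, length(rest))
      if (any(valid)) {
        ul <- unique_location(index, fl[valid])
        nonuniq[valid] <- ul$n_total != 1L
      }
      nonuniq[!valid] <- TRUE
      status[rest[nonuniq]] <- "FN1"
    }
  }

  out <- planted
  out$status <- status
  attr(out, "false_discoveries") <- nrow(disc) - nrow(cand_match)
  attr(out, "tol") <- tol
  class(out) <- c("alu_eval", class(out))
  out
}
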