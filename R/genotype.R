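# Alignment-free genotyping: count the two allele-specific 32-mers of every
# element directly in raw reads (canonical matching, exact counts) and call
# the genotype with a flat-prior Bayes classifier. Allele counts are modelled
# as independent Poisson draws with per-genotype expected intensities
#   ploidy 2:  AA (lam, eps), AB (lam/2, lam/2), BB (eps, lam)
#   ploidy 1:  A  (lam, eps), B  (eps, lam)
# where lam is the expected per-element k-mer coverage and eps the leak rate
# for an absent allele (sequencing errors, cross-mapping).

#' Count allele-specific 32-mer pairs in raw reads
#'
#' Exact occurrence counts of every pair k-mer in the read stream, canonical
#' (strand-independent) matching; a read containing a k-mer twice contributes
#' two counts. Counting is invariant to read order and orientation.
#'
#' @param reads Read input (sequences, FASTQ/BAM/SAM paths, or a read tibble).
#' @param pairs Pair database ([build_pairs()] / [read_pairs()]).
#' @return Tibble `element_id`, `nA`, `nB`; class `alu_counts`.
#' @export
count_pair_kmers <- function(reads, pairs) {
  reads <- as_reads(reads)
  validate_pairs(pairs)
  if (nrow(pairs) == 0L) {
    out <- tibble(element_id = character(), nA = integer(), nB = integer())
    class(out) <- c("alu_counts", class(out))
    return(out)
  }
  subject <- Biostrings::DNAString(paste(reads, collapse = "+"))
  count_in <- function(kmers) {
    rc <- revcomp(kmers)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(c(kmers, rc)))
    cnt <- Biostrings::countPDict(pd, subject)
    n <- length(kmers)
    as.integer(ifelse(kmers == rc, cnt[seq_len(n)],
                      cnt[seq_len(n)] + cnt[n + seq_len(n)]))
  }
  out <- tibble(
    element_id = pairs$element_id,
    nA = count_in(pairs$kmerA),
    nB = count_in(pairs$kmerB)
  )
  class(out) <- c("alu_counts", class(out))
  out
}

#' Calibrate the genotype caller from one individual's counts
#'
#' The expected per-element k-mer coverage `lam` is estimated as the median
#' of `nA + nB` over elements with at least one observed k-mer (for a
#' diploid, both alleles together represent two copies whatever the
#' genotype, so the total count is genotype-independent). The leak rate for
#' an absent allele is `eps = max(0.01 * lam, 0.1)`.
#'
#' @param counts `alu_counts` tibble (at least 100 informative elements for
#'   a self-contained calibration).
#' @param coverage Optional user-supplied expected k-mer coverage, used as
#'   `lam` when fewer than 100 informative elements are available.
#' @return A `caller_model` object with fields `lam` and `eps`.
#' @export
calibrate_caller <- function(counts, coverage = NULL) {
  if (nrow(counts) == 0L && is.null(coverage)) {
    abort("cannot calibrate from an empty count set without `coverage`")
  }
  tot <- counts$nA + counts$nB
  informative <- tot[tot > 0L]
  if (length(informative) < 100L) {
    if (is.null(coverage)) {
      if (length(informative) == 0L) {
        abort("no informative elements and no `coverage` supplied")
      }
      warn(sprintf(
        "only %d informative elements (< 100); calibration may be unstable",
        length(informative)
      ))
      lam <- median(informative)
    } else {
      warn("fewer than 100 informative elements; using supplied coverage")
      lam <- coverage
    }
  } else {
    lam <- median(informative)
  }
  structure(list(lam = as.numeric(lam), eps = max(0.01 * lam, 0.1)),
            class = "caller_model")
}

#' @export
print.caller_model <- function(x, ...) {
  cat(sprintf("<caller_model> lam=%.2f (per-allele k-mer coverage), eps=%.3f\n",
              x$lam, x$eps))
  invisible(x)
}

genotype_posteriors <- function(nA, nB, lam, eps, ploidy) {
  if (ploidy == 2L) {
    hyp <- c("AA", "AB", "BB")
    muA <- c(lam, lam / 2, eps)
    muB <- c(eps, lam / 2, lam)
  } else {
    hyp <- c("A", "B")
    muA <- c(lam, eps)
    muB <- c(eps, lam)
  }
  ll <- vapply(seq_along(hyp), function(i) {
    dpois(nA, muA[i], log = TRUE) + dpois(nB, muB[i], log = TRUE)
  }, numeric(length(nA)))
  ll <- matrix(ll, ncol = length(hyp))
  m <- apply(ll, 1L, max)
  post <- exp(ll - m)
  post <- post / rowSums(post)
  colnames(post) <- hyp
  post
}

#' Call genotypes from allele counts
#'
#' Flat-prior Bayes classification among the genotype hypotheses for the
#' element's ploidy, with Poisson count likelihoods (see the model above).
#' The maximum-posterior genotype is called iff its posterior reaches
#' `min_posterior`; otherwise the call is `NC` (no call).
#'
#' @param counts `alu_counts` tibble.
#' @param model `caller_model` from [calibrate_caller()].
#' @param ploidy Integer scalar or per-element vector (1 or 2; default 2).
#' @param min_posterior Call threshold in (0.5, 1); default 0.95.
#' @return Tibble `element_id`, `nA`, `nB`, `ploidy`, `genotype`,
#'   `posterior`; class `alu_calls`.
#' @export
call_genotypes <- function(counts, model, ploidy = 2L,
                           min_posterior = 0.95) {
  stopifnot(inherits(model, "caller_model"),
            min_posterior > 0.5, min_posterior < 1)
  ploidy <- as.integer(rep(ploidy, length.out = nrow(counts)))
  stopifnot(all(ploidy %in% c(1L, 2L)))
  out <- counts |>
    as_tibble() |>
    mutate(ploidy = ploidy, genotype = "NC", posterior = NA_real_)
  for (p in unique(ploidy)) {
    idx <- which(ploidy == p)
    post <- genotype_posteriors(out$nA[idx], out$nB[idx],
                                model$lam, model$eps, p)
    best <- max.col(post, ties.method = "first")
    bp <- post[cbind(seq_along(idx), best)]
    g <- colnames(post)[best]
    g[bp < min_posterior] <- "NC"
    out$genotype[idx] <- g
    out$posterior[idx] <- bp
  }
  class(out) <- c("alu_calls", class(out))
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the allele counts, the probability of each
#' possible heterozygote count follows the Levene-Haldane distribution; the
#' two-sided p-value sums the probabilities of all configurations no more
#' probable than the observed one. Computed with the standard mid-out
#' recurrence over heterozygote counts, vectorised over markers.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (vectors recycle).
#' @return Numeric vector of p-values.
#' @examples
#' hwe_exact_test(25, 50, 25)  # ~1: textbook equilibrium
#' hwe_exact_test(50, 0, 50)   # << 1e-4
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  args <- vctrs_recycle(n_aa, n_ab, n_bb)
  mapply(hwe_exact_one, args[[1L]], args[[2L]], args[[3L]])
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, rep, length.out = n)
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_r <- 2L * n_aa + n_ab   # rarer-or-not allele a count
  n_c <- 2L * n_bb + n_ab
  if (n_r > n_c) { tmp <- n_r; n_r <- n_c; n_c <- tmp }
  if (n_r == 0L) return(1)

  hets <- seq.int(n_r %% 2L, n_r, by = 2L)
  # unnormalised probabilities by recurrence from the smallest het count:
  # P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+2) * (h+1))
  # with n_aa(h) = (n_r - h)/2, n_bb(h) = (n_c - h)/2
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1L]) {
    h <- hets[i - 1L]
    lp[i] <- lp[i - 1L] +
      log(4) + log((n_r - h) / 2) + log((n_c - h) / 2) -
      log(h + 2) - log(h + 1)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_ab, hets)
  if (is.na(obs)) abort("inconsistent genotype counts")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Cohort-level reliability filter for genotyped elements
#'
#' Removes elements that misbehave across a cohort: (a) an excessive
#' fraction of unexpected-ploidy genotypes (a diploid call where a haploid
#' one is expected for that individual's sex and the element's chromosome,
#' or vice versa; `NC` never counts, and is excluded from the denominator);
#' (b) deviation from Hardy-Weinberg equilibrium (exact test over autosomal
#' diploid calls); (c) REF- elements with no B allele anywhere in the cohort
#' (monomorphic, i.e. never actually observed inserted). Monomorphic REF+
#' elements are retained: absence of the B allele there just means no tested
#' individual lacks the element, which may differ in other populations.
#'
#' @param calls Long tibble of per-individual calls: columns `element_id`,
#'   `individual`, `genotype`, `ploidy`.
#' @param pairs Pair database (provides `class` and `chrom` per element).
#' @param ploidy_map Tibble `individual`, `sex` (`"male"`/`"female"`).
#'   Haploid calls are expected on `chrY` for males; `chrY` is absent in
#'   females (any call there is unexpected).
#' @param max_unexpected Maximum tolerated unexpected-genotype fraction
#'   (default 0.02).
#' @param hwe_alpha HWE rejection threshold (default 1e-4).
#' @return The validated subset of `pairs`, with a `rejections` attribute
#'   (tibble `element_id`, `reason`).
#' @export
cohort_filter <- function(calls, pairs, ploidy_map,
                          max_unexpected = 0.02, hwe_alpha = 1e-4) {
  stopifnot(all(c("element_id", "individual", "genotype") %in% names(calls)))
  unknown <- setdiff(unique(calls$individual), ploidy_map$individual)
  if (length(unknown)) {
    abort(sprintf("individuals missing from ploidy map: %s",
                  paste(head(unknown, 3L), collapse = ", ")))
  }
  ann <- calls |>
    inner_join(pairs |> select("element_id", "class", "chrom"),
               by = "element_id") |>
    inner_join(ploidy_map, by = "individual") |>
    mutate(
      expected_ploidy = dplyr::case_when(
        .data$chrom %in% c("chrY", "Y") & .data$sex == "male" ~ 1L,
        .data$chrom %in% c("chrY", "Y") & .data$sex == "female" ~ 0L,
        TRUE ~ 2L
      ),
      called_ploidy = dplyr::case_when(
        .data$genotype %in% c("AA", "AB", "BB") ~ 2L,
        .data$genotype %in% c("A", "B") ~ 1L,
        TRUE ~ NA_integer_
      )
    )

  unexpected <- ann |>
    filter(!is.na(.data$called_ploidy)) |>
    group_by(.data$element_id) |>
    summarise(
      frac_unexpected = mean(.data$called_ploidy != .data$expected_ploidy)
    ) |>
    filter(.data$frac_unexpected > max_unexpected)
  rej_unexp <- tibble(element_id = unexpected$element_id,
                      reason = "unexpected_ploidy")

  hwe <- ann |>
    filter(.data$expected_ploidy == 2L,
           .data$genotype %in% c("AA", "AB", "BB")) |>
    group_by(.data$element_id) |>
    summarise(
      n_aa = sum(.data$genotype == "AA"),
      n_ab = sum(.data$genotype == "AB"),
      n_bb = sum(.data$genotype == "BB")
    ) |>
    mutate(p_hwe = hwe_exact_test(.data$n_aa, .data$n_ab, .data$n_bb)) |>
    filter(.data$p_hwe < hwe_alpha)
  rej_hwe <- tibble(element_id = hwe$element_id, reason = "hwe_deviation")

  mono <- ann |>
    group_by(.data$element_id, .data$class) |>
    summarise(
      n_b = sum(.data$genotype %in% c("AB", "BB", "B")),
      .groups = "drop"
    ) |>
    filter(.data$class == "REF_MINUS", .data$n_b == 0L)
  rej_mono <- tibble(element_id = mono$element_id,
                     reason = "monomorphic_ref_minus")

  rejections <- bind_rows(rej_unexp, rej_hwe, rej_mono) |>
    arrange(.data$element_id, .data$reason)
  kept <- pairs |> filter(!.data$element_id %in% rejections$element_id)
  new_alu_pairs(kept, attr(pairs, "ref") %||% "unnamed",
                rejections = rejections)
}

#' Write and read genotype call tables
#'
#' @param calls `alu_calls` tibble.
#' @param path File path.
#' @return `write_calls()` returns `path` invisibly; `read_calls()` the
#'   restored tibble.
#' @export
write_calls <- function(calls, path) {
  stopifnot(all(c("element_id", "nA", "nB", "genotype", "posterior") %in%
                  names(calls)))
  write_tsv_headed(as_tibble(calls), path,
                   std_headers("calls", attr(calls, "ref") %||% "unnamed"))
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read_tsv_headed(path, readr::cols(
    element_id = readr::col_character(),
    nA = readr::col_integer(), nB = readr::col_integer(),
    ploidy = readr::col_integer(),
    genotype = readr::col_character(), posterior = readr::col_double()
  ))
  out <- as_tibble(df)
  attr(out, "meta") <- NULL
  class(out) <- c("alu_calls", class(out))
  out
}

#' Export genotype calls as VCF with symbolic mobile-element alleles
#'
#' Minimal VCF 4.2 output: REF- elements become symbolic `<INS:ME:ALU>`
#' insertions and REF+ elements `<DEL:ME:ALU>` deletions relative to the
#' reference, with the called genotype in the sample column.
#'
#' @param calls `alu_calls` tibble for one sample.
#' @param pairs Pair database (coordinates and classes).
#' @param genome Reference genome (REF base at each site).
#' @param path Output path.
#' @param sample Sample name (default `"sample"`).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, pairs, genome, path, sample = "sample") {
  genome <- as_genome(genome)
  d <- calls |>
    inner_join(pairs |> select("element_id", "class", "chrom", "pos"),
               by = "element_id") |>
    arrange(.data$chrom, .data$pos)
  refbase <- substring(genome[d$chrom], pmax(d$pos - 1L, 1L),
                       pmax(d$pos - 1L, 1L))
  alt <- ifelse(d$class == "REF_MINUS", "<INS:ME:ALU>", "<DEL:ME:ALU>")
  gt <- dplyr::case_when(
    d$genotype == "AA" ~ "0/0", d$genotype == "AB" ~ "0/1",
    d$genotype == "BB" ~ "1/1", d$genotype == "A" ~ "0",
    d$genotype == "B" ~ "1", TRUE ~ "./."
  )
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=aluscan-%s", packageVersion("aluscan")),
    "##ALT=<ID=INS:ME:ALU,Description=\"Alu element insertion\">",
    "##ALT=<ID=DEL:ME:ALU,Description=\"Alu element deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=KA,Number=1,Type=Integer,Description=\"kmerA count\">",
    "##FORMAT=<ID=KB,Number=1,Type=Integer,Description=\"kmerB count\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=%s\tGT:KA:KB\t%s:%d:%d",
    d$chrom, pmax(d$pos - 1L, 1L), d$element_id, refbase, alt,
    ifelse(d$class == "REF_MINUS", "INS", "DEL"), gt, d$nA, d$nB
  )
  writeLines(c(header, body), path)
  invisible(path)
}
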