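# Independent oracles used to verify the implementation by a different route.

# brute-force Hamming-distance-<=1 scan of every window against a consensus
brute_sig_hits <- function(seq, consensus = "GGCCGGGCGC",
                           both_strands = TRUE) {
  w <- nchar(consensus)
  cons <- strsplit(consensus, "")[[1]]
  scan_one <- function(s, strand) {
    L <- nchar(s)
    if (L < w) return(NULL)
    out <- list()
    for (i in seq_len(L - w + 1)) {
      win <- strsplit(substr(s, i, i + w - 1), "")[[1]]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      if (sum(win != cons) <= 1) {
        pos <- if (strand == "+") i else nchar(s) - (i + w - 1) + 1
        out[[length(out) + 1]] <- data.frame(pos = pos, strand = strand)
      }
    }
    do.call(rbind, out)
  }
  res <- scan_one(seq, "+")
  if (both_strands) res <- rbind(res, scan_one(revcomp(seq), "-"))
  if (is.null(res)) {
    return(tibble::tibble(pos = integer(), strand = character()))
  }
  tibble::as_tibble(res[order(res$pos, res$strand), ])
}

# brute-force exact location of a k-mer in a genome, both strands
brute_locate <- function(genome, kmer) {
  out <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") kmer else revcomp(kmer)
      # regexpr rescan from each match + 1 so overlapping matches count
      starts <- integer()
      from <- 1L
      s <- genome[[chrom]]
      repeat {
        i <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
        if (i < 0) break
        starts <- c(starts, from + i - 1L)
        from <- from + i
      }
      if (length(starts)) {
        out[[length(out) + 1]] <-
          data.frame(chrom = chrom, pos = starts, strand = strand)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character()))
  }
  d <- do.call(rbind, out)
  # palindromic k-mer: forward and reverse hits coincide; keep "+"
  if (kmer == revcomp(kmer)) d <- d[d$strand == "+", ]
  tibble::as_tibble(d[order(d$chrom, d$pos, d$strand), ])
}

# affine-gap local alignment score by dynamic programming (gap of length g
# costs open + g * ext, the same convention as the implementation)
sw_local_score <- function(a, b, match = 1, mismatch = -2,
                           open = 5, ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- M[, 1] <- 0
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Levene-Haldane exact HWE p-value via the closed-form log-factorial
# expression (independent of the recurrence used by the implementation)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n - n_a
  lp_of <- function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }
  hmin <- min(n_a, n_b)
  hets <- seq(hmin %% 2, hmin, by = 2)
  lp <- vapply(hets, lp_of, numeric(1))
  p <- exp(lp)
  p_obs <- exp(lp_of(n_ab))
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# deterministic small random genome for tests
test_genome <- function(len, seed, name = "chrX") {
  set.seed(seed)
  g <- setNames(aluscan:::random_dna(len), name)
  attr(g, "ref") <- sprintf("test_%s_%d_%d", name, len, seed)
  g
}

alu_seq1 <- function() unname(alu_consensus()[1])

# construct a reference locus that contains a full Alu copy with TSDs:
# left + TSD + alu + polyA + TSD + right (element present in the reference)
ref_plus_locus <- function(left, right, tsd = "ACTGA", polya = 20,
                           alu = alu_seq1()) {
  paste0(left, tsd, alu, strrep("A", polya), tsd, right)
}
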