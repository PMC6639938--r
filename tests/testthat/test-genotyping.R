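mk_pairs <- function(n = 2, seed = 60) {
  set.seed(seed)
  flank <- replicate(n, aluscan:::random_dna(25))
  tibble::tibble(
    element_id = paste0("E", seq_len(n)),
    class = "REF_MINUS", chrom = "chr1",
    pos = 1000L * seq_len(n), strand = "+",
    kmerA = paste0(flank, replicate(n, aluscan:::random_dna(7))),
    kmerB = paste0(flank, "GGCCGGG")
  )
}

test_that("pair counting is exact, canonical and order-invariant", {
  pairs <- mk_pairs(2)
  pad <- function(k) paste0(aluscan:::random_dna(30), k,
                            aluscan:::random_dna(30))
  set.seed(61)
  reads <- c(rep(pad(pairs$kmerA[1]), 10), rep(pad(pairs$kmerB[2]), 4))

  cnt <- count_pair_kmers(reads, pairs)
  expect_equal(cnt$nA, c(10L, 0L))
  expect_equal(cnt$nB, c(0L, 4L))

  # reverse-complemented reads give identical counts
  expect_equal(count_pair_kmers(revcomp(reads), pairs), cnt)
  # read order is irrelevant
  expect_equal(count_pair_kmers(rev(reads), pairs), cnt)
  # no pair k-mers at all
  set.seed(62)
  expect_equal(count_pair_kmers(replicate(5, aluscan:::random_dna(100)),
                                pairs)$nA, c(0L, 0L))
  # a read containing a k-mer twice contributes 2
  double_read <- paste0(pairs$kmerA[1], "TT", pairs$kmerA[1])
  expect_equal(count_pair_kmers(double_read, pairs)$nA[1], 2L)
})

test_that("the Poisson caller reproduces hand-computed posteriors", {
  model <- structure(list(lam = 30, eps = 0.3), class = "caller_model")

  # independent posterior computation straight from the model definition
  post_oracle <- function(nA, nB, lam, eps) {
    li <- c(AA = dpois(nA, lam) * dpois(nB, eps),
            AB = dpois(nA, lam / 2) * dpois(nB, lam / 2),
            BB = dpois(nA, eps) * dpois(nB, lam))
    li / sum(li)
  }

  counts <- tibble::tibble(element_id = c("e1", "e2", "e3"),
                           nA = c(30L, 0L, 14L), nB = c(0L, 0L, 15L))
  calls <- call_genotypes(counts, model, min_posterior = 0.99)
  expect_equal(calls$genotype, c("AA", "NC", "AB"))

  for (i in c(1, 3)) {
    o <- post_oracle(counts$nA[i], counts$nB[i], 30, 0.3)
    expect_equal(calls$posterior[i], unname(max(o)), tolerance = 1e-12)
    expect_equal(calls$genotype[i], names(which.max(o)))
  }
  # (0,0): posterior spread among hypotheses, max below any sane threshold
  o00 <- post_oracle(0, 0, 30, 0.3)
  expect_lt(max(o00), 0.5)

  # haploid calling uses two hypotheses
  h <- call_genotypes(tibble::tibble(element_id = "y1", nA = 0L, nB = 25L),
                      model, ploidy = 1L)
  expect_equal(h$genotype, "B")
})

test_that("the caller is symmetric under allele relabelling", {
  model <- structure(list(lam = 28, eps = 0.3), class = "caller_model")
  set.seed(63)
  nA <- rpois(50, sample(c(28, 14, 0.3), 50, replace = TRUE))
  nB <- rpois(50, sample(c(28, 14, 0.3), 50, replace = TRUE))
  cnt <- tibble::tibble(element_id = paste0("s", 1:50), nA = nA, nB = nB)
  swp <- cnt
  swp$nA <- cnt$nB
  swp$nB <- cnt$nA
  a <- call_genotypes(cnt, model)
  b <- call_genotypes(swp, model)
  flip <- c(AA = "BB", AB = "AB", BB = "AA", NC = "NC")
  expect_equal(unname(flip[a$genotype]), b$genotype)
  expect_equal(a$posterior, b$posterior)
})

test_that("calibration recovers lam from counts and handles edge cases", {
  set.seed(64)
  n <- 150
  nA <- rpois(n, 30)
  cnt <- tibble::tibble(element_id = paste0("c", 1:n), nA = nA,
                        nB = rpois(n, 0.3))
  model <- calibrate_caller(cnt)
  expect_equal(model$lam, median((cnt$nA + cnt$nB)[cnt$nA + cnt$nB > 0]))
  expect_equal(model$eps, max(0.01 * model$lam, 0.1))

  small <- cnt[1:20, ]
  expect_warning(m2 <- calibrate_caller(small, coverage = 30), "fewer")
  expect_equal(m2$lam, 30)
  expect_error(calibrate_caller(small[0, ]), "empty|coverage")
})

test_that("HWE exact test matches the closed-form oracle", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(10, 1, 0), c(0, 2, 8),
                c(3, 3, 3), c(40, 20, 40), c(1, 0, 0), c(0, 0, 5))
  for (cc in cases) {
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 hwe_oracle(cc[1], cc[2], cc[3]),
                 tolerance = 1e-9, info = paste(cc, collapse = "/"))
  }
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-4)
})

test_that("cohort filter removes HWE deviants, ploidy violators and
           monomorphic REF- elements", {
  pairs <- mk_pairs(5, seed = 66)
  pairs$class <- c("REF_MINUS", "REF_MINUS", "REF_PLUS", "REF_MINUS",
                   "REF_MINUS")
  pairs$chrom <- c("chr1", "chr1", "chr1", "chr1", "chrY")
  inds <- paste0("I", 1:100)
  ploidy_map <- tibble::tibble(
    individual = inds,
    sex = rep(c("male", "female"), each = 50)
  )
  gts <- list(
    E1 = c(rep("AA", 25), rep("AB", 50), rep("BB", 25)),  # HWE-clean
    E2 = c(rep("AA", 50), rep("BB", 50)),                 # extreme deviation
    E3 = rep("AA", 100),                                  # monomorphic REF+
    E4 = rep("AA", 100),                                  # monomorphic REF-
    E5 = c(rep("A", 25), rep("B", 25), rep("AA", 50))     # diploid on female Y
  )
  calls <- purrr::map_dfr(names(gts), function(e) {
    tibble::tibble(element_id = e, individual = inds, genotype = gts[[e]],
                   ploidy = ifelse(gts[[e]] %in% c("A", "B"), 1L, 2L))
  })
  kept <- cohort_filter(calls, pairs, ploidy_map)
  rej <- pair_rejections(kept)
  expect_setequal(kept$element_id, c("E1", "E3"))
  expect_equal(rej$reason[rej$element_id == "E2"], "hwe_deviation")
  expect_equal(rej$reason[rej$element_id == "E4"], "monomorphic_ref_minus")
  expect_true("unexpected_ploidy" %in% rej$reason[rej$element_id == "E5"])

  # NC never counts as unexpected (the all-NC element is then dropped as
  # monomorphic instead, since no B allele remains)
  calls_nc <- calls
  calls_nc$genotype[calls_nc$element_id == "E5"] <- "NC"
  rej_nc <- pair_rejections(cohort_filter(calls_nc, pairs, ploidy_map))
  expect_false("unexpected_ploidy" %in%
                 rej_nc$reason[rej_nc$element_id == "E5"])

  expect_error(cohort_filter(calls, pairs, ploidy_map[1:10, ]),
               "ploidy map")
})
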