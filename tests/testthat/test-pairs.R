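test_that("REF- pairs follow the construction by definition", {
  set.seed(50)
  f <- aluscan:::random_dna(25)
  cand <- tibble::tibble(
    chrom = "chr1", pos = 1000L, strand = "+",
    flank25 = f, signature10 = "GGCCGGGCGC", ref_next10 = "TTTAACCGTA",
    support = 12L
  )
  pairs <- build_pairs(cand)
  expect_equal(pairs$kmerA, paste0(f, "TTTAACC"))
  expect_equal(pairs$kmerB, paste0(f, "GGCCGGG"))
  expect_equal(pairs$class, "REF_MINUS")
  # shared flank, length, distinctness
  expect_equal(substr(pairs$kmerA, 1, 25), substr(pairs$kmerB, 1, 25))
  expect_equal(nchar(pairs$kmerA), 32L)

  # degenerate pair: reference continuation equals the signature prefix
  cand$ref_next10 <- "GGCCGGGCGT"
  degen <- build_pairs(cand)
  expect_equal(nrow(degen), 0L)
  expect_equal(attr(degen, "dropped"), "RM_chr1_1000")
})

test_that("REF+ pairs slice the reference around both TSD copies", {
  set.seed(51)
  left <- aluscan:::random_dna(600)
  right <- aluscan:::random_dna(600)
  g <- c(chrP = ref_plus_locus(left, right, tsd = "GACTT", polya = 25))
  attr(g, "ref") <- "rp_pairs"
  cand <- suppressWarnings(discover_ref_plus(g))
  expect_equal(nrow(cand), 1L)
  pairs <- build_pairs(cand, g)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$class, "REF_PLUS")
  s <- g[[1]]
  # manual slicing: flank ends with TSD copy 1; A continues into the
  # element (signature), B continues after TSD copy 2
  expect_equal(pairs$kmerA,
               paste0(substr(s, cand$start - 25, cand$start - 1),
                      substr(s, cand$start, cand$start + 6)))
  expect_equal(pairs$kmerB,
               paste0(substr(s, cand$start - 25, cand$start - 1),
                      substr(s, cand$end + 1, cand$end + 7)))
  expect_true(startsWith(substr(pairs$kmerA, 26, 32), "GGCCGGG"))

  # a minus-strand element yields the same pair sequences on the element
  # strand
  grc <- c(chrP = revcomp(g[[1]]))
  attr(grc, "ref") <- "rp_pairs_rc"
  cand_rc <- suppressWarnings(discover_ref_plus(grc))
  expect_equal(cand_rc$strand, "-")
  pairs_rc <- build_pairs(cand_rc, grc)
  expect_equal(pairs_rc$kmerA, pairs$kmerA)
  expect_equal(pairs_rc$kmerB, pairs$kmerB)
})

test_that("pair filters remove duplicates, close, GC-rich, repeated", {
  g <- test_genome(60000, seed = 53, name = "chrF")
  idx <- build_kmer_index(g)
  pl <- plant_insertions(g, n = 6, seed = 54)
  rd <- simulate_reads(pl, coverage = 40, error_rate = 0, seed = 55)
  pairs <- build_pairs(discover_ref_minus(rd, g, index = idx))
  expect_equal(nrow(pairs), 6L)

  # (a) duplicate kmerB across two pairs: both removed
  p_dup <- pairs
  p_dup$kmerB[2] <- p_dup$kmerB[1]
  kept <- filter_pairs(p_dup, g)
  rej <- pair_rejections(kept)
  expect_true(all(p_dup$element_id[1:2] %in%
                    rej$element_id[rej$reason == "duplicate_kmer"]))

  # (b) two breakpoints 10 bp apart: both removed
  p_close <- pairs
  p_close$pos[2] <- p_close$pos[1] + 10L
  keptc <- filter_pairs(p_close, g)
  rejc <- pair_rejections(keptc)
  expect_true(all(p_close$element_id[1:2] %in%
                    rejc$element_id[rejc$reason == "closely_located"]))
  # exactly min_distance apart: kept
  p_edge <- pairs
  p_edge$pos[2] <- p_edge$pos[1] + 32L
  expect_false(any(pair_rejections(filter_pairs(p_edge, g))$reason ==
                     "closely_located"))

  # (c) GC = 1.0 k-mer with gc_max 0.8: removed
  p_gc <- pairs
  p_gc$kmerB[3] <- strrep("GC", 16)
  rejg <- pair_rejections(filter_pairs(p_gc, g))
  expect_true(p_gc$element_id[3] %in%
                rejg$element_id[rejg$reason == "gc_rich"])

  # (d) clean planted pairs pass every filter
  clean <- filter_pairs(pairs, g)
  expect_equal(nrow(clean), 6L)
  expect_equal(nrow(pair_rejections(clean)), 0L)
})

test_that("kept pairs have kmerA unique and kmerB absent (brute force)", {
  g <- test_genome(40000, seed = 57, name = "chrB")
  idx <- build_kmer_index(g)
  pl <- plant_insertions(g, n = 4, seed = 58)
  rd <- simulate_reads(pl, coverage = 40, error_rate = 0, seed = 59)
  kept <- filter_pairs(build_pairs(discover_ref_minus(rd, g, index = idx)), g)
  expect_gt(nrow(kept), 0L)
  for (i in seq_len(nrow(kept))) {
    expect_equal(nrow(brute_locate(g, kept$kmerA[i])), 1L)
    expect_equal(nrow(brute_locate(g, kept$kmerB[i])), 0L)
  }
})

test_that("filtering is order-independent (a set property)", {
  g <- test_genome(60000, seed = 53, name = "chrF")
  pl <- plant_insertions(g, n = 6, seed = 54)
  rd <- simulate_reads(pl, coverage = 40, error_rate = 0, seed = 55)
  pairs <- build_pairs(discover_ref_minus(rd, g))
  pairs$kmerB[2] <- pairs$kmerB[1]       # inject a duplicate
  pairs$pos[5] <- pairs$pos[4] + 5L      # and a close pair
  for (perm in list(1:6, 6:1, c(3, 1, 6, 2, 5, 4))) {
    kept <- filter_pairs(pairs[perm, ], g)
    expect_setequal(kept$element_id,
                    filter_pairs(pairs, g)$element_id)
  }
})

test_that("merge is identity, idempotent, additive, and ref-checked", {
  g <- test_genome(60000, seed = 53, name = "chrF")
  pl <- plant_insertions(g, n = 6, seed = 54)
  rd <- simulate_reads(pl, coverage = 40, error_rate = 0, seed = 55)
  x <- build_pairs(discover_ref_minus(rd, g))
  empty <- x[0, ]

  expect_equal(as.data.frame(merge_pair_databases(x, empty)),
               as.data.frame(x))
  expect_equal(as.data.frame(merge_pair_databases(x, x)),
               as.data.frame(x))

  y <- x
  y$class <- "REF_PLUS"
  y$element_id <- sub("RM", "RP", y$element_id)
  y$pos <- y$pos + 10000L
  expect_equal(nrow(merge_pair_databases(x, y)), nrow(x) + nrow(y))

  z <- x
  attr(z, "ref") <- "other_build"
  expect_error(merge_pair_databases(x, z), "conflicting")
})
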