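test_that("scan_reference reports genomic signature hits with strands", {
  set.seed(3)
  sig <- "GGCCGGGCGC"
  g <- c(chr1 = paste0(aluscan:::random_dna(500), sig,
                       aluscan:::random_dna(500), revcomp(sig),
                       aluscan:::random_dna(500), sig,
                       aluscan:::random_dna(500)))
  hits <- scan_reference(g)
  planted <- hits[hits$pos %in% c(501L, 1011L, 1521L), ]
  expect_equal(nrow(planted), 3L)
  expect_equal(planted$strand[planted$pos == 1011L], "-")
  expect_setequal(planted$strand[planted$pos != 1011L], "+")

  # pure-N chromosome: no hits
  expect_equal(nrow(scan_reference(c(chrN = strrep("N", 5000)))), 0L)
})

test_that("scan_reference equals the brute-force Hamming scan", {
  g <- test_genome(20000, seed = 33)
  got <- scan_reference(g)[, c("pos", "strand")]
  want <- brute_sig_hits(g[[1]])
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("find_tsd honours the inclusive distance window", {
  set.seed(35)
  left <- aluscan:::random_dna(600)
  tsd <- "ACTGA"
  sig <- "GGCCGGGCGC"
  body <- function(d) paste0(sig, aluscan:::random_dna(d - 10))
  mk <- function(d) {
    c(chrP = paste0(left, tsd, body(d), tsd, aluscan:::random_dna(600)))
  }
  s <- 606L  # signature start: left(600) + tsd(5) + 1

  for (d in c(270L, 300L, 350L)) {
    cand <- find_tsd(mk(d), "chrP", s, "+")
    expect_false(is.null(cand), info = paste("d =", d))
    expect_equal(cand$tsd_dist, d)
    expect_equal(cand$start, s)
    expect_true(grepl(tsd, cand$tsd, fixed = TRUE))
    expect_gte(cand$tsd_len, 5L)
  }
  # one outside either boundary: no candidate
  expect_null(find_tsd(mk(269L), "chrP", s, "+"))
  expect_null(find_tsd(mk(351L), "chrP", s, "+"))
})

test_that("find_tsd handles minus-strand hits and polyA-adjacent TSDs", {
  set.seed(36)
  left <- aluscan:::random_dna(600)
  right <- aluscan:::random_dna(600)
  locus <- ref_plus_locus(left, right, tsd = "CATTG", polya = 20)
  g <- c(chrP = locus)
  s_plus <- 606L
  plus <- find_tsd(g, "chrP", s_plus, "+")
  expect_false(is.null(plus))

  # the same locus reverse-complemented: hit on the minus strand
  grc <- c(chrP = revcomp(locus))
  L <- nchar(locus)
  pos_rc <- L - (s_plus + 9L) + 1L  # leftmost base of the rc'd signature
  minus <- find_tsd(grc, "chrP", pos_rc, "-")
  expect_false(is.null(minus))
  expect_equal(minus$tsd_dist, plus$tsd_dist)
  expect_equal(minus$tsd, plus$tsd)
  expect_equal(minus$start, L - plus$end + 1L)
  expect_equal(minus$end, L - plus$start + 1L)

  # polyA-adjacent TSD: extension stays exact and still reports >= 5
  locus2 <- ref_plus_locus(left, right, tsd = "AAAAA", polya = 20)
  cand2 <- find_tsd(c(chrP = locus2), "chrP", 606L, "+")
  expect_false(is.null(cand2))
  expect_gte(cand2$tsd_len, 5L)
  expect_true(grepl("AAAAA", cand2$tsd, fixed = TRUE))
})

test_that("homology bits match the Karlin-Altschul conversion and a DP oracle", {
  alu <- alu_seq1()
  self <- score_homology(alu)
  expect_equal(self$score, nchar(alu))
  expect_equal(self$bits, (1.28 * nchar(alu) - log(0.46)) / log(2))
  expect_gt(self$bits, 100)

  # random sequences score far below the retention threshold
  set.seed(40)
  rand <- replicate(20, aluscan:::random_dna(300))
  expect_true(all(score_homology(rand)$bits < 100))

  # 20% diverged copies stay above it
  div <- vapply(1:5, function(i) aluscan:::mutate_seq(alu, 0.2), "")
  expect_true(all(score_homology(div)$bits > 100))

  # raw scores equal an independent affine-gap DP on short sequences
  for (i in 1:6) {
    a <- aluscan:::random_dna(45)
    b <- if (i %% 2) aluscan:::random_dna(45) else
      paste0(substr(a, 6, 30), aluscan:::random_dna(15))
    expect_equal(score_homology(a, library = c(ref = b))$score,
                 sw_local_score(a, b), info = i)
  }
  expect_error(score_homology("ACGT", library = character(0)), "empty")
})

test_that("outgroup junction lookup behaves at both extremes", {
  set.seed(44)
  g <- c(chrP = ref_plus_locus(aluscan:::random_dna(600),
                               aluscan:::random_dna(600)))
  attr(g, "ref") <- "ogfix"
  cand <- suppressWarnings(discover_ref_plus(g))
  expect_equal(nrow(cand), 1L)
  expect_true(is.na(cand$outgroup_absent))

  junction <- paste0(substring(g[[1]], cand$start - 25, cand$start - 1),
                     substring(g[[1]], cand$start, cand$start + 6))
  # outgroup = the reference itself: junction present, candidate fails
  expect_false(outgroup_absent(junction, g))
  expect_false(outgroup_absent(revcomp(junction), g))
  # outgroup with the element deleted: junction absent, candidate passes
  og <- c(chrP = paste0(substring(g[[1]], 1, cand$start - 1),
                        substring(g[[1]], cand$end + 1, nchar(g[[1]]))))
  expect_true(outgroup_absent(junction, og))
  expect_warning(outgroup_absent(junction, NULL), "outgroup")

  withme <- discover_ref_plus(g, outgroup = g)
  expect_equal(nrow(withme), 0L)
  without <- discover_ref_plus(g, outgroup = og)
  expect_equal(nrow(without), 1L)
  expect_true(without$outgroup_absent)
})

test_that("the REF+ cascade returns planted elements and rejects decoys", {
  set.seed(47)
  sig <- "GGCCGGGCGC"
  pieces <- character()
  starts <- integer()
  cursor <- 0L
  add <- function(piece) {
    pieces[[length(pieces) + 1L]] <<- piece
    cursor <<- cursor + nchar(piece)
  }
  # three full elements with TSDs (P = 3), two signature decoys without
  for (i in 1:3) {
    add(aluscan:::random_dna(800))
    tsd <- aluscan:::random_dna(6)
    starts <- c(starts, cursor + nchar(tsd) + 1L)
    add(paste0(tsd, alu_seq1(), strrep("A", 10 + 5 * i), tsd))
  }
  for (i in 1:2) {
    add(aluscan:::random_dna(700))
    add(sig)  # bare signature, no element body, no TSD
  }
  add(aluscan:::random_dna(800))
  g <- c(chrQ = paste(pieces, collapse = ""))
  attr(g, "ref") <- "cascade_fix"

  cand <- suppressWarnings(discover_ref_plus(g))
  expect_equal(nrow(cand), 3L)
  expect_equal(cand$start, starts)
  expect_true(all(cand$tsd_len >= 5L))
  expect_true(all(cand$homology_bits > 100))
  cs <- cascade(cand)
  expect_true(all(diff(cs$n) <= 0))  # monotone cascade
  expect_gte(cs$n[1], 5L)            # decoys seen at the scan stage
})
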