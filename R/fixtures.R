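# Deterministic fixture generators used by the test suite, the vignette and
# the quickstart. Everything is generated programmatically; nothing large is
# shipped.

#' Generate a deterministic test fixture
#'
#' Builds small documented genomes (and, for `full_demo`, a complete planted
#' simulation) used throughout the test suite and the documentation:
#' \describe{
#'   \item{toy_genome}{one 100 kb random chromosome (`chrT`).}
#'   \item{duplication}{a 60 kb chromosome whose 10-20 kb block is repeated
#'     exactly at 40-50 kb, so 25-mers inside it are never reference-unique.}
#'   \item{n_region}{an 80 kb chromosome with three N runs (1 kb at 20 kb,
#'     500 bp at 45 kb, 2 kb at 65 kb).}
#'   \item{full_demo}{a 120 kb genome with 12 planted heterozygous
#'     insertions and 30x error-free reads; returns genome, planted object,
#'     truth and reads.}
#' }
#' When `dir` is given, FASTA/FASTQ/TSV files are also written there.
#'
#' @param kind One of `"toy_genome"`, `"duplication"`, `"n_region"`,
#'   `"full_demo"`.
#' @param seed RNG seed (fixtures are byte-identical for equal seeds).
#' @param dir Optional output directory.
#' @return A list with at least `genome`; `full_demo` adds `planted`,
#'   `truth` and `reads`. The output directory (if any) is in `$dir`.
#' @export
make_fixture <- function(kind = c("toy_genome", "duplication", "n_region",
                                  "full_demo"),
                         seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  out <- switch(
    kind,
    toy_genome = {
      g <- c(chrT = random_dna(1e5))
      attr(g, "ref") <- paste0("toy_genome_seed", seed)
      list(genome = g)
    },
    duplication = {
      base <- random_dna(6e4)
      block <- substr(base, 10001L, 20000L)
      g <- c(chrD = paste0(
        substr(base, 1L, 40000L), block, substr(base, 50001L, 60000L)
      ))
      attr(g, "ref") <- paste0("duplication_seed", seed)
      list(genome = g)
    },
    n_region = {
      base <- random_dna(8e4)
      s <- base
      substr(s, 20001L, 21000L) <- strrep("N", 1000L)
      substr(s, 45001L, 45500L) <- strrep("N", 500L)
      substr(s, 65001L, 67000L) <- strrep("N", 2000L)
      g <- c(chrN = s)
      attr(g, "ref") <- paste0("n_region_seed", seed)
      list(genome = g)
    },
    full_demo = {
      g <- c(chrT = random_dna(12e4))
      attr(g, "ref") <- paste0("full_demo_seed", seed)
      planted <- plant_insertions(g, n = 12L, mutation_rate = 0,
                                  seed = seed + 1L)
      reads <- simulate_reads(planted, coverage = 30, error_rate = 0,
                              seed = seed + 2L)
      list(genome = g, planted = planted, truth = planted$truth,
           reads = reads)
    }
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$genome, file.path(dir, "ref.fa"))
    if (!is.null(out$reads)) {
      write_fastq(setNames(out$reads$mate1, out$reads$read_id),
                  file.path(dir, "reads_1.fq"))
      write_fastq(setNames(out$reads$mate2, out$reads$read_id),
                  file.path(dir, "reads_2.fq"))
      readr::write_tsv(out$truth, file.path(dir, "truth.tsv"))
    }
    out$dir <- dir
  }
  out
}
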