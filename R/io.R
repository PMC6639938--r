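#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; record names are trimmed to the first
#' whitespace-delimited token. Duplicate record names are an error. Gzipped
#' input is handled transparently.
#'
#' @param path Path to a FASTA (optionally `.gz`) file.
#' @return Named character vector of sequences, with attribute `ref` set to
#'   the file's basename (used as the reference build tag in output headers).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA record name: %s", nm[duplicated(nm)][1L]))
  }
  out <- setNames(toupper(as.character(ss)), nm)
  attr(out, "ref") <- sub("\\.(fa|fasta)(\\.gz)?$", "", basename(path))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(as.list(genome)))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' Reads a FASTQ (optionally gzipped) file and returns the read sequences
#' uppercased. The four-line record structure is validated (header and
#' separator markers, sequence/quality length agreement, no truncation);
#' structural problems are reported with the 1-based index of the offending
#' record. Validation is done here because the Bioconductor FASTQ readers
#' accept quality strings of the wrong length silently.
#'
#' @param path Path to a FASTQ file.
#' @return Character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  n_rec <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ record %d in %s (truncated)",
                  n_rec + 1L, path))
  }
  if (n_rec == 0L) return(setNames(character(), character()))
  i0 <- (seq_len(n_rec) - 1L) * 4L
  hdr <- lines[i0 + 1L]
  seqs <- lines[i0 + 2L]
  sep <- lines[i0 + 3L]
  qual <- lines[i0 + 4L]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ record %d in %s", bad[1L], path))
  }
  setNames(toupper(seqs), sub("\\s.*$", "", sub("^@", "", hdr)))
}

#' Write reads to FASTQ
#'
#' Constant quality (`I`, Phred 40) is written, as the package never consumes
#' base qualities. A `.gz` suffix triggers gzip compression.
#'
#' @param reads Character vector of read sequences (names used as read ids;
#'   unnamed reads get `read<i>`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  ids[!nzchar(ids)] <- paste0("read", which(!nzchar(ids)))
  qual <- strrep("I", nchar(reads))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read query sequences from a BAM/SAM file
#'
#' The method is alignment-free: alignments are ignored and the BAM is used
#' purely as a read container. Secondary and supplementary records are
#' skipped to avoid double counting. SAM input is converted on the fly.
#'
#' @param path Path to a BAM or SAM file.
#' @return Character vector of read sequences.
#' @export
read_bam_reads <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "seq")
  res <- Rsamtools::scanBam(path, param = param)[[1L]]$seq
  toupper(as.character(res))
}

# Coerce the many accepted read inputs to one character vector of sequences:
# a character vector of sequences, FASTQ/BAM/SAM paths, or a read-pair tibble
# from simulate_reads().
as_reads <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("mate1", "mate2") %in% names(x)))
    return(c(x$mate1, x$mate2))
  }
  if (!is.character(x)) abort("reads must be sequences, file paths or a read tibble")
  looks_path <- grepl("\\.(fq|fastq)(\\.gz)?$|\\.(bam|sam)$", x,
                      ignore.case = TRUE)
  if (any(looks_path)) {
    if (!all(looks_path)) abort("cannot mix raw sequences and file paths")
    return(unlist(lapply(x, function(p) {
      if (grepl("\\.(bam|sam)$", p, ignore.case = TRUE)) read_bam_reads(p)
      else read_fastq(p)
    }), use.names = FALSE))
  }
  toupper(x)
}

# Coerce genome inputs (named character / DNAStringSet / FASTA path) to a
# named character vector with a `ref` tag attribute.
as_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    return(read_fasta(x))
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- setNames(toupper(as.character(x)), names(x))
    attr(out, "ref") <- attr(x, "ref") %||% "unnamed"
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) abort("genome character vector must be named by chromosome")
    out <- toupper(x)
    attr(out, "ref") <- attr(x, "ref", exact = TRUE) %||% "unnamed"
    return(out)
  }
  abort("cannot interpret `genome`: expected named character, DNAStringSet or FASTA path")
}

ref_tag <- function(genome) attr(genome, "ref", exact = TRUE) %||% "unnamed"

## ---- versioned TSV interchange --------------------------------------------

write_tsv_headed <- function(df, path, headers) {
  lines <- c(headers, paste(names(df), collapse = "\t"))
  writeLines(lines, path)
  readr::write_tsv(df, path, append = TRUE, col_names = FALSE, progress = FALSE)
  invisible(path)
}

read_tsv_headed <- function(path, col_types) {
  all_lines <- readLines(path, n = 50L)
  headers <- grep("^#", all_lines, value = TRUE)
  meta <- list()
  for (h in headers) {
    kv <- stringr::str_match(h, "^#([A-Za-z0-9_.]+)=(.*)$")
    if (!is.na(kv[1, 1])) meta[[kv[1, 2]]] <- kv[1, 3]
  }
  df <- readr::read_tsv(path, comment = "#", col_types = col_types,
                        progress = FALSE)
  attr(df, "meta") <- meta
  df
}

std_headers <- function(type, ref, extra = character()) {
  c(sprintf("#aluscan=%s", as.character(packageVersion("aluscan"))),
    sprintf("#type=%s", type),
    sprintf("#ref=%s", ref),
    extra)
}

#' Write and read discovery candidate tables
#'
#' Candidates are written as versioned TSV with `#` header lines carrying the
#' tool version, the table type (`ref_minus` / `ref_plus`) and the reference
#' tag. All coordinates are 1-based inclusive. `read_candidates()` restores
#' the class and reference tag, so `read_candidates(write_candidates(x))`
#' round-trips.
#'
#' @param x Candidate tibble from [discover_ref_minus()] or
#'   [discover_ref_plus()].
#' @param path File path.
#' @return `write_candidates()` returns `path` invisibly; `read_candidates()`
#'   returns the candidate tibble.
#' @export
write_candidates <- function(x, path) {
  type <- if ("flank25" %in% names(x)) "ref_minus" else "ref_plus"
  if (type == "ref_minus") {
    stopifnot(all(nchar(x$flank25) == 25), all(nchar(x$signature10) == 10))
    if (any(x$ref_next10 == x$signature10)) {
      abort("invalid REF- candidate: ref_next10 equals signature10")
    }
  }
  write_tsv_headed(as_tibble(x), path,
                   std_headers(type, attr(x, "ref") %||% "unnamed"))
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- read_tsv_headed(path, readr::cols(
    chrom = readr::col_character(), strand = readr::col_character(),
    .default = readr::col_guess()
  ))
  meta <- attr(df, "meta")
  out <- as_tibble(df)
  attr(out, "meta") <- NULL
  for (col in intersect(c("pos", "support", "start", "end", "tsd_len"),
                        names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  attr(out, "ref") <- meta$ref
  class(out) <- c(paste0("alu_", meta$type %||% "candidates"), class(out))
  out
}
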