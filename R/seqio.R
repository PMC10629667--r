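#' Read a FASTQ file into a read set
#'
#' Parses canonical 4-line FASTQ records (optionally gzip-compressed) into a
#' `read_set`: a data frame with one row per read and columns `id` (token
#' before the first whitespace of the `@` line), `seq` (uppercased bases) and
#' `qual`. Additional columns added downstream (truth tags from the
#' simulator, stranding flags) travel with the reads.
#'
#' @param path Path to a FASTQ file, plain or `.gz`.
#' @return A `read_set` data frame with columns `id`, `seq`, `qual`.
#' @details Sequences are uppercased on ingest; characters outside
#'   `A`,`C`,`G`,`T`,`N` are rejected, as all downstream primer matching is
#'   defined on the 5-letter DNA alphabet. Malformed records (missing `@` or
#'   `+` framing, quality/sequence length mismatch, truncated final record)
#'   raise an error naming the offending line.
#' @seealso [write_fastq()], [dedup_by_id()], [reverse_complement_reads()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)  # readLines transparently decompresses .gz
  n <- length(lines)
  if (n == 0L) return(read_set(character(), character(), character()))
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record starting at line ", (n %/% 4L) * 4L + 1L,
         " in ", path)
  }
  at <- seq(1L, n, by = 4L)
  hdr <- lines[at]
  seqs <- lines[at + 1L]
  plus <- lines[at + 2L]
  qual <- lines[at + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("line ", at[bad[1L]], ": expected '@' record header in ", path)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("line ", at[bad[1L]] + 2L, ": expected '+' separator in ", path)
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop("line ", at[bad[1L]] + 3L,
         ": quality length differs from sequence length in ", path)
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  read_set(ids, toupper(seqs), qual)
}

#' Construct a read set
#'
#' @param id,seq,qual Equal-length character vectors. `qual` may be `NA` for
#'   reads without qualities.
#' @param ... Further equal-length vectors kept as tag columns.
#' @return A `read_set` data frame.
#' @export
read_set <- function(id, seq, qual = NA_character_, ...) {
  seq <- toupper(seq)
  if (length(seq) && any(grepl("[^ACGTN]", seq))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  ok <- is.na(qual) | nchar(qual) == nchar(seq)
  if (!all(ok)) {
    stop("qualities differ in length from sequences for read(s): ",
         paste(utils::head(id[!ok], 3L), collapse = ", "))
  }
  df <- data.frame(id = as.character(id), seq = seq,
                   qual = as.character(qual), ...,
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

#' Write a read set as FASTQ
#'
#' Emits canonical 4-line records in input order. Reads lacking qualities get
#' a constant fill quality so that output is deterministic.
#'
#' @param reads A `read_set`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param fill_qual Single character used to fill missing qualities
#'   (default `"I"`).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, fill_qual = "I") {
  stopifnot(is.character(fill_qual), nchar(fill_qual) == 1L)
  qual <- reads$qual
  miss <- is.na(qual)
  if (any(miss)) {
    qual[miss] <- vapply(nchar(reads$seq[miss]), function(n)
      strrep(fill_qual, n), "")
  }
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    at <- seq(1L, length(out), by = 4L)
    out[at] <- paste0("@", reads$id)
    out[at + 1L] <- reads$seq
    out[at + 2L] <- "+"
    out[at + 3L] <- qual
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Watson-Crick reverse complement over `{A,C,G,T,N}` (`N` maps to `N`).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Reverse complement every read in a set
#'
#' Sequences are reverse-complemented, qualities reversed, ids preserved. A
#' logical `flipped` column records the orientation flip (toggled if already
#' present), so truth tags stay interpretable after re-orientation.
#'
#' @param reads A `read_set`.
#' @return The re-oriented `read_set`.
#' @export
reverse_complement_reads <- function(reads) {
  reads$seq <- revcomp(reads$seq)
  has_q <- !is.na(reads$qual)
  if (any(has_q)) {
    reads$qual[has_q] <- as.character(
      Biostrings::reverse(Biostrings::BStringSet(reads$qual[has_q])))
  }
  if (is.null(reads$flipped)) {
    reads$flipped <- rep(TRUE, nrow(reads))
  } else {
    reads$flipped <- !reads$flipped
  }
  reads
}

#' Deduplicate reads by identifier
#'
#' Keeps the first occurrence of every id, preserving order. First-wins
#' survivorship mirrors the branch order of the stranding pipeline, where a
#' read collected by an earlier criterion must not be re-emitted by a later
#' one.
#'
#' @param reads A `read_set`.
#' @return A `read_set` with pairwise-distinct ids.
#' @export
dedup_by_id <- function(reads) {
  reads[!duplicated(reads$id), , drop = FALSE]
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}
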