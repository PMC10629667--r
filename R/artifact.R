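#' Screen a read for the terminal primer-1 pair
#'
#' The hallmark of the reverse-transcriptase template-switch artifact: primer
#' 1 within the head window AND the reverse complement of primer 1 within the
#' tail window of the same read, a configuration that library chemistry
#' cannot produce from an intact template. Each end is matched within
#' `config$max_mismatch`.
#'
#' @param reads A `read_set` (any number of reads).
#' @param config A [primer_config()].
#' @return Logical vector, one element per read.
#' @export
detect_terminal_primer_pair <- function(reads, config = primer_config()) {
  head_hit <- terminal_match_table(reads$seq, config$p1, "head",
                                   config$window, config$max_mismatch,
                                   config$metric)$hit
  tail_hit <- terminal_match_table(reads$seq, revcomp(config$p1), "tail",
                                   config$window, config$max_mismatch,
                                   config$metric)$hit
  head_hit & tail_hit
}

# 5-letter scoring matrix: match +1 on A/C/G/T, everything else (including
# N-N) -1, so ambiguous bases never count as self-complementary.
.fold_submat <- function(match = 1, mismatch = -1) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m)[1:4] <- match
  m
}

#' Self-complementarity fold of a read
#'
#' Palindrome proxy: the first half of the sequence is globally aligned
#' against the reverse complement of the second half (match +1, mismatch -1,
#' gap -2); every aligned match column pairs base `i` of the first half with
#' the corresponding base near the mirror position of the second half,
#' emitting `(` and `)`; all other positions are `.`. A read formed by a
#' sequence followed by its own reverse complement pairs fully; unrelated
#' halves pair only as well as a random alignment allows. The construction
#' guarantees a balanced, nested (pseudoknot-free) structure. For odd
#' lengths the middle base is unpaired.
#'
#' @param sequence A DNA string of length at least 2.
#' @param match,mismatch,gap Alignment scores (gap is per gapped position).
#' @return A `dot_bracket` string over `(`, `)`, `.` of the same length as
#'   `sequence`.
#' @seealso [paired_fraction()], [mountain_profile()]
#' @export
self_fold <- function(sequence, match = 1, mismatch = -1, gap = -2) {
  n <- nchar(sequence)
  stopifnot(n >= 2L)
  h <- n %/% 2L
  first <- substr(sequence, 1L, h)
  second <- substr(sequence, h + 1L, n)
  aln <- Biostrings::pairwiseAlignment(
    first, revcomp(second), type = "global",
    substitutionMatrix = .fold_submat(match, mismatch),
    gapOpening = 0, gapExtension = abs(gap))
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  struct <- rep(".", n)
  i <- 0L  # position in first half
  j <- 0L  # position in rc(second half); maps to read position n + 1 - j
  for (k in seq_along(p)) {
    if (p[k] != "-") i <- i + 1L
    if (s[k] != "-") j <- j + 1L
    if (p[k] != "-" && s[k] != "-" && p[k] == s[k] && p[k] != "N" &&
        i < n + 1L - j) {
      struct[i] <- "("
      struct[n + 1L - j] <- ")"
    }
  }
  structure(paste(struct, collapse = ""), class = "dot_bracket")
}

#' Fraction of paired bases in a dot-bracket structure
#'
#' @param structure A dot-bracket string.
#' @return `(count("(") + count(")")) / nchar(structure)`.
#' @export
paired_fraction <- function(structure) {
  ch <- strsplit(unclass(structure), "")[[1L]]
  if (!length(ch)) return(0)
  mean(ch != ".")
}

#' Mountain profile of a dot-bracket structure
#'
#' Each base scores +1 if paired downstream (`(`), -1 if paired upstream
#' (`)`), 0 if unpaired; the cumulative sum over positions is the mountain,
#' which starts and ends at 0 for a balanced structure and peaks where
#' pairing is deepest. The mountain is rescaled to `bins` values by averaging
#' within equal-width position bins, so reads of different lengths are
#' comparable on one meta-transcript axis.
#'
#' @param structure A dot-bracket string.
#' @param bins Number of output bins (default 100).
#' @return Numeric vector of length `bins`.
#' @export
mountain_profile <- function(structure, bins = 100L) {
  ch <- strsplit(unclass(structure), "")[[1L]]
  score <- ifelse(ch == "(", 1L, ifelse(ch == ")", -1L, 0L))
  mountain <- cumsum(score)
  n <- length(mountain)
  if (n >= bins) {
    idx <- floor((seq_len(n) - 1L) * bins / n) + 1L
    as.numeric(tapply(mountain, idx, mean))
  } else {
    # short structures: sample the mountain at interpolated positions
    stats::approx(x = seq_len(n) / n, y = mountain,
                  xout = (seq_len(bins) - 0.5) / bins, rule = 2)$y
  }
}

#' Assess one read for the palindrome artifact
#'
#' Combines the terminal primer-pair screen, the self-complementarity fold,
#' the paired-base fraction and the mountain profile. A read is called an
#' artifact when it carries the terminal primer pair AND its paired fraction
#' reaches `threshold`.
#'
#' @param read A single-row `read_set` (or a list with `id` and `seq`).
#' @param config A [primer_config()].
#' @param threshold Paired-fraction cutoff (default 0.7, calibrated against
#'   the random-read null of the simulator; see the package vignette).
#' @return A list with `read_id`, `terminal_primer_pair`, `paired_fraction`,
#'   `mountain_scaled` (100 values) and `is_artifact`.
#' @export
assess_palindrome <- function(read, config = primer_config(),
                              threshold = 0.7) {
  stopifnot(length(read$id) == 1L)
  pair <- detect_terminal_primer_pair(read, config)
  db <- self_fold(read$seq)
  pf <- paired_fraction(db)
  list(read_id = read$id,
       terminal_primer_pair = pair,
       paired_fraction = pf,
       mountain_scaled = mountain_profile(db, 100L),
       is_artifact = pair && pf >= threshold)
}

#' Scan a library for palindrome artifacts
#'
#' Vectorised artifact screen. Every read passes the terminal primer-pair
#' screen; the fold (the expensive step) is computed for all reads or, by
#' default, only for reads carrying the terminal primer pair — the
#' short-circuit cannot change any `is_artifact` call because an artifact
#' requires both lines of evidence.
#'
#' @param reads A `read_set`.
#' @param config A [primer_config()].
#' @param threshold Paired-fraction cutoff.
#' @param fold `"candidates"` (default) folds only terminal-pair reads,
#'   leaving `paired_fraction` `NA` elsewhere; `"all"` folds every read.
#' @return A list of class `artifact_scan` with `report` (data frame:
#'   `read_id`, `terminal_primer_pair`, `paired_fraction`, `is_artifact`)
#'   and `prevalence` (fraction of reads called artifact).
#' @export
scan_artifacts <- function(reads, config = primer_config(), threshold = 0.7,
                           fold = c("candidates", "all")) {
  fold <- match.arg(fold)
  pair <- detect_terminal_primer_pair(reads, config)
  pf <- rep(NA_real_, nrow(reads))
  todo <- if (fold == "all") seq_len(nrow(reads)) else which(pair)
  for (i in todo) pf[i] <- paired_fraction(self_fold(reads$seq[i]))
  is_art <- pair & !is.na(pf) & pf >= threshold
  report <- data.frame(read_id = reads$id, terminal_primer_pair = pair,
                       paired_fraction = pf, is_artifact = is_art,
                       stringsAsFactors = FALSE)
  structure(list(report = report,
                 prevalence = if (nrow(reads)) mean(is_art) else 0,
                 threshold = threshold),
            class = "artifact_scan")
}

#' @export
print.artifact_scan <- function(x, ...) {
  cat("palindrome artifact scan\n")
  cat(sprintf("  reads:            %d\n", nrow(x$report)))
  cat(sprintf("  terminal pairs:   %d\n", sum(x$report$terminal_primer_pair)))
  cat(sprintf("  artifacts called: %d (%.2f%%) at paired fraction >= %.2f\n",
              sum(x$report$is_artifact), 100 * x$prevalence, x$threshold))
  invisible(x)
}
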