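#' Primer configuration for terminal matching
#'
#' Holds the kit primer sequences and the terminal-search parameters used by
#' the stranding and artifact-detection methods. Defaults are the direct-cDNA
#' kit values: primer 1 (first-strand, polyT-ended) `GCTCTATCTTCTTT`, primer 2
#' (strand-switch, GGG-ended) `CTGATATTGCTGGG`, a 100 bp terminal window, a
#' 2-mismatch budget, and the 3-criteria search (primer 1 at the head, reverse
#' complement of primer 2 at the tail, primer 2 at the head) that balances
#' stranding yield against correctness.
#'
#' @param p1,p2 Primer sequences over `{A,C,G,T}`. Their reverse complements
#'   are always derived, never stored.
#' @param window Terminal window length in bases searched at each read end.
#' @param max_mismatch Mismatch (or edit) budget for a primer hit.
#' @param criteria Character subset of `"P1_HEAD"`, `"RC_P2_TAIL"`,
#'   `"P2_HEAD"`, `"RC_P1_TAIL"`, in precedence order.
#' @param metric `"edit"` (default) scores substitutions, insertions and
#'   deletions, each costing 1; `"hamming"` permits substitutions only.
#'   Nanopore errors are indel-rich, so the edit metric is the default: with
#'   a Hamming scan a single indel inside the 14-mer primer region defeats
#'   the match, and at realistic indel rates roughly a third of true primer
#'   occurrences would be missed.
#' @return A `primer_config` object.
#' @examples
#' cfg <- primer_config()
#' find_terminal_match("GCTCTATCTTCTTTACGTACGTACGT", cfg$p1, "head",
#'                     cfg$window, cfg$max_mismatch)
#' @export
primer_config <- function(p1 = "GCTCTATCTTCTTT",
                          p2 = "CTGATATTGCTGGG",
                          window = 100L,
                          max_mismatch = 2L,
                          criteria = c("P1_HEAD", "RC_P2_TAIL", "P2_HEAD"),
                          metric = c("edit", "hamming")) {
  metric <- match.arg(metric)
  p1 <- toupper(p1); p2 <- toupper(p2)
  if (!nzchar(p1) || !nzchar(p2) || grepl("[^ACGT]", paste0(p1, p2))) {
    stop("primers must be non-empty strings over {A,C,G,T}")
  }
  window <- as.integer(window)
  max_mismatch <- as.integer(max_mismatch)
  if (window < max(nchar(p1), nchar(p2))) {
    stop("window must be at least as long as the longest primer")
  }
  if (max_mismatch < 0L || max_mismatch >= min(nchar(p1), nchar(p2))) {
    stop("max_mismatch must be in [0, min primer length)")
  }
  all_crit <- c("P1_HEAD", "RC_P2_TAIL", "P2_HEAD", "RC_P1_TAIL")
  criteria <- match.arg(criteria, all_crit, several.ok = TRUE)
  structure(list(p1 = p1, p2 = p2, window = window,
                 max_mismatch = max_mismatch, criteria = criteria,
                 metric = metric),
            class = "primer_config")
}

#' @export
print.primer_config <- function(x, ...) {
  cat("primer_config\n")
  cat("  primer 1:", x$p1, " primer 2:", x$p2, "\n")
  cat("  window:", x$window, "bp  max mismatch:", x$max_mismatch,
      " metric:", x$metric, "\n")
  cat("  criteria:", paste(x$criteria, collapse = " > "), "\n")
  invisible(x)
}

# Approximate-match distance spec for the TRE engine at edit budget k.
.match_distance <- function(k, metric) {
  if (metric == "hamming") {
    list(cost = k, all = k, insertions = 0L, deletions = 0L,
         substitutions = k)
  } else {
    list(cost = k, all = k, insertions = k, deletions = k, substitutions = k)
  }
}

# Vectorised best terminal match of `pattern` in the head or tail window of
# each sequence. Returns a data.frame(hit, offset, mismatches): offset is
# 0-based from the window start; the best hit minimises mismatches and breaks
# ties by smallest offset (passes at k = 0, 1, ... guarantee this, as the TRE
# engine returns the leftmost lowest-cost match). 'N' in the read never
# matches a primer base. Sequences shorter than the pattern yield no hit.
terminal_match_table <- function(seqs, pattern, end = c("head", "tail"),
                                 window = 100L, max_mismatch = 2L,
                                 metric = c("edit", "hamming")) {
  end <- match.arg(end)
  metric <- match.arg(metric)
  n <- length(seqs)
  plen <- nchar(pattern)
  len <- nchar(seqs)
  win <- if (end == "head") {
    substr(seqs, 1L, pmin(window, len))
  } else {
    substr(seqs, pmax(1L, len - window + 1L), len)
  }
  offset <- rep(NA_integer_, n)
  mism <- rep(NA_integer_, n)
  open <- nchar(win) >= plen
  for (k in 0:max_mismatch) {
    idx <- which(open)
    if (!length(idx)) break
    if (k == 0L) {
      pos <- regexpr(pattern, win[idx], fixed = TRUE)
      st <- as.integer(pos)
    } else {
      m <- aregexec(pattern, win[idx], max.distance = .match_distance(k, metric),
                    fixed = TRUE)
      st <- vapply(m, function(z) as.integer(z[1L]), 0L)
    }
    found <- st > 0L
    offset[idx[found]] <- st[found] - 1L
    mism[idx[found]] <- k
    open[idx[found]] <- FALSE
  }
  data.frame(hit = !is.na(offset), offset = offset, mismatches = mism)
}

#' Best approximate primer match in a terminal window
#'
#' Scans the head (first `window` bases) or tail (last `window` bases) of one
#' sequence for the best approximate occurrence of `pattern`: minimum
#' mismatches first, ties broken by smallest offset. Reads shorter than the
#' window are searched over their full length; reads shorter than the pattern
#' yield no hit. `N` bases count as mismatches.
#'
#' @param sequence A single DNA string.
#' @param pattern Primer sequence to search for.
#' @param end `"head"` or `"tail"`.
#' @param window Terminal window length.
#' @param max_mismatch Mismatch budget.
#' @param metric `"edit"` or `"hamming"` (see [primer_config()]).
#' @return A list with `offset` (0-based from the window start) and
#'   `mismatches`, or `NULL` when no offset achieves the budget.
#' @export
find_terminal_match <- function(sequence, pattern, end = c("head", "tail"),
                                window = 100L, max_mismatch = 2L,
                                metric = c("edit", "hamming")) {
  stopifnot(length(sequence) == 1L)
  tab <- terminal_match_table(sequence, pattern, end, window, max_mismatch,
                              metric)
  if (!tab$hit) return(NULL)
  list(offset = tab$offset, mismatches = tab$mismatches)
}

#' Positional enrichment profile of a primer
#'
#' For each read, records the start position of the best primer hit within
#' the first (head-anchored) and last (tail-anchored) `max_pos` bases, and
#' reports the fraction of reads with any hit (prevalence). Head positions
#' are 0-based offsets from the 5' end; tail positions are distances from the
#' 3' end to the end of the match, so an exactly terminal hit scores 0 on
#' both axes. Kit primers pile up at position 0 of the appropriate end, which
#' is the evidence the stranding criteria rest on.
#'
#' @param reads A `read_set`.
#' @param pattern Primer sequence.
#' @param max_mismatch Mismatch budget.
#' @param max_pos Window length profiled from each end.
#' @param metric `"edit"` or `"hamming"`.
#' @return A list with integer count vectors `head` and `tail` (positions
#'   `0 ... max_pos - 1`) and scalars `prevalence_head`, `prevalence_tail`.
#' @export
positional_profile <- function(reads, pattern, max_mismatch = 2L,
                               max_pos = 100L, metric = c("edit", "hamming")) {
  metric <- match.arg(metric)
  stopifnot(max_pos >= nchar(pattern))
  nr <- nrow(reads)
  head_tab <- terminal_match_table(reads$seq, pattern, "head", max_pos,
                                   max_mismatch, metric)
  tail_tab <- terminal_match_table(reads$seq, pattern, "tail", max_pos,
                                   max_mismatch, metric)
  win_len <- pmin(max_pos, nchar(reads$seq))
  # distance from the 3' end to the match end (match length ~ pattern length;
  # exact for hamming, within max_mismatch for edit)
  tail_pos <- win_len - (tail_tab$offset + nchar(pattern))
  tail_pos <- pmax(tail_pos, 0L)
  count_at <- function(pos) {
    pos <- pos[!is.na(pos) & pos >= 0L & pos < max_pos]
    tabulate(pos + 1L, nbins = max_pos)
  }
  list(head = count_at(head_tab$offset),
       tail = count_at(tail_pos),
       prevalence_head = if (nr) mean(head_tab$hit) else 0,
       prevalence_tail = if (nr) mean(tail_tab$hit) else 0)
}

# Logical hit table for the four stranding criteria (plus any needed by the
# artifact screen). Columns are criterion names; only requested criteria are
# computed.
criterion_hits <- function(seqs, config, criteria = config$criteria) {
  out <- matrix(FALSE, nrow = length(seqs), ncol = length(criteria),
                dimnames = list(NULL, criteria))
  for (cr in criteria) {
    spec <- switch(cr,
      P1_HEAD    = list(pat = config$p1, end = "head"),
      RC_P2_TAIL = list(pat = revcomp(config$p2), end = "tail"),
      P2_HEAD    = list(pat = config$p2, end = "head"),
      RC_P1_TAIL = list(pat = revcomp(config$p1), end = "tail"),
      stop("unknown criterion: ", cr))
    out[, cr] <- terminal_match_table(seqs, spec$pat, spec$end, config$window,
                                      config$max_mismatch, config$metric)$hit
  }
  out
}
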