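.code_precedence <- c("=", "c", "k", "j", "o", "s", "i", "u")

# class code for one query/reference transcript pair, or NA when the pair
# supports no code. `q`/`r` are single rows of a transcripts table; chains
# are intron matrices; `q_exons`/`r_exons` the pair's exon rows; `ov` their
# exonic overlap in bases.
.pair_code <- function(q, r, q_chain, r_chain, q_exons, r_exons, ov,
                       mono_frac = 0.8) {
  same <- q$strand == r$strand
  q_mono <- nrow(q_chain) == 0L
  r_mono <- nrow(r_chain) == 0L
  if (same) {
    if (!q_mono && !r_mono &&
        chain_key(q_chain) == chain_key(r_chain)) return("=")
    if (q_mono && r_mono) {
      wq <- q$end0 - q$start0; wr <- r$end0 - r$start0
      if (ov >= mono_frac * wq && ov >= mono_frac * wr) return("=")
    }
    # containment: sub-chain within span, or mono transcript inside an exon
    contained_in <- function(a, a_chain, b, b_chain, b_exons) {
      if (!(a$start0 >= b$start0 && a$end0 <= b$end0)) return(FALSE)
      if (nrow(a_chain) == 0L) {
        return(any(b_exons$start0 <= a$start0 & a$end0 <= b_exons$end0))
      }
      nrow(b_chain) > 0L && is_subchain(a_chain, b_chain)
    }
    if (contained_in(q, q_chain, r, r_chain, r_exons)) return("c")
    if (contained_in(r, r_chain, q, q_chain, q_exons)) return("k")
    if (!q_mono && !r_mono) {
      qk <- paste(q_chain[, 1L], q_chain[, 2L])
      rk <- paste(r_chain[, 1L], r_chain[, 2L])
      if (length(intersect(qk, rk))) return("j")
    }
    if (ov >= 1L) return("o")
  } else if (ov >= 1L) {
    return("s")
  }
  if (ov == 0L && nrow(r_chain)) {
    inside <- r_chain[, 1L] <= q$start0 & q$end0 <= r_chain[, 2L]
    if (any(inside)) return("i")
  }
  NA_character_
}

#' Class codes of query transcripts against a reference
#'
#' Assigns each query transcript a gffcompare-style class code describing
#' its relation to the closest reference transcript, evaluated against all
#' same-chrom references in precedence order `=` > `c` > `k` > `j` > `o` >
#' `s` > `i` > `u`:
#' \describe{
#'   \item{`=`}{same strand; identical intron chain (multi-exon), or
#'     reciprocal overlap of at least `mono_frac` for a mono-exon pair.}
#'   \item{`c`}{same strand; query contained: its intron chain is a
#'     contiguous sub-chain of the reference's and its span lies within the
#'     reference span; a mono-exon query inside a reference exon also
#'     qualifies.}
#'   \item{`k`}{the reverse containment.}
#'   \item{`j`}{same strand, at least one shared intron, none of the above.}
#'   \item{`o`}{same strand, exonic overlap only.}
#'   \item{`s`}{exonic overlap with an opposite-strand reference only.}
#'   \item{`i`}{query span inside a reference intron (either strand), no
#'     exonic overlap.}
#'   \item{`u`}{no overlap with any reference exon or intron.}
#' }
#' Ties within a code pick the reference with the largest exonic overlap.
#'
#' @param query,reference `transcript_set`s.
#' @param mono_frac Reciprocal-overlap fraction for a mono-exon `=` call
#'   (default 0.8).
#' @return Data frame (`query_id`, `ref_id`, `class_code`), one row per
#'   query transcript; `ref_id` is `NA` for code `u`.
#' @export
classify_set <- function(query, reference, mono_frac = 0.8) {
  qmeta <- query$transcripts
  rmeta <- reference$transcripts
  q_chains <- intron_chains(query)
  r_chains <- intron_chains(reference)
  ov_same <- exonic_overlaps(query, reference, same_strand = TRUE)
  ov_any <- exonic_overlaps(query, reference, same_strand = FALSE)
  ov_key <- paste(ov_any$a, ov_any$b)
  q_ex <- split(query$exons, query$exons$tx)
  r_ex <- split(reference$exons, reference$exons$tx)
  codes <- rep("u", nrow(qmeta))
  refs <- rep(NA_character_, nrow(qmeta))
  for (qi in seq_len(nrow(qmeta))) {
    q <- qmeta[qi, ]
    cand <- which(rmeta$chrom == q$chrom &
                    rmeta$start0 < q$end0 & q$start0 < rmeta$end0)
    if (!length(cand)) next
    best_code <- NA_character_; best_ref <- NA_character_; best_ov <- -1L
    for (ri in cand) {
      r <- rmeta[ri, ]
      ov <- ov_any$overlap[match(paste(q$id, r$id), ov_key)]
      if (is.na(ov)) ov <- 0L
      code <- .pair_code(q, r, q_chains[[q$id]], r_chains[[r$id]],
                         q_ex[[q$id]], r_ex[[r$id]], ov, mono_frac)
      if (is.na(code)) next
      rank <- match(code, .code_precedence)
      brank <- match(best_code, .code_precedence)
      if (is.na(brank) || rank < brank ||
          (rank == brank && ov > best_ov)) {
        best_code <- code; best_ref <- r$id; best_ov <- ov
      }
    }
    if (!is.na(best_code)) {
      codes[qi] <- best_code
      refs[qi] <- best_ref
    }
  }
  data.frame(query_id = qmeta$id, ref_id = refs, class_code = codes,
             stringsAsFactors = FALSE)
}

#' Compare a query assembly against a reference annotation
#'
#' Summary of a query transcriptome against a reference: per-code counts,
#' transcript-level sensitivity (reference transcripts matched `=` by at
#' least one query, over all references) and precision (queries coded `=`,
#' over all queries), and locus-level sensitivity and precision, where loci
#' are connected components of same-strand exonic overlap and a locus counts
#' as detected when at least one query transcript overlaps it exonically on
#' the same strand.
#'
#' @param query,reference `transcript_set`s.
#' @param mono_frac Mono-exon `=` reciprocal-overlap fraction.
#' @return A list of class `assembly_comparison`: `tmap` (per-query table),
#'   `code_counts`, `transcript` and `locus` sensitivity/precision (each
#'   with a `zero_denominator` flag when undefined and reported as 0).
#' @export
compare_sets <- function(query, reference, mono_frac = 0.8) {
  tmap <- classify_set(query, reference, mono_frac)
  nq <- n_transcripts(query); nr <- n_transcripts(reference)
  eq <- tmap$class_code == "="
  tx_sens <- if (nr) length(unique(tmap$ref_id[eq])) / nr else 0
  tx_prec <- if (nq) sum(eq) / nq else 0
  # locus level
  ref_comp <- if (nr) overlap_components(reference) else integer()
  ov <- exonic_overlaps(query, reference, same_strand = TRUE)
  hit_refs <- unique(ov$b)
  detected <- unique(ref_comp[match(hit_refs, reference$transcripts$id)])
  n_loci <- length(unique(ref_comp))
  q_comp <- if (nq) overlap_components(query) else integer()
  q_hit <- unique(q_comp[match(unique(ov$a), query$transcripts$id)])
  n_qloci <- length(unique(q_comp))
  structure(list(
    tmap = tmap,
    code_counts = table(factor(tmap$class_code, levels = .code_precedence)),
    transcript = list(sensitivity = tx_sens, precision = tx_prec,
                      zero_denominator = nr == 0L || nq == 0L),
    locus = list(
      sensitivity = if (n_loci) length(detected) / n_loci else 0,
      precision = if (n_qloci) length(q_hit) / n_qloci else 0,
      zero_denominator = n_loci == 0L || n_qloci == 0L)
  ), class = "assembly_comparison")
}

#' @export
print.assembly_comparison <- function(x, ...) {
  cat("assembly comparison\n  class codes: ")
  cc <- x$code_counts[x$code_counts > 0L]
  cat(paste(sprintf("%s:%d", names(cc), cc), collapse = "  "), "\n")
  cat(sprintf("  transcript sensitivity %.1f%%  precision %.1f%%\n",
              100 * x$transcript$sensitivity, 100 * x$transcript$precision))
  cat(sprintf("  locus      sensitivity %.1f%%  precision %.1f%%\n",
              100 * x$locus$sensitivity, 100 * x$locus$precision))
  invisible(x)
}

#' Distances between query and reference transcript ends
#'
#' For every query transcript, the signed distance from its transcription
#' start (or termination) site to the nearest same-strand reference TSS (or
#' TTS). The TSS is the strand-respecting 5' end of the span — on `-` the
#' rightmost coordinate — and the TTS the 3' end.
#'
#' @param query,reference `transcript_set`s.
#' @param which `"TSS"` or `"TTS"`.
#' @param within Distance cutoffs for the cumulative fractions.
#' @return A list with `distance` (signed, query minus reference, `NA` when
#'   no same-strand reference shares the chrom), `abs_distance` and
#'   `fraction_within` (named cumulative fractions of queries within each
#'   cutoff).
#' @export
end_distances <- function(query, reference, which = c("TSS", "TTS"),
                          within = c(50, 100, 500, 1000)) {
  which <- match.arg(which)
  end_of <- function(meta) {
    five <- ifelse(meta$strand == "-", meta$end0, meta$start0)
    three <- ifelse(meta$strand == "-", meta$start0, meta$end0)
    if (which == "TSS") five else three
  }
  q <- query$transcripts; r <- reference$transcripts
  qe <- end_of(q); re <- end_of(r)
  dist <- rep(NA_real_, nrow(q))
  for (i in seq_len(nrow(q))) {
    cand <- which(r$chrom == q$chrom[i] & r$strand == q$strand[i])
    if (length(cand)) {
      d <- qe[i] - re[cand]
      dist[i] <- d[which.min(abs(d))]
    }
  }
  frac <- vapply(within, function(w) mean(abs(dist) <= w, na.rm = TRUE),
                 0)
  list(distance = dist, abs_distance = abs(dist),
       fraction_within = stats::setNames(frac, paste0("<=", within, "bp")))
}

#' Count segmented genes against merged spans
#'
#' A gene of the original annotation is segmented when the merged span it
#' overlaps (same strand, at least 1 bp exonic overlap) also overlaps at
#' least one other original gene — i.e. several original genes collapse
#' into one consolidated span, the signature of artifactual fragmentation.
#'
#' @param originals A `transcript_set` whose transcripts are the original
#'   gene models (one model per gene).
#' @param merged_spans A `transcript_set` of consolidated spans, normally
#'   from [strand_aware_union()].
#' @return Integer: the number of segmented original genes.
#' @export
count_segmented <- function(originals, merged_spans) {
  ov <- exonic_overlaps(originals, merged_spans, same_strand = TRUE)
  if (!nrow(ov)) return(0L)
  genes_per_span <- tapply(ov$a, ov$b, function(g) length(unique(g)))
  multi <- names(genes_per_span)[genes_per_span >= 2L]
  length(unique(ov$a[ov$b %in% multi]))
}
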