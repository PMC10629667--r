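#' Merge configuration
#'
#' Parameters of the strand-aware transcript merge.
#'
#' @param min_cov Stringency of transcript calling (default 0 = keep all):
#'   a merged model is reported only when its best supporting input
#'   transcript has `cov >= min_cov` — the analog of an assembler's
#'   minimum-read-count option. Applied to the merged models rather than
#'   the inputs, so raising the stringency can only shrink the output.
#' @param mono_overlap_frac Fraction of the shorter transcript that two
#'   mono-exon transcripts must overlap by to be merged (default 0.3):
#'   any-overlap merging over-fuses adjacent genes, while
#'   full-containment-only under-fuses fragments.
#' @param track_sources Record which inputs contributed to each output
#'   transcript (default `TRUE`).
#' @return A `merge_config` object. Strand awareness is not optional:
#'   transcripts only ever merge with transcripts on the same strand, and
#'   `.`-strand models only with `.`-strand models.
#' @export
merge_config <- function(min_cov = 0, mono_overlap_frac = 0.3,
                         track_sources = TRUE) {
  if (min_cov < 0) stop("min_cov must be non-negative")
  if (!(mono_overlap_frac > 0 && mono_overlap_frac <= 1)) {
    stop("mono_overlap_frac must be in (0, 1]")
  }
  structure(list(min_cov = min_cov, mono_overlap_frac = mono_overlap_frac,
                 track_sources = isTRUE(track_sources)),
            class = "merge_config")
}

#' Filter transcripts by coverage
#'
#' Retains transcripts whose `cov` attribute is at least `min_cov`.
#' Transcripts without a `cov` attribute pass only when `min_cov` is 0, so
#' raising the stringency can only shrink the set.
#'
#' @param ts A `transcript_set`.
#' @param min_cov Non-negative coverage threshold.
#' @return The filtered `transcript_set`.
#' @export
filter_by_coverage <- function(ts, min_cov) {
  if (min_cov < 0) stop("min_cov must be non-negative")
  cov <- ts$transcripts$cov
  if (is.null(cov)) cov <- rep(NA_real_, n_transcripts(ts))
  keep <- if (min_cov == 0) rep(TRUE, n_transcripts(ts)) else
    !is.na(cov) & cov >= min_cov
  subset_transcripts(ts, ts$transcripts$id[keep])
}

# max of two possibly-NA coverages; NA when both missing
.max_cov <- function(a, b) {
  v <- c(a, b)
  if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
}

# one merge pass inside a component; returns list(members=list of member
# lists, changed). Each member: exons (matrix start0/end0), chain, span,
# sources, cov. Operates until caller reaches a fixed point.
.merge_pass <- function(mem, frac) {
  n <- length(mem)
  if (n < 2L) return(list(members = mem, changed = FALSE))
  key <- vapply(mem, function(m) chain_key(m$chain), "")
  is_mono <- !nzchar(key)
  width <- vapply(mem, function(m) m$span[2L] - m$span[1L], 0)
  absorb <- function(host, guest) {
    mem[[host]]$span <<- range(c(mem[[host]]$span, mem[[guest]]$span))
    mem[[host]]$sources <<- sort(unique(c(mem[[host]]$sources,
                                          mem[[guest]]$sources)))
    mem[[host]]$cov <<- .max_cov(mem[[host]]$cov, mem[[guest]]$cov)
    # extend the host's terminal exons to the merged span
    ex <- mem[[host]]$exons
    ex[1L, 1L] <- mem[[host]]$span[1L]
    ex[nrow(ex), 2L] <- mem[[host]]$span[2L]
    mem[[host]]$exons <<- ex
    mem[guest] <<- list(NULL)
  }
  # deterministic host preference: wider span, then earlier start
  ord <- order(-width, vapply(mem, function(m) m$span[1L], 0))
  for (a_i in seq_len(n - 1L)) for (b_i in (a_i + 1L):n) {
    a <- ord[a_i]; b <- ord[b_i]
    if (is.null(mem[[a]]) || is.null(mem[[b]])) next
    ma <- mem[[a]]; mb <- mem[[b]]
    ov <- min(ma$span[2L], mb$span[2L]) - max(ma$span[1L], mb$span[1L])
    if (ov <= 0L && key[a] != key[b]) next
    # rule: identical intron chains collapse (span -> min/max)
    if (!is_mono[a] && key[a] == key[b]) {
      absorb(a, b); return(list(members = mem, changed = TRUE))
    }
    # rule: contiguous sub-chain within span is absorbed
    if (!is_mono[a] && !is_mono[b] &&
        mb$span[1L] >= ma$span[1L] && mb$span[2L] <= ma$span[2L] &&
        is_subchain(mb$chain, ma$chain)) {
      mem[[a]]$sources <- sort(unique(c(ma$sources, mb$sources)))
      mem[[a]]$cov <- .max_cov(ma$cov, mb$cov)
      mem[b] <- list(NULL)
      return(list(members = mem, changed = TRUE))
    }
    # rule: mono-exon transcript inside an exon of another is absorbed
    if (is_mono[b] && ov > 0L) {
      ex <- ma$exons
      if (any(ex[, 1L] <= mb$span[1L] & mb$span[2L] <= ex[, 2L])) {
        mem[[a]]$sources <- sort(unique(c(ma$sources, mb$sources)))
        mem[[a]]$cov <- .max_cov(ma$cov, mb$cov)
        mem[b] <- list(NULL)
        return(list(members = mem, changed = TRUE))
      }
    }
    # rule: overlapping mono-exon transcripts merge into their union span
    if (is_mono[a] && is_mono[b] && ov > 0L &&
        ov >= frac * min(width[a], width[b])) {
      absorb(a, b); return(list(members = mem, changed = TRUE))
    }
  }
  list(members = mem, changed = FALSE)
}

#' Strand-aware merge of transcriptomes
#'
#' TASSEL's consolidation step: two or more transcript sets — typically a
#' short-read-derived assembly and a SLURP-stranded long-read-derived
#' assembly — are pooled and reduced to a non-redundant consensus. The pool
#' is clustered into connected components of same-chrom, same-strand exonic
#' overlap, and within each component the following collapses are applied
#' to a fixed point:
#' multi-exon transcripts with identical intron chains collapse to one model
#' spanning their extremes; a transcript whose intron chain is a contiguous
#' sub-chain of another's, with its span contained, is absorbed; a mono-exon
#' transcript contained in an exon of a retained transcript is absorbed; and
#' mono-exon transcripts overlapping by at least `mono_overlap_frac` of the
#' shorter merge transitively into their union span. Transcripts on
#' different strands never merge. Output ids (`TSL.<n>`) are regenerated in
#' genomic sort order, so the result is independent of input order; each
#' output carries a `sources` attribute listing the contributing inputs
#' (0-based), `consensus = "true"` when two or more inputs contributed, and
#' `cov` equal to the best supporting input coverage, against which the
#' `min_cov` stringency is applied.
#'
#' @param inputs A list of `transcript_set`s (length >= 1).
#' @param config A [merge_config()].
#' @return The merged `transcript_set`.
#' @export
merge_transcriptomes <- function(inputs, config = merge_config()) {
  stopifnot(is.list(inputs), length(inputs) >= 1L)
  if (inherits(inputs, "transcript_set")) inputs <- list(inputs)
  pooled_ex <- list(); pooled_meta <- list()
  for (i in seq_along(inputs)) {
    ts <- inputs[[i]]
    if (!n_transcripts(ts)) next
    tag <- function(x) paste0("in", i - 1L, ".", x)
    ex <- ts$exons; ex$tx <- tag(ex$tx)
    meta <- ts$transcripts; meta$id <- tag(meta$id)
    meta$source_idx <- i - 1L
    if (is.null(meta$cov)) meta$cov <- NA_real_
    pooled_ex[[length(pooled_ex) + 1L]] <- ex
    pooled_meta[[length(pooled_meta) + 1L]] <-
      meta[c("id", "chrom", "strand", "start0", "end0", "cov", "source_idx")]
  }
  if (!length(pooled_ex)) {
    return(transcript_set(data.frame(tx = character(), chrom = character(),
                                     start0 = integer(), end0 = integer(),
                                     strand = character())))
  }
  ex <- do.call(rbind, pooled_ex)
  meta <- do.call(rbind, pooled_meta)
  pooled <- transcript_set(ex, data.frame(id = meta$id, cov = meta$cov,
                                          sources = as.character(meta$source_idx),
                                          stringsAsFactors = FALSE))
  comp <- overlap_components(pooled)
  pmeta <- pooled$transcripts
  chains <- intron_chains(pooled)
  out_members <- list()
  for (cid in unique(comp)) {
    ids <- pmeta$id[comp == cid]
    mem <- lapply(ids, function(id) {
      m <- pmeta[pmeta$id == id, ]
      e <- pooled$exons[pooled$exons$tx == id, , drop = FALSE]
      list(exons = cbind(e$start0, e$end0), chain = chains[[id]],
           span = c(m$start0, m$end0),
           sources = as.integer(m$sources),
           cov = m$cov, chrom = m$chrom, strand = m$strand)
    })
    repeat {
      res <- .merge_pass(mem, config$mono_overlap_frac)
      mem <- Filter(Negate(is.null), res$members)
      if (!res$changed) break
    }
    out_members <- c(out_members, mem)
  }
  # deterministic ids in genomic sort order
  key <- vapply(out_members, function(m)
    sprintf("%s\t%012d\t%012d\t%s", m$chrom, m$span[1L], m$span[2L],
            m$strand), "")
  out_members <- out_members[order(key)]
  ex_rows <- list(); meta_rows <- list()
  for (i in seq_along(out_members)) {
    m <- out_members[[i]]
    id <- sprintf("TSL.%d", i)
    ex_rows[[i]] <- data.frame(tx = id, chrom = m$chrom,
                               start0 = m$exons[, 1L], end0 = m$exons[, 2L],
                               strand = m$strand, stringsAsFactors = FALSE)
    meta_rows[[i]] <- data.frame(
      id = id, gene_id = id, cov = m$cov,
      sources = if (config$track_sources)
        paste(m$sources, collapse = ",") else NA_character_,
      consensus = if (config$track_sources)
        tolower(length(m$sources) >= 2L) else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- transcript_set(do.call(rbind, ex_rows), do.call(rbind, meta_rows))
  if (config$min_cov > 0) out <- filter_by_coverage(out, config$min_cov)
  out
}
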