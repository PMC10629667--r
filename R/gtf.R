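#' Construct a transcript set
#'
#' The container for transcript models used by the comparison and merge
#' machinery. Internally coordinates are 0-based half-open (`start0`,
#' `end0`); GTF on disk is 1-based inclusive and converted at the boundary.
#'
#' @param exons Data frame with columns `tx`, `chrom`, `start0`, `end0`,
#'   `strand` (one row per exon).
#' @param transcripts Optional data frame with one row per transcript id
#'   (`id`, plus any of `gene_id`, `cov`, `tpm`, `sources`, `expression`).
#'   Missing metadata is derived from the exons.
#' @return A `transcript_set`: list with sorted `exons` and `transcripts`
#'   data frames.
#' @details Invariants enforced: every transcript has at least one exon;
#'   exons of one transcript share chrom and strand, are non-empty
#'   (`start0 < end0`) and pairwise non-overlapping.
#' @export
transcript_set <- function(exons, transcripts = NULL) {
  stopifnot(all(c("tx", "chrom", "start0", "end0", "strand") %in%
                  colnames(exons)))
  if (nrow(exons) && any(exons$start0 >= exons$end0)) {
    stop("exon with start0 >= end0")
  }
  exons <- exons[order(exons$tx, exons$start0), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons)) {
    by_tx <- split(seq_len(nrow(exons)), exons$tx)
    for (idx in by_tx) {
      if (length(unique(exons$chrom[idx])) > 1L ||
          length(unique(exons$strand[idx])) > 1L) {
        stop("exons of transcript '", exons$tx[idx[1L]],
             "' on mixed chrom/strand")
      }
      if (length(idx) > 1L &&
          any(exons$start0[idx][-1L] < exons$end0[idx][-length(idx)])) {
        stop("overlapping exons in transcript '", exons$tx[idx[1L]], "'")
      }
    }
    first <- !duplicated(exons$tx)
    meta <- data.frame(id = exons$tx[first], chrom = exons$chrom[first],
                       strand = exons$strand[first],
                       stringsAsFactors = FALSE)
    meta$start0 <- as.integer(tapply(exons$start0, exons$tx, min)[meta$id])
    meta$end0 <- as.integer(tapply(exons$end0, exons$tx, max)[meta$id])
    meta$n_exons <- as.integer(tapply(exons$tx, exons$tx, length)[meta$id])
  } else {
    meta <- data.frame(id = character(), chrom = character(),
                       strand = character(), start0 = integer(),
                       end0 = integer(), n_exons = integer(),
                       stringsAsFactors = FALSE)
  }
  if (!is.null(transcripts)) {
    extra <- transcripts[match(meta$id, transcripts$id), , drop = FALSE]
    for (cn in setdiff(colnames(extra), colnames(meta))) {
      meta[[cn]] <- extra[[cn]]
    }
  }
  if (is.null(meta$gene_id)) meta$gene_id <- meta$id
  meta <- meta[order(meta$chrom, meta$start0, meta$end0, meta$strand), ,
               drop = FALSE]
  rownames(meta) <- NULL
  structure(list(exons = exons, transcripts = meta),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons on",
      length(unique(x$transcripts$chrom)), "sequence(s)\n")
  invisible(x)
}

#' Number of transcripts in a set
#' @param ts A `transcript_set`.
#' @return Integer count.
#' @export
n_transcripts <- function(ts) nrow(ts$transcripts)

# extract one attribute value from a GTF attribute column
.gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0('(?:^|; ?)', key, ' "([^"]*)"'),
                                 attrs))
  vapply(m, function(z) if (length(z) == 2L) z[2L] else NA_character_, "")
}

#' Parse a GTF annotation
#'
#' Reads GTF2-style exon features, grouping them by `transcript_id`. Disk
#' coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open representation. Non-exon features are ignored; `cov`, `TPM` and
#' `sources` attributes are retained when present.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_set()].
#' @export
parse_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(transcript_set(data.frame(tx = character(), chrom = character(),
                                     start0 = integer(), end0 = integer(),
                                     strand = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) {
    stop("line ", lineno[bad[1L]], ": expected 9 tab-separated GTF fields")
  }
  feature <- vapply(fields, `[[`, "", 3L)
  is_exon <- feature == "exon"
  if (!any(is_exon)) {
    return(transcript_set(data.frame(tx = character(), chrom = character(),
                                     start0 = integer(), end0 = integer(),
                                     strand = character())))
  }
  fields <- fields[is_exon]
  lineno <- lineno[is_exon]
  attrs <- vapply(fields, `[[`, "", 9L)
  tx <- .gtf_attr(attrs, "transcript_id")
  if (anyNA(tx)) {
    stop("line ", lineno[which(is.na(tx))[1L]],
         ": exon feature lacks transcript_id")
  }
  exons <- data.frame(
    tx = tx,
    chrom = vapply(fields, `[[`, "", 1L),
    start0 = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,
    end0 = as.integer(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    stringsAsFactors = FALSE)
  gene <- .gtf_attr(attrs, "gene_id")
  cov <- suppressWarnings(as.numeric(.gtf_attr(attrs, "cov")))
  tpm <- suppressWarnings(as.numeric(.gtf_attr(attrs, "TPM")))
  src <- .gtf_attr(attrs, "sources")
  first <- !duplicated(tx)
  meta <- data.frame(id = tx[first], gene_id = gene[first], cov = cov[first],
                     tpm = tpm[first], sources = src[first],
                     stringsAsFactors = FALSE)
  meta$gene_id[is.na(meta$gene_id)] <- meta$id[is.na(meta$gene_id)]
  transcript_set(exons, meta)
}

#' Write a transcript set as GTF
#'
#' Emits one exon feature per exon, 1-based inclusive coordinates, with
#' attributes in the order `gene_id`, `transcript_id`, then `cov`, `TPM`,
#' `sources`, `consensus` when present. Coordinates round-trip bit-exactly
#' through [parse_gtf()].
#'
#' @param ts A `transcript_set`.
#' @param path Output path.
#' @param source Value of the GTF source column.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(ts, path, source = "tassel") {
  meta <- ts$transcripts
  ex <- ts$exons
  ord <- order(match(ex$tx, meta$id), ex$start0)
  ex <- ex[ord, , drop = FALSE]
  i <- match(ex$tx, meta$id)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   meta$gene_id[i], ex$tx)
  for (key in c("cov", "tpm", "sources", "consensus")) {
    v <- meta[[key]][i]
    if (is.null(v)) next
    lab <- c(cov = "cov", tpm = "TPM", sources = "sources",
             consensus = "consensus")[[key]]
    has <- !is.na(v)
    val <- if (is.numeric(v)) sub("\\.?0+$", "", sprintf("%.6f", v)) else
      as.character(v)
    attrs[has] <- paste0(attrs[has], sprintf(' %s "%s";', lab, val[has]))
  }
  out <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                 ex$chrom, source, ex$start0 + 1L, ex$end0, ex$strand, attrs)
  writeLines(out, path)
  invisible(path)
}

# intron chain of each transcript as a list of 2-column matrices
# (0-based half-open intron intervals), named by transcript id
intron_chains <- function(ts) {
  out <- lapply(split(ts$exons[c("start0", "end0")], ts$exons$tx),
                function(e) {
                  k <- nrow(e)
                  if (k < 2L) return(matrix(integer(), ncol = 2L))
                  cbind(e$end0[-k], e$start0[-1L])
                })
  out[ts$transcripts$id]
}

# chain as a canonical string key ("" for mono-exon)
chain_key <- function(chain) {
  if (!nrow(chain)) return("")
  paste(chain[, 1L], chain[, 2L], sep = "-", collapse = ",")
}

# is `small` a contiguous sub-chain of `big`?
is_subchain <- function(small, big) {
  ns <- nrow(small); nb <- nrow(big)
  if (ns == 0L || ns > nb) return(FALSE)
  for (off in 0:(nb - ns)) {
    if (all(small == big[(off + 1L):(off + ns), , drop = FALSE])) return(TRUE)
  }
  FALSE
}

# pairwise exonic overlap between two transcript sets.
# Returns data.frame(a, b, overlap) of transcript-id pairs with >=1 bp
# exonic overlap; same_strand restricts to literally equal strands. When
# `b_ts` is NULL, overlaps within `a_ts` (a < b) are returned.
exonic_overlaps <- function(a_ts, b_ts = NULL, same_strand = TRUE) {
  self <- is.null(b_ts)
  if (self) b_ts <- a_ts
  ea <- a_ts$exons; eb <- b_ts$exons
  keys_a <- if (same_strand) paste(ea$chrom, ea$strand) else ea$chrom
  keys_b <- if (same_strand) paste(eb$chrom, eb$strand) else eb$chrom
  res <- list()
  for (key in intersect(unique(keys_a), unique(keys_b))) {
    ia <- which(keys_a == key); ib <- which(keys_b == key)
    ra <- IRanges::IRanges(ea$start0[ia] + 1L, ea$end0[ia])
    rb <- IRanges::IRanges(eb$start0[ib] + 1L, eb$end0[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    if (!length(ov)) next
    qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(ra[qa], rb[qb]))
    df <- data.frame(a = ea$tx[ia[qa]], b = eb$tx[ib[qb]], overlap = w,
                     stringsAsFactors = FALSE)
    res[[length(res) + 1L]] <- df
  }
  if (!length(res)) {
    return(data.frame(a = character(), b = character(), overlap = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  df <- stats::aggregate(overlap ~ a + b, df, sum)
  if (self) df <- df[df$a != df$b, , drop = FALSE]
  df
}

#' Strand-aware union of a transcript set into merged spans
#'
#' Collapses transcripts into the spans of their connected components of
#' same-chrom, same-strand exonic overlap — the gene-level consolidation
#' used for segmentation counting.
#'
#' @param ts A `transcript_set`.
#' @return A `transcript_set` of mono-exon spans (ids `SPAN.1`, ...).
#' @export
strand_aware_union <- function(ts) {
  meta <- ts$transcripts
  if (!nrow(meta)) return(ts)
  comp <- overlap_components(ts)
  spans <- do.call(rbind, lapply(split(meta, comp), function(m) {
    data.frame(chrom = m$chrom[1L], strand = m$strand[1L],
               start0 = min(m$start0), end0 = max(m$end0),
               stringsAsFactors = FALSE)
  }))
  spans <- spans[order(spans$chrom, spans$start0, spans$end0, spans$strand), ,
                 drop = FALSE]
  spans$tx <- sprintf("SPAN.%d", seq_len(nrow(spans)))
  transcript_set(spans[c("tx", "chrom", "start0", "end0", "strand")])
}

# connected components of same-strand exonic overlap; integer component
# label per transcript (in ts$transcripts order)
overlap_components <- function(ts) {
  meta <- ts$transcripts
  ov <- exonic_overlaps(ts, same_strand = TRUE)
  g <- igraph::graph_from_data_frame(
    ov[c("a", "b")], directed = FALSE,
    vertices = data.frame(name = meta$id))
  comp <- igraph::components(g)$membership
  as.integer(comp[meta$id])
}

# subset a transcript_set by transcript ids (keeps metadata columns)
subset_transcripts <- function(ts, ids) {
  transcript_set(ts$exons[ts$exons$tx %in% ids, , drop = FALSE],
                 ts$transcripts[ts$transcripts$id %in% ids, , drop = FALSE])
}
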