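# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive: literal definitions, exhaustive
# scans, no shared code with the package internals.

# exhaustive all-offsets Hamming scan: best (min mismatches, then smallest
# offset) occurrence of `pattern` in the head or tail window of `sequence`
oracle_hamming_scan <- function(sequence, pattern, end, window,
                                max_mismatch) {
  n <- nchar(sequence)
  win <- if (end == "head") substr(sequence, 1, min(window, n)) else
    substr(sequence, max(1, n - window + 1), n)
  wl <- nchar(win)
  pl <- nchar(pattern)
  if (wl < pl) return(NULL)
  pch <- strsplit(pattern, "")[[1]]
  best <- NULL
  for (off in 0:(wl - pl)) {
    sch <- strsplit(substr(win, off + 1, off + pl), "")[[1]]
    mm <- sum(sch != pch | sch == "N")
    if (mm <= max_mismatch && (is.null(best) || mm < best$mismatches)) {
      best <- list(offset = off, mismatches = mm)
    }
  }
  best
}

# pure-R reverse complement, independent of Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch], collapse = "")
  }, "", USE.NAMES = FALSE)
}

# --- literal-definition class-code oracle --------------------------------
# Works directly on exon tables; every predicate restated from scratch.

.o_exons <- function(ts, id) {
  e <- ts$exons[ts$exons$tx == id, , drop = FALSE]
  e[order(e$start0), , drop = FALSE]
}

.o_introns <- function(e) {
  if (nrow(e) < 2) return(character())
  sprintf("%d:%d", e$end0[-nrow(e)], e$start0[-1])
}

.o_exonic_overlap <- function(ea, eb) {
  total <- 0
  for (i in seq_len(nrow(ea))) for (j in seq_len(nrow(eb))) {
    total <- total +
      max(0, min(ea$end0[i], eb$end0[j]) - max(ea$start0[i], eb$start0[j]))
  }
  total
}

.o_contig_sub <- function(small, big) {
  ns <- length(small); nb <- length(big)
  if (ns == 0 || ns > nb) return(FALSE)
  any(vapply(0:(nb - ns), function(off)
    identical(small, big[(off + 1):(off + ns)]), TRUE))
}

oracle_pair_code <- function(q_ts, qid, r_ts, rid, mono_frac = 0.8) {
  eq <- .o_exons(q_ts, qid); er <- .o_exons(r_ts, rid)
  qm <- q_ts$transcripts[q_ts$transcripts$id == qid, ]
  rm <- r_ts$transcripts[r_ts$transcripts$id == rid, ]
  if (qm$chrom != rm$chrom) return(NA_character_)
  iq <- .o_introns(eq); ir <- .o_introns(er)
  ov <- .o_exonic_overlap(eq, er)
  span_q <- c(min(eq$start0), max(eq$end0))
  span_r <- c(min(er$start0), max(er$end0))
  if (qm$strand == rm$strand) {
    if (length(iq) && length(ir) && identical(iq, ir)) return("=")
    if (!length(iq) && !length(ir)) {
      wq <- diff(span_q); wr <- diff(span_r)
      if (ov >= mono_frac * wq && ov >= mono_frac * wr) return("=")
    }
    cont <- function(ea, ia, eb, ib, span_a, span_b) {
      if (!(span_a[1] >= span_b[1] && span_a[2] <= span_b[2])) return(FALSE)
      if (!length(ia)) {
        return(any(eb$start0 <= span_a[1] & span_a[2] <= eb$end0))
      }
      length(ib) > 0 && .o_contig_sub(ia, ib)
    }
    if (cont(eq, iq, er, ir, span_q, span_r)) return("c")
    if (cont(er, ir, eq, iq, span_r, span_q)) return("k")
    if (length(intersect(iq, ir))) return("j")
    if (ov >= 1) return("o")
  } else if (ov >= 1) {
    return("s")
  }
  if (ov == 0 && length(ir)) {
    for (s in ir) {
      ab <- as.integer(strsplit(s, ":")[[1]])
      if (ab[1] <= span_q[1] && span_q[2] <= ab[2]) return("i")
    }
  }
  NA_character_
}

oracle_classify <- function(query, reference, mono_frac = 0.8) {
  prec <- c("=", "c", "k", "j", "o", "s", "i", "u")
  vapply(query$transcripts$id, function(qid) {
    codes <- vapply(reference$transcripts$id, function(rid)
      oracle_pair_code(query, qid, reference, rid, mono_frac), "")
    codes <- codes[!is.na(codes)]
    if (!length(codes)) "u" else prec[min(match(codes, prec))]
  }, "", USE.NAMES = FALSE)
}

# --- random fixtures -----------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random valid transcript set: up to `n` transcripts on one chromosome,
# 1-4 exons each, mixed strands, coordinates within ~12 kb
random_transcript_set <- function(n, prefix = "t") {
  rows <- list()
  for (i in seq_len(n)) {
    k <- sample(1:4, 1)
    lens <- sample(50:400, k, replace = TRUE)
    gaps <- if (k > 1) sample(60:500, k - 1, replace = TRUE) else integer()
    start <- sample(0:8000, 1)
    starts <- start + cumsum(c(0, head(lens, -1) + gaps))
    rows[[i]] <- data.frame(
      tx = sprintf("%s%03d", prefix, i), chrom = "chr1",
      start0 = as.integer(starts), end0 = as.integer(starts + lens),
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }
  transcript_set(do.call(rbind, rows))
}

# small deterministic spike-in style simulation shared by several tests
small_sim <- function(seed = 11, n_reads = 400, ...) {
  cfg <- sim_config(seed = seed, n_reads = n_reads, genome_size = 2e5,
                    n_genes = 20, ...)
  genome <- make_genome(cfg)
  ann <- make_annotation(cfg, genome)
  sim <- simulate_reads(cfg, ann$spikein, ann$spikein_seqs)
  list(cfg = cfg, genome = genome, ann = ann, sim = sim)
}
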