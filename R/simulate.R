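#' Simulation configuration
#'
#' All generators are pure functions of their configuration: the same
#' `sim_config` yields bit-identical genomes, annotations and libraries.
#' Defaults describe an ONT direct-cDNA chromatin-RNA-like library: an
#' ERCC-style ladder of 92 mono-exonic spike-in contigs, roughly half the
#' reads presented as each cDNA strand, indel-rich base errors, 3'-biased
#' truncation, and a 6 percent palindrome-artifact rate.
#'
#' @param seed Integer seed; every generator draws from an RNG stream
#'   derived from it.
#' @param genome_size Bases of random genome (default 2e6).
#' @param n_genes Number of genes placed on the genome (default 200).
#' @param exon_range Integer range of exons per gene (default 1..8).
#' @param isoform_prob Probability that a gene with enough exons gets a
#'   second, 5'-truncated isoform sharing at least one intron.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters for
#'   genes.
#' @param n_spikeins Number of mono-exonic spike-in transcripts (default
#'   92, the ERCC mix size), each on its own contig, lengths 250-2000.
#' @param n_reads Reads to simulate.
#' @param sub_rate,ins_rate,del_rate Per-base substitution, insertion and
#'   deletion probabilities (defaults 0.03 / 0.01 / 0.02, summing to the ~6
#'   percent error typical of ONT basecalls).
#' @param full_length_prob Probability a read covers its whole transcript
#'   (default 0.6); otherwise a 5' prefix is removed.
#' @param trunc_mean Mean of the geometric number of bases removed from the
#'   5' end of truncated reads (3'-anchored truncation: the polyA end is
#'   always retained).
#' @param artifact_rate Probability a direct-cDNA read is a template-switch
#'   palindrome (default 0.06, the prevalence observed in direct-cDNA
#'   libraries); forced to 0 in `direct_RNA` mode.
#' @param strand_presentation Fraction of non-artifact reads presented as
#'   the first cDNA strand (default 0.5).
#' @param polya_len PolyA tail length appended to the sense fragment.
#' @param mode `"direct_cDNA"` (primer-decorated, both strands, artifacts
#'   possible) or `"direct_RNA"` (sense only, no primers, no artifacts).
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L, genome_size = 2e6, n_genes = 200L,
                       exon_range = c(1L, 8L), isoform_prob = 0.3,
                       expr_meanlog = 1, expr_sdlog = 1, n_spikeins = 92L,
                       n_reads = 2000L, sub_rate = 0.03, ins_rate = 0.01,
                       del_rate = 0.02, full_length_prob = 0.6,
                       trunc_mean = 300, artifact_rate = 0.06,
                       strand_presentation = 0.5, polya_len = 20L,
                       mode = c("direct_cDNA", "direct_RNA")) {
  mode <- match.arg(mode)
  rates <- c(isoform_prob, sub_rate, ins_rate, del_rate, full_length_prob,
             artifact_rate, strand_presentation)
  stopifnot(all(rates >= 0 & rates <= 1), n_spikeins >= 1L)
  structure(list(seed = as.integer(seed), genome_size = genome_size,
                 n_genes = as.integer(n_genes),
                 exon_range = as.integer(exon_range),
                 isoform_prob = isoform_prob, expr_meanlog = expr_meanlog,
                 expr_sdlog = expr_sdlog, n_spikeins = as.integer(n_spikeins),
                 n_reads = as.integer(n_reads), sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 full_length_prob = full_length_prob, trunc_mean = trunc_mean,
                 artifact_rate = if (mode == "direct_RNA") 0 else
                   artifact_rate,
                 strand_presentation = strand_presentation,
                 polya_len = as.integer(polya_len), mode = mode),
            class = "sim_config")
}

# run `expr` under a deterministic RNG stream derived from (seed, tag),
# restoring the caller's RNG state afterwards
.with_sim_rng <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  offset <- sum(utf8ToInt(tag)) %% 1000L
  set.seed((seed * 1009L + offset) %% .Machine$integer.max)
  force(expr)
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random genome
#'
#' @param config A [sim_config()].
#' @return A named character vector with one uniform-random chromosome
#'   (`chrSim`) of `config$genome_size` bases. Same seed, same sequence.
#' @export
make_genome <- function(config) {
  .with_sim_rng(config$seed, "genome", c(chrSim = .rand_dna(config$genome_size)))
}

#' Generate the truth annotation and spike-in ladder
#'
#' Places `n_genes` genes on the genome without any same-strand overlap
#' (each gene in its own slot), with 1-8 exons and, for some multi-exon
#' genes, a second 5'-truncated isoform sharing the remaining introns.
#' Mono-exon genes are kilobase-scale, mimicking unspliced
#' chromatin-enriched transcripts. The spike-in ladder consists of
#' `n_spikeins` mono-exonic transcripts, each on its own contig, lengths
#' 250-2000, with concentrations doubling every group of four — a 2-fold
#' abundance ladder recorded in the concentration table.
#'
#' @param config A [sim_config()].
#' @param genome Output of [make_genome()].
#' @return A list with `truth` (gene `transcript_set`, `expression` column
#'   set), `spikein` (`transcript_set`), `spikein_seqs` (named character),
#'   and `concentrations` (data frame `transcript_id`, `group`,
#'   `concentration`).
#' @export
make_annotation <- function(config, genome) {
  .with_sim_rng(config$seed, "annotation", {
    gsize <- nchar(genome[[1L]])
    slot <- floor(gsize / config$n_genes)
    if (slot < 3000L) stop("genome too small to place ", config$n_genes,
                           " genes")
    ex_rows <- list(); meta_rows <- list()
    for (g in seq_len(config$n_genes)) {
      base <- (g - 1L) * slot
      k <- sample(config$exon_range[1L]:config$exon_range[2L], 1L)
      if (k == 1L) {
        lens <- round(stats::runif(1L, 1000, min(4000, slot - 400)))
        gaps <- integer()
      } else {
        lens <- round(stats::runif(k, 150, 600))
        gaps <- round(stats::runif(k - 1L, 150, 900))
        while (sum(lens) + sum(gaps) > slot - 400L) {
          lens <- pmax(100L, round(lens * 0.8))
          gaps <- pmax(120L, round(gaps * 0.8))
        }
      }
      start <- base + sample.int(max(1L, slot - sum(lens) - sum(gaps) - 200L),
                                 1L)
      starts <- start + cumsum(c(0L, utils::head(lens, -1L) + gaps))
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("G%04d", g)
      tid <- paste0(gid, ".1")
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(
        tx = tid, chrom = "chrSim", start0 = as.integer(starts),
        end0 = as.integer(starts + lens), strand = strand,
        stringsAsFactors = FALSE)
      expr <- stats::rlnorm(1L, config$expr_meanlog, config$expr_sdlog)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        id = tid, gene_id = gid, expression = expr,
        stringsAsFactors = FALSE)
      if (k >= 3L && stats::runif(1L) < config$isoform_prob) {
        # 5'-truncated isoform: drops the strand-respecting first exon,
        # sharing the remaining introns with the primary isoform
        drop <- if (strand == "-") k else 1L
        tid2 <- paste0(gid, ".2")
        keep <- setdiff(seq_len(k), drop)
        ex_rows[[length(ex_rows) + 1L]] <- data.frame(
          tx = tid2, chrom = "chrSim", start0 = as.integer(starts[keep]),
          end0 = as.integer(starts[keep] + lens[keep]), strand = strand,
          stringsAsFactors = FALSE)
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          id = tid2, gene_id = gid, expression = expr / 2,
          stringsAsFactors = FALSE)
      }
    }
    truth <- transcript_set(do.call(rbind, ex_rows),
                            do.call(rbind, meta_rows))
    # spike-in ladder: groups of 4, concentration doubling per group
    sp_len <- round(stats::runif(config$n_spikeins, 250, 2000))
    sp_id <- sprintf("SPIKE_%03d", seq_len(config$n_spikeins))
    group <- (seq_len(config$n_spikeins) - 1L) %/% 4L
    conc <- 2^group
    sp_seqs <- stats::setNames(vapply(sp_len, .rand_dna, ""), sp_id)
    spike <- transcript_set(
      data.frame(tx = sp_id, chrom = sp_id, start0 = 0L, end0 = sp_len,
                 strand = "+", stringsAsFactors = FALSE),
      data.frame(id = sp_id, gene_id = sp_id, expression = conc,
                 stringsAsFactors = FALSE))
    list(truth = truth, spikein = spike, spikein_seqs = sp_seqs,
         concentrations = data.frame(transcript_id = sp_id, group = group,
                                     concentration = conc,
                                     stringsAsFactors = FALSE))
  })
}

#' Spliced transcript sequences
#'
#' @param ts A `transcript_set`.
#' @param contigs Named character vector of contig sequences.
#' @return Named character vector of sense transcript sequences (exons
#'   spliced; `-`-strand transcripts reverse-complemented).
#' @export
transcript_seqs <- function(ts, contigs) {
  meta <- ts$transcripts
  out <- character(nrow(meta))
  ex_by_tx <- split(ts$exons, ts$exons$tx)
  for (i in seq_len(nrow(meta))) {
    e <- ex_by_tx[[meta$id[i]]]
    contig <- contigs[[meta$chrom[i]]]
    s <- paste(substring(contig, e$start0 + 1L, e$end0), collapse = "")
    out[i] <- if (meta$strand[i] == "-") revcomp(s) else s
  }
  stats::setNames(out, meta$id)
}

# apply iid substitution / insertion / deletion errors to one sequence
.mutate_seq <- function(s, sub, ins, del) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  u <- stats::runif(n)
  si <- which(u < sub)
  if (length(si)) {
    repl <- sample(bases, length(si), replace = TRUE)
    same <- repl == ch[si]
    while (any(same)) {
      repl[same] <- sample(bases, sum(same), replace = TRUE)
      same <- repl == ch[si]
    }
    ch[si] <- repl
  }
  d <- stats::runif(n) < del
  ch <- ch[!d]
  n2 <- length(ch)
  iv <- which(stats::runif(n2 + 1L) < ins)
  if (length(iv)) {
    add <- sample(bases, length(iv), replace = TRUE)
    # key p - 0.5 sorts an inserted base directly before position p
    ch <- c(ch, add)[order(c(seq_len(n2), iv - 0.5))]
  }
  paste(ch, collapse = "")
}

#' Simulate an ONT-like long-read library
#'
#' Draws each read's source transcript proportionally to its expression (or
#' spike-in concentration), keeps the full transcript with probability
#' `full_length_prob` or removes a geometric 5' prefix (the polyA end is
#' always retained), appends a polyA tail, and renders the read as one of
#' the two cDNA strands: the second-strand presentation is
#' `p2 + sense + rc(p1)` and the first-strand presentation is its reverse
#' complement, `p1 + antisense + rc(p2)`. With probability `artifact_rate`
#' (direct-cDNA only) the read is instead a template-switch palindrome: the
#' first-strand rendering followed by its own reverse complement, so primer
#' 1 appears at the head and its reverse complement at the tail. Errors are
#' then applied per base. In `direct_RNA` mode reads are bare sense
#' fragments with no primers and no artifacts.
#'
#' @param config A [sim_config()].
#' @param annotation A `transcript_set` whose `transcripts` carry an
#'   `expression` column (e.g. the `spikein` element of
#'   [make_annotation()]).
#' @param contigs Named character vector of contig sequences (e.g.
#'   `spikein_seqs`), or `NULL` to splice from `genome`.
#' @param primers A [primer_config()] providing the decoration sequences.
#' @return A list with `reads` (a `read_set`) and `truth` (data frame:
#'   `read_id`, `transcript_id`, `true_orientation` (`first`/`second`),
#'   `artifact`, `span_start`, `span_end` — 1-based transcript interval
#'   covered).
#' @export
simulate_reads <- function(config, annotation, contigs,
                           primers = primer_config()) {
  tx_seq <- transcript_seqs(annotation, contigs)
  rc_tx <- revcomp(tx_seq)  # precomputed so the read loop stays string-only
  expr <- annotation$transcripts$expression
  if (is.null(expr)) expr <- rep(1, length(tx_seq))
  p1 <- primers$p1; p2 <- primers$p2
  rc_p1 <- revcomp(p1); rc_p2 <- revcomp(p2)
  polya <- strrep("A", config$polya_len)
  polyt <- strrep("T", config$polya_len)
  .with_sim_rng(config$seed, "reads", {
    n <- config$n_reads
    tx_i <- sample.int(length(tx_seq), n, replace = TRUE, prob = expr)
    full <- stats::runif(n) < config$full_length_prob
    cut <- ifelse(full, 0L,
                  stats::rgeom(n, 1 / config$trunc_mean))
    art <- stats::runif(n) < config$artifact_rate
    first <- stats::runif(n) < config$strand_presentation
    seqs <- character(n); quals <- character(n)
    sp_start <- integer(n); sp_end <- integer(n)
    orient <- character(n)
    tx_len <- nchar(tx_seq)
    for (i in seq_len(n)) {
      len <- tx_len[tx_i[i]]
      from <- min(cut[i] + 1L, max(1L, len - 50L))
      sense <- paste0(substr(tx_seq[[tx_i[i]]], from, len), polya)
      # rc(sense) assembled from the precomputed reverse complement
      anti <- paste0(polyt, substr(rc_tx[[tx_i[i]]], 1L, len - from + 1L))
      sp_start[i] <- from; sp_end[i] <- len
      if (config$mode == "direct_RNA") {
        raw <- sense
        orient[i] <- "second"
      } else if (art[i]) {
        # first-strand rendering followed by its own reverse complement
        raw <- paste0(p1, anti, rc_p2, p2, sense, rc_p1)
        orient[i] <- "first"
      } else if (first[i]) {
        raw <- paste0(p1, anti, rc_p2)
        orient[i] <- "first"
      } else {
        raw <- paste0(p2, sense, rc_p1)
        orient[i] <- "second"
      }
      seqs[i] <- .mutate_seq(raw, config$sub_rate, config$ins_rate,
                             config$del_rate)
      quals[i] <- strrep("I", nchar(seqs[i]))
    }
    ids <- sprintf("read%06d", seq_len(n))
    list(reads = read_set(ids, seqs, quals),
         truth = data.frame(read_id = ids,
                            transcript_id = names(tx_seq)[tx_i],
                            true_orientation = orient,
                            artifact = art,
                            span_start = sp_start, span_end = sp_end,
                            stringsAsFactors = FALSE))
  })
}

#' Fragmented short-read-like assembly of the truth annotation
#'
#' Emulates the artifactual segmentation of low-depth short-read assembly:
#' with probability `split_prob` a transcript is split into two pieces
#' separated by a gap of at least 100 bases (mono-exon models are cut
#' internally; multi-exon models are split at an intron), and every piece's
#' outer ends are trimmed by 50-200 bases. Each piece becomes its own gene
#' model with a `cov` attribute from the truth expression.
#'
#' @param truth A `transcript_set` with an `expression` column.
#' @param config A [sim_config()] (seed source).
#' @param split_prob Probability of splitting a transcript (default 0.6).
#' @return A `transcript_set` of fragments.
#' @export
make_fragmented_assembly <- function(truth, config, split_prob = 0.6) {
  .with_sim_rng(config$seed, "fragmented", {
    meta <- truth$transcripts
    ex_by_tx <- split(truth$exons, truth$exons$tx)
    ex_rows <- list(); meta_rows <- list()
    emit <- function(e, id, cov) {
      trim <- round(stats::runif(2L, 50, 200))
      e$start0[1L] <- min(e$start0[1L] + trim[1L], e$end0[1L] - 50L)
      k <- nrow(e)
      e$end0[k] <- max(e$end0[k] - trim[2L], e$start0[k] + 50L)
      e$tx <- id
      ex_rows[[length(ex_rows) + 1L]] <<- e
      meta_rows[[length(meta_rows) + 1L]] <<- data.frame(
        id = id, gene_id = id, cov = cov, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(meta))) {
      e <- ex_by_tx[[meta$id[i]]]
      cov <- if (is.null(meta$expression)) 10 else
        round(meta$expression[i] * 5 + 1, 2)
      split <- stats::runif(1L) < split_prob
      k <- nrow(e)
      if (split && k >= 2L) {
        at <- if (k == 2L) 1L else sample.int(k - 1L, 1L)
        emit(e[seq_len(at), , drop = FALSE], paste0(meta$id[i], ".f1"), cov)
        emit(e[(at + 1L):k, , drop = FALSE], paste0(meta$id[i], ".f2"), cov)
      } else if (split && e$end0[1L] - e$start0[1L] >= 900L) {
        mid <- e$start0[1L] +
          sample.int(e$end0[1L] - e$start0[1L] - 600L, 1L) + 250L
        gap <- round(stats::runif(1L, 100, 300))
        e1 <- e; e1$end0 <- mid
        e2 <- e; e2$start0 <- min(mid + gap, e$end0 - 60L)
        emit(e1, paste0(meta$id[i], ".f1"), cov)
        emit(e2, paste0(meta$id[i], ".f2"), cov)
      } else {
        emit(e, paste0(meta$id[i], ".f1"), cov)
      }
    }
    transcript_set(do.call(rbind, ex_rows), do.call(rbind, meta_rows))
  })
}

#' Unstranded, truncated long-read-like assembly of the truth annotation
#'
#' Emulates low-depth unstranded long-read assembly: transcripts are
#' 5'-truncated with probability `trunc_prob` (the 3' end is retained,
#' mirroring the 3' coverage bias of cDNA long reads) and a fraction
#' `flip_frac` of models land on the wrong strand, as happens when
#' unstranded reads are assembled against the opposite strand.
#'
#' @param truth A `transcript_set` with an `expression` column.
#' @param config A [sim_config()] (seed source).
#' @param flip_frac Fraction of models strand-flipped (default 0.07).
#' @param trunc_prob Probability of 5' truncation (default 0.5).
#' @return A `transcript_set`.
#' @export
make_unstranded_truncated_assembly <- function(truth, config,
                                               flip_frac = 0.07,
                                               trunc_prob = 0.5) {
  .with_sim_rng(config$seed, "longread", {
    meta <- truth$transcripts
    ex_by_tx <- split(truth$exons, truth$exons$tx)
    ex_rows <- list(); meta_rows <- list()
    for (i in seq_len(nrow(meta))) {
      e <- ex_by_tx[[meta$id[i]]]
      strand <- meta$strand[i]
      if (stats::runif(1L) < trunc_prob) {
        k <- nrow(e)
        if (k >= 2L) {
          # drop the strand-respecting 5'-most exon
          e <- if (strand == "-") e[-k, , drop = FALSE] else
            e[-1L, , drop = FALSE]
        } else {
          w <- e$end0 - e$start0
          cut <- round(stats::runif(1L, 0.1, 0.3) * w)
          if (strand == "-") e$end0 <- e$end0 - cut else
            e$start0 <- e$start0 + cut
        }
      }
      if (stats::runif(1L) < flip_frac) {
        strand <- if (strand == "-") "+" else "-"
      }
      e$strand <- strand
      e$tx <- paste0(meta$id[i], ".lr")
      ex_rows[[length(ex_rows) + 1L]] <- e
      cov <- if (is.null(meta$expression)) 2 else
        round(meta$expression[i] + 1, 2)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        id = e$tx[1L], gene_id = e$tx[1L], cov = cov,
        stringsAsFactors = FALSE)
    }
    transcript_set(do.call(rbind, ex_rows), do.call(rbind, meta_rows))
  })
}

#' Orientation accuracy of a stranded library against simulator truth
#'
#' Joins the emitted reads of a [strand_library()] run to the simulator's
#' truth table and reports the fraction whose final presentation matches
#' the expected uniform orientation of the output library. The default
#' (second-strand) output converges every read to the p1-headed,
#' first-strand presentation, so an emitted read is correct when its
#' presentation after any SLURP flip equals `first`; a first-strand output
#' expects the opposite.
#'
#' @param stranded The `reads` element of a [strand_library()] result
#'   (carries the `slurp_flipped` column).
#' @param truth The `truth` table of [simulate_reads()].
#' @param output_orientation Orientation the library was emitted in.
#' @param drop_artifacts Exclude truth-flagged artifact reads from the
#'   denominator (mirrors the `--drop-artifacts` pipeline flag).
#' @return A list with `accuracy`, `n`, and a `confusion` table of final
#'   presentation by truth orientation.
#' @export
evaluate_stranding <- function(stranded, truth,
                               output_orientation = c("second_strand",
                                                      "first_strand"),
                               drop_artifacts = FALSE) {
  output_orientation <- match.arg(output_orientation)
  m <- match(stranded$id, truth$read_id)
  if (anyNA(m)) {
    stop("emitted read id missing from truth table: ",
         stranded$id[which(is.na(m))[1L]])
  }
  tr <- truth[m, ]
  keep <- rep(TRUE, nrow(tr))
  if (drop_artifacts) keep <- !tr$artifact
  flip <- stranded$slurp_flipped
  if (is.null(flip)) flip <- rep(FALSE, nrow(stranded))
  final <- ifelse(flip,
                  ifelse(tr$true_orientation == "first", "second", "first"),
                  tr$true_orientation)
  expected <- if (output_orientation == "second_strand") "first" else
    "second"
  list(accuracy = if (any(keep)) mean(final[keep] == expected) else NA_real_,
       n = sum(keep),
       confusion = table(final = final[keep],
                         truth = tr$true_orientation[keep]))
}
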