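gtf_lines <- function() {
  c(paste("chr1\tx\texon\t101\t200\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1"; cov "7.5";', sep = "\t"),
    paste("chr1\tx\texon\t301\t400\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1"; cov "7.5";', sep = "\t"),
    paste("chr1\tx\ttranscript\t101\t400\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"))
}

test_that("GTF coordinates convert to 0-based half-open and round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_lines(), f)
  ts <- parse_gtf(f)
  expect_equal(n_transcripts(ts), 1L)
  expect_equal(ts$exons$start0, c(100L, 300L))
  expect_equal(ts$exons$end0, c(200L, 400L))
  expect_equal(ts$transcripts$cov, 7.5)
  # derived intron chain
  expect_equal(tassel:::intron_chains(ts)[["t1"]],
               cbind(200L, 300L), ignore_attr = TRUE)
  out <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ts, out)
  rt <- parse_gtf(out)
  expect_equal(rt$exons[c("start0", "end0", "strand", "chrom")],
               ts$exons[c("start0", "end0", "strand", "chrom")])
  # written coordinates are the original 1-based inclusive values
  expect_match(readLines(out)[1], "\t101\t200\t")
  # empty file parses to an empty set
  empty <- withr::local_tempfile(fileext = ".gtf")
  file.create(empty)
  expect_equal(n_transcripts(parse_gtf(empty)), 0L)
})

test_that("GTF coordinates agree with an independent reader", {
  skip_if_not_installed("rtracklayer")
  f <- withr::local_tempfile(fileext = ".gtf")
  set.seed(50)
  ts <- random_transcript_set(15)
  write_gtf(ts, f)
  gr <- rtracklayer::import(f, format = "gtf")
  got <- data.frame(
    start0 = as.integer(BiocGenerics::start(gr)) - 1L,
    end0 = as.integer(BiocGenerics::end(gr)),
    tx = as.character(gr$transcript_id))
  got <- got[order(got$tx, got$start0), ]
  want <- ts$exons[order(ts$exons$tx, ts$exons$start0), ]
  expect_equal(got$start0, want$start0)
  expect_equal(got$end0, want$end0)
})

test_that("GTF errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_lines()[1],
               "chr1\tx\texon\t500\t600\t.\t+\t.\tgene_id \"g2\";"), f)
  expect_error(parse_gtf(f), "line 2.*transcript_id")
  writeLines(c(gtf_lines()[1],
               paste("chr2\tx\texon\t301\t400\t.\t+\t.",
                     'gene_id "g1"; transcript_id "t1";', sep = "\t")), f)
  expect_error(parse_gtf(f), "mixed chrom/strand")
})

test_that("transcript_set enforces its invariants", {
  bad <- data.frame(tx = "t", chrom = "c", start0 = 10L, end0 = 10L,
                    strand = "+")
  expect_error(transcript_set(bad), "start0 >= end0")
  over <- data.frame(tx = c("t", "t"), chrom = "c",
                     start0 = c(0L, 50L), end0 = c(60L, 100L), strand = "+")
  expect_error(transcript_set(over), "overlapping exons")
})

mk_ts <- function(..., prefix = "q") {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    data.frame(tx = paste0(prefix, i), chrom = "chr1",
               start0 = sp$exons[, 1], end0 = sp$exons[, 2],
               strand = sp$strand, stringsAsFactors = FALSE)
  })
  transcript_set(do.call(rbind, rows))
}

test_that("class codes follow the stated definitions on constructed cases", {
  ref <- mk_ts(list(exons = rbind(c(100, 500), c(1000, 1500), c(2000, 2600)),
                    strand = "+"), prefix = "r")
  # identity
  q_eq <- mk_ts(list(exons = rbind(c(100, 500), c(1000, 1500), c(2000, 2600)),
                     strand = "+"))
  expect_equal(classify_set(q_eq, ref)$class_code, "=")
  # mono-exon query inside a reference exon, same strand -> contained
  q_c <- mk_ts(list(exons = rbind(c(1100, 1400)), strand = "+"))
  expect_equal(classify_set(q_c, ref)$class_code, "c")
  # strand-flipped copy -> antisense
  q_s <- mk_ts(list(exons = rbind(c(100, 500), c(1000, 1500), c(2000, 2600)),
                    strand = "-"))
  expect_equal(classify_set(q_s, ref)$class_code, "s")
  # wholly inside a reference intron -> 'i'
  q_i <- mk_ts(list(exons = rbind(c(600, 900)), strand = "+"))
  expect_equal(classify_set(q_i, ref)$class_code, "i")
  # empty region -> 'u'
  q_u <- mk_ts(list(exons = rbind(c(9000, 9500)), strand = "+"))
  expect_equal(classify_set(q_u, ref)$class_code, "u")
  # shared junction, not contained (extends past the reference 5' end) -> 'j'
  q_j <- mk_ts(list(exons = rbind(c(50, 500), c(1000, 1200)), strand = "+"))
  expect_equal(classify_set(q_j, ref)$class_code, "j")
  # reference chain is a contiguous sub-chain of a longer query -> 'k'
  q_k <- mk_ts(list(exons = rbind(c(50, 500), c(1000, 1500), c(2000, 2600),
                                  c(3000, 3500)),
                    strand = "+"))
  expect_equal(classify_set(q_k, ref)$class_code, "k")
  # mono-exon reciprocal-overlap '='
  ref_m <- mk_ts(list(exons = rbind(c(1000, 2000)), strand = "+"),
                 prefix = "rm")
  q_m <- mk_ts(list(exons = rbind(c(1100, 2000)), strand = "+"))
  expect_equal(classify_set(q_m, ref_m)$class_code, "=")  # 90% reciprocal
  q_m2 <- mk_ts(list(exons = rbind(c(1500, 2000)), strand = "+"))
  expect_false(classify_set(q_m2, ref_m)$class_code == "=")
})

test_that("classification matches the literal-definition oracle on random sets", {
  set.seed(60)
  for (rep in 1:8) {
    q <- random_transcript_set(sample(5:25, 1), prefix = "q")
    r <- random_transcript_set(sample(5:25, 1), prefix = "r")
    expect_equal(classify_set(q, r)$class_code, oracle_classify(q, r))
    # every transcript matches itself exactly
    expect_true(all(classify_set(r, r)$class_code == "="))
  }
})

test_that("sensitivity and precision arithmetic is exact", {
  set.seed(61)
  ref <- random_transcript_set(10, prefix = "r")
  self <- compare_sets(ref, ref)
  expect_equal(self$transcript$sensitivity, 1)
  expect_equal(self$transcript$precision, 1)
  expect_equal(self$locus$sensitivity, 1)
  expect_equal(self$locus$precision, 1)

  # 5 exact copies + 5 intergenic novels vs 10 references
  ref10 <- transcript_set(data.frame(
    tx = sprintf("r%d", 1:10), chrom = "chr1",
    start0 = seq(0, 90000, by = 10000),
    end0 = seq(0, 90000, by = 10000) + 2000L, strand = "+"))
  q_ex <- ref10$exons[1:5, ]; q_ex$tx <- sprintf("q%d", 1:5)
  q_nov <- data.frame(tx = sprintf("q%d", 6:10), chrom = "chr1",
                      start0 = seq(500000, 540000, by = 10000),
                      end0 = seq(500000, 540000, by = 10000) + 2000L,
                      strand = "+")
  q <- transcript_set(rbind(q_ex, q_nov))
  cmp <- compare_sets(q, ref10)
  expect_equal(cmp$transcript$sensitivity, 0.5)
  expect_equal(cmp$transcript$precision, 0.5)

  emptyq <- transcript_set(ref10$exons[0, ])
  cmp0 <- compare_sets(emptyq, ref10)
  expect_equal(cmp0$transcript$sensitivity, 0)
  expect_equal(cmp0$transcript$precision, 0)
  expect_true(cmp0$transcript$zero_denominator)
})

test_that("end distances respect strand and report cumulative fractions", {
  ref <- mk_ts(list(exons = rbind(c(1000, 2000)), strand = "+"),
               list(exons = rbind(c(5000, 6000)), strand = "-"),
               prefix = "r")
  # query equal to reference: all distances 0
  d0 <- end_distances(ref, ref, "TSS")
  expect_equal(d0$distance, c(0, 0))
  expect_equal(unname(d0$fraction_within), rep(1, 4))
  # +100 shift of a '+' 5' end
  q <- mk_ts(list(exons = rbind(c(1100, 2000)), strand = "+"))
  expect_equal(end_distances(q, ref, "TSS")$distance, 100)
  expect_equal(end_distances(q, ref, "TTS")$distance, 0)
  # on '-' the TSS is the rightmost coordinate
  qm <- mk_ts(list(exons = rbind(c(5000, 5900)), strand = "-"))
  expect_equal(end_distances(qm, ref, "TSS")$distance, -100)
  expect_equal(end_distances(qm, ref, "TTS")$distance, 0)
})

test_that("segmentation counting matches its definition", {
  span <- function(a, b, id) data.frame(tx = id, chrom = "chr1",
                                        start0 = a, end0 = b, strand = "+",
                                        stringsAsFactors = FALSE)
  # two originals under one merged span -> both segmented
  orig <- transcript_set(rbind(span(100, 500, "g1"), span(700, 900, "g2")))
  merged <- transcript_set(span(50, 1000, "m1"))
  expect_equal(count_segmented(orig, merged), 2L)
  # three under one span plus one alone -> 3
  orig2 <- transcript_set(rbind(span(100, 300, "g1"), span(400, 600, "g2"),
                                span(700, 900, "g3"), span(5000, 6000, "g4")))
  merged2 <- transcript_set(rbind(span(50, 1000, "m1"),
                                  span(4900, 6100, "m2")))
  expect_equal(count_segmented(orig2, merged2), 3L)
  # one-to-one mapping -> 0
  merged3 <- transcript_set(rbind(span(100, 300, "m1"), span(400, 600, "m2"),
                                  span(700, 900, "m3"),
                                  span(5000, 6000, "m4")))
  expect_equal(count_segmented(orig2, merged3), 0L)
})
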