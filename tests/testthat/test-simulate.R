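test_that("generators are bit-reproducible from the seed", {
  cfg <- sim_config(seed = 81, genome_size = 1e5, n_genes = 10,
                    n_reads = 50)
  g1 <- make_genome(cfg); g2 <- make_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[[1]]), 1e5)
  a1 <- make_annotation(cfg, g1); a2 <- make_annotation(cfg, g2)
  expect_identical(a1, a2)
  s1 <- simulate_reads(cfg, a1$spikein, a1$spikein_seqs)
  s2 <- simulate_reads(cfg, a2$spikein, a2$spikein_seqs)
  expect_identical(s1, s2)
  # a different seed gives different data
  g3 <- make_genome(sim_config(seed = 82, genome_size = 1e5, n_genes = 10))
  expect_false(identical(g1, g3))
})

test_that("the random genome has near-even base composition", {
  cfg <- sim_config(seed = 83, genome_size = 2e5)
  g <- make_genome(cfg)[[1]]
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / nchar(g)
  expect_lt(abs(gc - 0.5), 0.05)
})

test_that("the annotation respects bounds, ladder structure and isoform rules", {
  cfg <- sim_config(seed = 84, genome_size = 8e5, n_genes = 60,
                    isoform_prob = 0.5)
  g <- make_genome(cfg)
  ann <- make_annotation(cfg, g)
  # default spike-in fixture size is the ERCC mix size
  expect_equal(n_transcripts(ann$spikein), 92L)
  expect_equal(nrow(ann$concentrations), 92L)
  # 2-fold ladder over groups of four
  expect_equal(unique(diff(log2(ann$concentrations$concentration[
    !duplicated(ann$concentrations$group)]))), 1)
  expect_true(all(nchar(ann$spikein_seqs) >= 250 &
                    nchar(ann$spikein_seqs) <= 2000))
  # genes lie within the genome, satisfy the set invariants
  expect_true(all(ann$truth$exons$end0 <= nchar(g[[1]])))
  expect_true(all(ann$truth$exons$start0 >= 0))
  # no same-strand exonic overlap between distinct genes
  ov <- tassel:::exonic_overlaps(ann$truth, same_strand = TRUE)
  gene_of <- ann$truth$transcripts$gene_id[
    match(ov$a, ann$truth$transcripts$id)]
  gene_of_b <- ann$truth$transcripts$gene_id[
    match(ov$b, ann$truth$transcripts$id)]
  expect_true(all(gene_of == gene_of_b))
  # isoform pairs share at least one intron by construction
  chains <- tassel:::intron_chains(ann$truth)
  meta <- ann$truth$transcripts
  for (gid in unique(meta$gene_id[duplicated(meta$gene_id)])) {
    ids <- meta$id[meta$gene_id == gid]
    k1 <- apply(chains[[ids[1]]], 1, paste, collapse = "-")
    k2 <- apply(chains[[ids[2]]], 1, paste, collapse = "-")
    expect_gt(length(intersect(k1, k2)), 0)
  }
})

test_that("error-free reads carry the stated primer geometry", {
  cfg <- sim_config(seed = 85, n_reads = 200, sub_rate = 0, ins_rate = 0,
                    del_rate = 0, artifact_rate = 0)
  g <- make_genome(sim_config(seed = 85, genome_size = 1e5, n_genes = 5))
  ann <- make_annotation(sim_config(seed = 85, genome_size = 1e5,
                                    n_genes = 5), g)
  sim <- simulate_reads(cfg, ann$spikein, ann$spikein_seqs)
  pc <- primer_config()
  first <- sim$truth$true_orientation == "first"
  # first-strand presentations start with p1 and end with rc(p2)
  expect_true(all(startsWith(sim$reads$seq[first], pc$p1)))
  expect_true(all(endsWith(sim$reads$seq[first], revcomp(pc$p2))))
  # second-strand presentations start with p2 and end with rc(p1)
  expect_true(all(startsWith(sim$reads$seq[!first], pc$p2)))
  expect_true(all(endsWith(sim$reads$seq[!first], revcomp(pc$p1))))
  # both presentations occur at roughly the configured rate
  expect_gt(mean(first), 0.35); expect_lt(mean(first), 0.65)
  # truth has exactly one row per read
  expect_equal(sim$truth$read_id, sim$reads$id)

  # error-free artifact reads are perfect palindromes with the primer pair
  cfa <- sim_config(seed = 85, n_reads = 60, sub_rate = 0, ins_rate = 0,
                    del_rate = 0, artifact_rate = 1)
  sima <- simulate_reads(cfa, ann$spikein, ann$spikein_seqs)
  expect_true(all(sima$truth$artifact))
  expect_true(all(detect_terminal_primer_pair(sima$reads, pc)))
  pf <- vapply(sima$reads$seq[1:10], function(s)
    paired_fraction(self_fold(s)), 0, USE.NAMES = FALSE)
  expect_true(all(pf == 1))
})

test_that("artifact injection matches the configured rate and direct-RNA has none", {
  cfg <- sim_config(seed = 86, n_reads = 4000)
  g <- make_genome(sim_config(seed = 86, genome_size = 1e5, n_genes = 5))
  ann <- make_annotation(sim_config(seed = 86, genome_size = 1e5,
                                    n_genes = 5), g)
  sim <- simulate_reads(cfg, ann$spikein, ann$spikein_seqs)
  p_hat <- mean(sim$truth$artifact)
  ci <- 2.58 * sqrt(0.06 * 0.94 / 4000)   # binomial 99% CI at the true rate
  expect_lt(abs(p_hat - 0.06), ci + 1e-9)
  simR <- simulate_reads(sim_config(seed = 86, n_reads = 500,
                                    mode = "direct_RNA"),
                         ann$spikein, ann$spikein_seqs)
  expect_equal(sum(simR$truth$artifact), 0L)
  # direct-RNA reads carry no primers
  expect_false(any(startsWith(simR$reads$seq, primer_config()$p1)))
})

test_that("fragmented assemblies split transcripts into gapped trimmed pieces", {
  cfg <- sim_config(seed = 87, genome_size = 4e5, n_genes = 30)
  g <- make_genome(cfg)
  truth <- make_annotation(cfg, g)$truth
  frag1 <- make_fragmented_assembly(truth, cfg, split_prob = 1)
  # every splittable transcript yields two same-strand pieces within span
  meta <- truth$transcripts
  fmeta <- frag1$transcripts
  for (i in seq_len(nrow(meta))) {
    pieces <- fmeta[startsWith(fmeta$id, paste0(meta$id[i], ".f")), ]
    expect_true(all(pieces$strand == meta$strand[i]))
    expect_true(all(pieces$start0 >= meta$start0[i] &
                      pieces$end0 <= meta$end0[i]))
    if (nrow(pieces) == 2) {
      pieces <- pieces[order(pieces$start0), ]
      expect_gte(pieces$start0[2] - pieces$end0[1], 100L)
    }
  }
  expect_true(all(!is.na(fmeta$cov)))
  # split probability 0 keeps one trimmed model per transcript
  frag0 <- make_fragmented_assembly(truth, cfg, split_prob = 0)
  expect_equal(n_transcripts(frag0), n_transcripts(truth))
  # fragments counted against the consolidated union are segmented
  un <- strand_aware_union(merge_transcriptomes(list(frag1, truth)))
  expect_gt(count_segmented(frag1, un), 0L)
})

test_that("unstranded truncated assemblies flip the configured strand fraction", {
  cfg <- sim_config(seed = 88, genome_size = 4e5, n_genes = 30)
  g <- make_genome(cfg)
  truth <- make_annotation(cfg, g)$truth
  lr0 <- make_unstranded_truncated_assembly(truth, cfg, flip_frac = 0)
  expect_equal(lr0$transcripts$strand[order(lr0$transcripts$id)],
               truth$transcripts$strand[order(truth$transcripts$id)])
  lr1 <- make_unstranded_truncated_assembly(truth, cfg, flip_frac = 1)
  codes <- classify_set(lr1, truth)$class_code
  expect_true(all(codes == "s"))
  # default flip count stays inside exact binomial 99.9% bounds
  lrd <- make_unstranded_truncated_assembly(truth, cfg)
  flipped <- sum(lrd$transcripts$strand[order(lrd$transcripts$id)] !=
                   truth$transcripts$strand[order(truth$transcripts$id)])
  n <- n_transcripts(truth)
  expect_gte(flipped, qbinom(0.0005, n, 0.07))
  expect_lte(flipped, qbinom(0.9995, n, 0.07))
})

test_that("stranding evaluation handles vacuous, chance and error cases", {
  s <- small_sim(seed = 89, n_reads = 200, sub_rate = 0, ins_rate = 0,
                 del_rate = 0, artifact_rate = 0)
  res <- strand_library(s$sim$reads, primer_config())
  ev <- evaluate_stranding(res$reads, s$sim$truth)
  expect_equal(ev$accuracy, 1)    # error-free full-length library
  # random pass-through without stranding sits at chance level
  raw <- s$sim$reads
  raw$slurp_flipped <- rep(FALSE, nrow(raw))
  ev_raw <- evaluate_stranding(raw, s$sim$truth)
  expect_gt(ev_raw$accuracy, 0.35); expect_lt(ev_raw$accuracy, 0.65)
  # unknown read ids are an error
  bad <- res$reads; bad$id[1] <- "nope"
  expect_error(evaluate_stranding(bad, s$sim$truth), "missing from truth")
})
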