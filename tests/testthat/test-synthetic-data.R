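test_that("all generators are pure functions of parameters and seed", {
  a <- sim_transcripts(n = 40, seed = 5)
  b <- sim_transcripts(n = 40, seed = 5)
  expect_equal(a, b)
  expect_false(identical(a$transcripts$seq,
                         sim_transcripts(n = 40, seed = 6)$transcripts$seq))

  expect_equal(sim_hits(a$truth, seed = 2), sim_hits(a$truth, seed = 2))
  expect_equal(sim_expression(n_genes = 20, seed = 3),
               sim_expression(n_genes = 20, seed = 3))
  expect_equal(sim_read_alignments(n = 50, seed = 4),
               sim_read_alignments(n = 50, seed = 4))

  # byte-identical FASTA from the same seed
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_fasta(a$transcripts, f1)
  write_fasta(b$transcripts, f2)
  expect_equal(readLines(f1), readLines(f2))
})

test_that("truth tables are 1:1 with emitted records and carry no header leakage", {
  sim <- sim_transcripts(n = 60, seed = 9)
  expect_equal(sim$truth$id, sim$transcripts$id)
  expect_equal(sim$truth$length, nchar(sim$transcripts$seq))
  expect_false(any(grepl("contam|sl|taxid", sim$transcripts$id, ignore.case = TRUE)))
})

test_that("planted SL remnants are recovered at the planted rate", {
  none <- sim_transcripts(n = 200, sl_fraction = 0, seed = 10)
  m0 <- scan_sl(none$transcripts, sl_test_seq, 12)
  # background 12-mer collisions are essentially absent at this scale
  expect_lte(nrow(m0), 1)

  sim <- sim_transcripts(n = 500, sl_fraction = 0.2, seed = 11)
  m <- scan_sl(sim$transcripts, sl_test_seq, 12)
  detected <- length(unique(m$transcript_id))
  planted <- sum(sim$truth$has_sl)
  expect_equal(detected, planted)
  ci <- 0.2 + c(-1, 1) * 1.96 * sqrt(0.2 * 0.8 / 500)
  expect_gte(detected / 500, ci[1])
  expect_lte(detected / 500, ci[2])
  # orientations match the planted truth
  tr <- dplyr::inner_join(m, sim$truth, by = c(transcript_id = "id"))
  expect_true(all(tr$orientation == tr$sl_orientation))
})

test_that("simulated hit tables round-trip through the BLAST parser", {
  sim <- sim_transcripts(n = 20, seed = 12)
  hits <- sim_hits(sim$truth, seed = 13)
  f <- withr::local_tempfile()
  flat <- dplyr::mutate(hits,
                        evalue = formatC(evalue, format = "e", digits = 3))
  utils::write.table(flat, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- read_blast6(f)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$subject_taxid, hits$subject_taxid)
  expect_equal(back$bit_score, hits$bit_score, tolerance = 1e-6)
})

test_that("simulated expression has the study-design shape and planted labels", {
  sim <- sim_expression(n_genes = 50, k_clusters = 5, seed = 14)
  expect_equal(ncol(sim$tpm) - 1L, 23L)  # 23 samples
  expect_equal(nrow(sim$tpm), 50L)
  expect_true(all(as.matrix(sim$tpm[-1]) > 0))
  expect_equal(sort(unique(sim$gene_truth$cluster)), 1:5)
  expect_equal(unname(table(sim$samples$study)),
               table(c(rep("A", 6), rep("B", 2), "C", rep("D", 10), rep("E", 4))),
               ignore_attr = TRUE)
})

test_that("zero-amplitude expression carries no cluster structure", {
  sim <- sim_expression(n_genes = 30, k_clusters = 4, amplitude = 0,
                        noise_sd = 0.5, seed = 15)
  z <- transform_expression(sim$tpm)
  d <- expr_dissimilarity(z)
  # absolute correlations stay modest everywhere: no planted signal
  offdiag <- abs(d$r)[upper.tri(d$r)]
  expect_lt(stats::quantile(offdiag, 0.99), 0.9)
})

test_that("simulated read alignments straddle the threshold exactly as planted", {
  sim <- sim_read_alignments(n = 400, exceed_fraction = 0.3, seed = 16)
  out <- filter_reads(sim$alignments)
  expect_equal(out$removed, sim$truth$exceeds)
  expect_equal(sum(out$removed), 0.3 * 400)

  none <- sim_read_alignments(n = 100, exceed_fraction = 0, seed = 17)
  expect_equal(sum(filter_reads(none$alignments)$removed), 0)

  # SAM round trip preserves what the filter needs
  f <- withr::local_tempfile()
  write_sam(sim$alignments, f)
  back <- read_sam_scores(f)
  expect_equal(back$read_id, sim$alignments$read_id)
  expect_equal(back$aln_score, sim$alignments$aln_score)
  expect_equal(back$mapped, sim$alignments$mapped)
  expect_equal(filter_reads(back)$removed, sim$truth$exceeds)
})
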