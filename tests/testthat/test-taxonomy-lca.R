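tax <- toy_taxonomy()

lca_hits <- function(bits, taxids = NA_integer_) {
  tibble::tibble(
    query_id = "q", subject_id = paste0("s", seq_along(bits)),
    pct_identity = 90, aln_length = 100, mismatches = 0, gap_opens = 0,
    q_start = 1, q_end = 100, s_start = 1, s_end = 100,
    evalue = 1e-30, bit_score = bits,
    subject_taxid = rep_len(taxids, length(bits)),
    subject_sciname = NA_character_
  )
}

test_that("select_lca_hits applies the floor and the inclusive top fraction", {
  expect_equal(select_lca_hits(lca_hits(c(100, 96, 94, 85)))$bit_score, c(100, 96))
  expect_equal(select_lca_hits(lca_hits(c(82, 79)))$bit_score, 82)
  expect_equal(nrow(select_lca_hits(lca_hits(c(70, 60)))), 0L)
  # boundary is inclusive: 95 is within 95% of 100
  expect_equal(select_lca_hits(lca_hits(c(100, 95)))$bit_score, c(100, 95))
})

test_that("compute_lca matches the ancestor-set oracle on the fixture taxonomy", {
  expect_equal(compute_lca(9606L, tax), 9606L)
  # two kinetoplastid genera -> their order
  expect_equal(compute_lca(c(5691L, 5658L), tax), 5653L)
  # bacterium + plant -> cellular organisms
  expect_equal(compute_lca(c(562L, 3055L), tax), 131567L)
  expect_error(compute_lca(999999L, tax), "999999")

  withr::local_seed(31)
  for (i in 1:25) {
    taxa <- sample(tax$taxid, sample(2:6, 1))
    expect_equal(compute_lca(taxa, tax), oracle_lca(taxa, tax))
  }
})

test_that("compute_lca is order-invariant and idempotent under its own result", {
  withr::local_seed(32)
  for (i in 1:10) {
    taxa <- sample(tax$taxid, 4)
    l <- compute_lca(taxa, tax)
    expect_equal(compute_lca(rev(taxa), tax), l)
    expect_equal(compute_lca(c(taxa, l), tax), l)
  }
})

test_that("broad groups follow the specific-before-fallback precedence", {
  expect_equal(classify_broad_group(5691L, tax), "Kinetoplastida")
  expect_equal(classify_broad_group(3055L, tax), "Viridiplantae")
  expect_equal(classify_broad_group(9606L, tax), "other Eukaryota")
  expect_equal(classify_broad_group(562L, tax), "Bacteria")
  expect_equal(classify_broad_group(2287L, tax), "Archaea")
  expect_equal(classify_broad_group(131567L, tax), "other cellular organisms")
  expect_equal(classify_broad_group(NA_integer_, tax), "unclassified")
})

test_that("assign_lca recovers planted groups and ignores sub-floor noise", {
  sim <- sim_transcripts(n = 150, contaminant_fraction = 0.2, seed = 21)
  hits <- sim_hits(sim$truth, tax, seed = 22)
  res <- assign_lca(hits, tax)
  truth_group <- classify_broad_group(sim$truth$source_taxid, tax)
  got <- res$broad_group[match(sim$truth$id, res$transcript_id)]
  expect_gte(mean(got == truth_group), 0.99)

  # adding a hit below the bit-score floor never changes the assignment
  one <- hits[hits$query_id == hits$query_id[1], ]
  below <- one[1, ]
  below$bit_score <- 60
  below$subject_taxid <- 562L
  expect_equal(
    assign_lca(dplyr::bind_rows(one, below), tax)$taxid,
    assign_lca(one, tax)$taxid
  )
})

test_that("noise hits within the top fraction pull the LCA upward", {
  sim <- sim_transcripts(n = 40, contaminant_fraction = 0, seed = 23)
  close_hits <- sim_hits(sim$truth, tax, noise_gap = 0.01, noise_spread = 0.03,
                         seed = 24)
  res <- assign_lca(close_hits, tax)
  # with noise hits inside the 95% band the LCA must climb above the species
  expect_true(all(res$taxid != 3039L))
})

test_that("hits without taxids are skipped with a warning, all-missing is unclassified", {
  h <- lca_hits(c(100, 99), taxids = NA_integer_)
  expect_warning(res <- assign_lca(h, tax), "without subject taxid")
  expect_equal(res$broad_group, "unclassified")
  expect_equal(res$n_support_hits, 0L)
})

test_that("the organelle rule demands near-identity and exact length agreement", {
  base <- tibble::tibble(
    query_id = "q", subject_id = "s", pct_identity = 99.5, aln_length = 300,
    mismatches = 0, gap_opens = 0, q_start = 1, q_end = 300, s_start = 1,
    s_end = 300, evalue = 0, bit_score = 500,
    query_length = 300, subject_length = 300
  )
  expect_true(is_organelle_encoded(base))
  longer <- dplyr::mutate(base, pct_identity = 100, subject_length = 310)
  expect_false(is_organelle_encoded(longer))
  low_id <- dplyr::mutate(base, pct_identity = 98.9)
  expect_false(is_organelle_encoded(low_id))
  expect_error(is_organelle_encoded(dplyr::select(base, -query_length)),
               "query_length")
})
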