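# Seeded generators producing synthetic inputs with the statistical
# structure the analyses assume: transcripts with a GC gradient and planted
# 5' SL prefixes, contaminants with distinct composition and foreign
# taxonomy, hit tables consistent with a toy taxonomy, SAM-like alignments
# straddling the read-removal threshold, and TPM matrices with planted
# co-expression clusters and an optional study-level batch effect. All
# generators are pure functions of (parameters, seed); planted truth lives
# only in the returned truth tables, never in record headers.

#' Toy taxonomy fixture
#'
#' A small tree with all broad groups represented (Viridiplantae,
#' Kinetoplastida, other Eukaryota, Bacteria, Archaea), rooted at
#' "cellular organisms", using real NCBI taxids for recognisability.
#'
#' @return A taxonomy tibble (see [taxonomy_table()]).
#' @export
toy_taxonomy <- function() {
  taxonomy_table(
    taxid  = c(1L, 131567L, 2L, 2157L, 2759L, 33090L, 3055L, 3702L,
               33682L, 5653L, 5690L, 5691L, 5658L, 3038L, 3039L,
               33154L, 9606L, 4932L, 9940L, 6239L, 562L, 1117L, 2287L),
    parent = c(1L, 1L, 131567L, 131567L, 131567L, 2759L, 33090L, 33090L,
               2759L, 33682L, 5653L, 5690L, 5653L, 33682L, 3038L,
               2759L, 33154L, 33154L, 33154L, 33154L, 2L, 2L, 2157L),
    rank = c("no rank", "no rank", "superkingdom", "superkingdom",
             "superkingdom", "kingdom", "species", "species",
             "phylum", "order", "genus", "species", "genus",
             "genus", "species", "clade", "species", "species",
             "species", "species", "species", "phylum", "genus"),
    name = c("root", "cellular organisms", "Bacteria", "Archaea",
             "Eukaryota", "Viridiplantae", "Chlamydomonas reinhardtii",
             "Arabidopsis thaliana", "Euglenozoa", "Kinetoplastida",
             "Trypanosoma", "Trypanosoma brucei", "Leishmania",
             "Euglena", "Euglena gracilis", "Opisthokonta",
             "Homo sapiens", "Saccharomyces cerevisiae", "Ovis aries",
             "Caenorhabditis elegans", "Escherichia coli",
             "Cyanobacteria", "Sulfolobus")
  )
}

#' Study design of the emulated expression compendium
#'
#' The 23-sample / 5-study layout of the culture-condition compendium:
#' studies A-E with 6/2/1/10/4 samples and trophic regimes F (fermentative),
#' H (heterotrophic), M (mixotrophic), P (phototrophic).
#'
#' @return A tibble with `sample_id`, `study`, `condition`.
#' @export
study_design <- function() {
  tibble::tibble(
    study = c(rep("A", 6), rep("B", 2), "C", rep("D", 10), rep("E", 4)),
    condition = c(
      "H", "H", "H", "M", "M", "M",   # A
      "M", "H",                        # B
      "M",                             # C
      "M", "M", "M", "M", "F", "F", "F", "F", "F", "F",  # D
      "P", "H", "M", "M"               # E
    )
  ) |>
    dplyr::group_by(.data$study) |>
    dplyr::mutate(sample_id = paste0(.data$study, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "study", "condition")
}

random_seq <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a transcript set with planted structure
#'
#' Lengths are log-normal around `mean_len`; per-transcript GC targets are
#' uniform over `gc_range` (a composition gradient); a fraction of
#' transcripts receive the SL sequence (or a suffix of it, >= 12 nt)
#' planted at the 5' end, half of them in reverse-complement orientation;
#' a fraction are contaminants with distinct GC (`contaminant_gc`) and a
#' foreign source taxid from the toy taxonomy.
#'
#' @param n Number of transcripts.
#' @param mean_len Mean transcript length in bases.
#' @param gc_range Range of target GC fractions for genuine transcripts.
#' @param sl_fraction Fraction of transcripts with a planted SL remnant.
#' @param contaminant_fraction Fraction of contaminant transcripts.
#' @param sl_seq SL sequence to plant (A/C/G/T).
#' @param contaminant_gc GC target of contaminant transcripts.
#' @param seed Integer seed.
#' @return A list with `transcripts` (tibble `id`, `seq`) and `truth`
#'   (tibble `id`, `is_contaminant`, `source_taxid`, `has_sl`,
#'   `sl_orientation`, `sl_len`, `gc_target`, `length`).
#' @export
sim_transcripts <- function(n = 500L, mean_len = 600L,
                            gc_range = c(0.40, 0.70),
                            sl_fraction = 0.1, contaminant_fraction = 0.05,
                            sl_seq = "ACACTTTCTGAGTGTCTATTTTTG",
                            contaminant_gc = 0.30, seed = 1L) {
  stopifnot(sl_fraction >= 0, sl_fraction <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1)
  sl_seq <- normalize_seq(sl_seq)
  foreign <- c(9606L, 4932L, 562L, 9940L, 6239L)
  withr::with_seed(seed, {
    len <- pmax(100L, as.integer(round(stats::rlnorm(
      n, meanlog = log(mean_len) - 0.35^2 / 2, sdlog = 0.35
    ))))
    contam <- stats::runif(n) < contaminant_fraction
    gc <- stats::runif(n, gc_range[1], gc_range[2])
    gc[contam] <- stats::rnorm(sum(contam), contaminant_gc, 0.02)
    taxid <- ifelse(contam, sample(foreign, n, replace = TRUE), 3039L)
    has_sl <- stats::runif(n) < sl_fraction
    orient <- ifelse(has_sl,
                     ifelse(stats::runif(n) < 0.5, "forward", "reverse"),
                     NA_character_)
    full <- stats::runif(n) < 0.5
    sl_len <- ifelse(
      has_sl,
      ifelse(full, nchar(sl_seq),
             sample(12:nchar(sl_seq), n, replace = TRUE)),
      NA_integer_
    )
    seqs <- vapply(seq_len(n), function(i) {
      s <- random_seq(len[i], gc[i])
      if (!has_sl[i]) return(s)
      piece <- substr(sl_seq, nchar(sl_seq) - sl_len[i] + 1L, nchar(sl_seq))
      if (orient[i] == "forward") {
        paste0(piece, substr(s, sl_len[i] + 1L, nchar(s)))
      } else {
        # reverse orientation: the revcomp of the transcript starts with the
        # SL remnant, i.e. the transcript ends with revcomp(piece)
        paste0(substr(s, 1L, nchar(s) - sl_len[i]), revcomp(piece))
      }
    }, character(1))
    ids <- sprintf("TR%05d", seq_len(n))
    list(
      transcripts = tibble::tibble(id = ids, seq = seqs),
      truth = tibble::tibble(
        id = ids, is_contaminant = contam, source_taxid = taxid,
        has_sl = has_sl, sl_orientation = orient,
        sl_len = as.integer(sl_len), gc_target = gc, length = nchar(seqs)
      )
    )
  })
}

#' Simulate a BLAST-like hit table consistent with planted taxonomy
#'
#' Each transcript receives a best hit to its planted source taxon near
#' `top_bit`, plus `n_noise` hits to random other taxa whose bit scores sit
#' at least `noise_gap` below the query's best bit score, so the MEGAN-like
#' top-fraction rule excludes them. Setting `noise_gap` below
#' `1 - top_fraction` creates controlled violations where the LCA climbs.
#'
#' @param truth Truth table from [sim_transcripts()] (needs `id`,
#'   `source_taxid`).
#' @param taxonomy Taxonomy tibble (default [toy_taxonomy()]).
#' @param top_bit Approximate best-hit bit score.
#' @param n_noise Noise hits per query.
#' @param noise_gap Minimum relative bit-score gap of noise hits below the
#'   best hit (default 0.06).
#' @param noise_spread Width of the gap range: noise gaps are uniform in
#'   `[noise_gap, noise_gap + noise_spread)` (default 0.09).
#' @param seed Integer seed.
#' @return A hit tibble in the [read_blast6()] layout (with
#'   `subject_taxid`, `subject_sciname`).
#' @export
sim_hits <- function(truth, taxonomy = toy_taxonomy(), top_bit = 200,
                     n_noise = 3L, noise_gap = 0.06, noise_spread = 0.09,
                     seed = 1L) {
  leaves <- setdiff(taxonomy$taxid, taxonomy$parent)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      q <- truth$id[i]
      best_bit <- top_bit * stats::runif(1, 0.97, 1.03)
      others <- sample(setdiff(leaves, truth$source_taxid[i]),
                       n_noise, replace = TRUE)
      noise_bit <- best_bit * (1 - noise_gap - stats::runif(n_noise, 0, noise_spread))
      taxids <- c(truth$source_taxid[i], others)
      bits <- c(best_bit, noise_bit)
      tibble::tibble(
        query_id = q,
        subject_id = sprintf("ref_%d_%d", taxids, seq_along(taxids)),
        pct_identity = c(stats::runif(1, 95, 100), stats::runif(n_noise, 70, 85)),
        aln_length = sample(80:400, n_noise + 1L, replace = TRUE),
        mismatches = 0, gap_opens = 0,
        q_start = 1, q_end = 100, s_start = 1, s_end = 100,
        evalue = 10^(-bits / 3),
        bit_score = bits,
        subject_taxid = taxids,
        subject_sciname = taxonomy$name[match(taxids, taxonomy$taxid)]
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a TPM matrix with planted co-expression clusters
#'
#' Gene profiles are cluster archetypes (iid standard-normal sample
#' patterns), possibly sign-flipped per gene (to exercise the `1 - r^2`
#' dissimilarity), plus a per-gene study-level batch shift and iid noise;
#' TPM values are `2^profile` scaled positive.
#'
#' @param n_genes Number of genes.
#' @param k_clusters Number of planted clusters (>= 2).
#' @param samples Sample sheet (default [study_design()]: 23 samples over
#'   5 studies).
#' @param amplitude Archetype amplitude (0 gives pure noise).
#' @param noise_sd Iid noise standard deviation.
#' @param batch_sd Standard deviation of per-gene, per-study batch shifts.
#' @param seed Integer seed.
#' @return A list with `tpm` (wide tibble `gene_id` + one column per
#'   sample), `gene_truth` (tibble `gene_id`, `cluster`, `sign`) and
#'   `samples` (the sample sheet).
#' @export
sim_expression <- function(n_genes = 200L, k_clusters = 5L,
                           samples = study_design(), amplitude = 1,
                           noise_sd = 0.5, batch_sd = 0, seed = 1L) {
  if (k_clusters < 2L) abort("`k_clusters` must be >= 2")
  S <- nrow(samples)
  withr::with_seed(seed, {
    arch <- matrix(stats::rnorm(k_clusters * S), k_clusters, S)
    cl <- rep(seq_len(k_clusters), length.out = n_genes)
    sign <- sample(c(-1, 1), n_genes, replace = TRUE)
    batch <- matrix(stats::rnorm(n_genes * length(unique(samples$study)),
                                 sd = batch_sd),
                    n_genes, length(unique(samples$study)),
                    dimnames = list(NULL, unique(samples$study)))
    profile <- sign * amplitude * arch[cl, , drop = FALSE] +
      batch[, samples$study, drop = FALSE] +
      matrix(stats::rnorm(n_genes * S, sd = noise_sd), n_genes, S)
    tpm <- 2^profile * 10
    colnames(tpm) <- samples$sample_id
    ids <- sprintf("G%04d", seq_len(n_genes))
    rownames(tpm) <- ids
    list(
      tpm = rebuild_expr(tpm, "gene_id"),
      gene_truth = tibble::tibble(gene_id = ids, cluster = cl, sign = sign),
      samples = samples
    )
  })
}

#' Simulate read alignments straddling the removal threshold
#'
#' Generates `n` reads of length `read_len`; a planted fraction of the
#' mapped reads receive integer alignment scores strictly above the
#' removal threshold `20 + 8 ln(L)`, the rest at or below it, so the
#' removed fraction equals the planted truth exactly.
#'
#' @param n Number of reads.
#' @param read_len Read length in bases.
#' @param exceed_fraction Fraction of reads (of `n`) whose score exceeds
#'   the threshold.
#' @param unmapped_fraction Fraction of unmapped reads (kept regardless).
#' @param seed Integer seed.
#' @return A list with `alignments` (tibble `read_id`, `read_length`,
#'   `aln_score`, `mapped`, plus `seq` for SAM export) and `truth`
#'   (tibble `read_id`, `mapped`, `exceeds`).
#' @export
sim_read_alignments <- function(n = 1000L, read_len = 100L,
                                exceed_fraction = 0.3,
                                unmapped_fraction = 0.05, seed = 1L) {
  thr <- read_removal_threshold(read_len)
  n_un <- round(n * unmapped_fraction)
  n_ex <- round(n * exceed_fraction)
  if (n_ex + n_un > n) abort("exceed and unmapped fractions exceed 1")
  withr::with_seed(seed, {
    status <- sample(c(rep("unmapped", n_un), rep("exceed", n_ex),
                       rep("keep", n - n_un - n_ex)))
    score <- ifelse(
      status == "exceed",
      floor(thr) + 1L + sample(0:15, n, replace = TRUE),
      floor(thr) - sample(0:15, n, replace = TRUE)
    )
    score[status == "unmapped"] <- NA_real_
    ids <- sprintf("read%05d", seq_len(n))
    seqs <- vapply(seq_len(n), function(i) random_seq(read_len, 0.5), character(1))
    list(
      alignments = tibble::tibble(
        read_id = ids, read_length = read_len,
        aln_score = score, mapped = status != "unmapped", seq = seqs
      ),
      truth = tibble::tibble(
        read_id = ids, mapped = status != "unmapped",
        exceeds = status == "exceed"
      )
    )
  })
}

#' Write simulated alignments as a minimal SAM file
#'
#' Emits unaligned-style records carrying only what the read filter needs:
#' the unmapped flag, the sequence, and the `AS:i` tag on mapped records.
#'
#' @param alignments Tibble from [sim_read_alignments()] (needs `read_id`,
#'   `aln_score`, `mapped`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path) {
  recs <- vapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    flag <- if (a$mapped) 0L else 4L
    base <- paste(a$read_id, flag, "*", 0, 255, "*", "*", 0, 0,
                  a$seq, "*", sep = "\t")
    if (a$mapped) paste0(base, "\tAS:i:", as.integer(a$aln_score)) else base
  }, character(1))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", recs), path)
  invisible(path)
}
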