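# Composition analysis: tetranucleotide-frequency (TNF) profiles, GC-rank
# partitioning, and repeated sub-sampled PCA. Composition signatures are a
# classic screen for sequences of foreign origin; here the forward strand
# only is counted (no reverse-complement canonicalisation) and frequencies
# are normalised per transcript.

kmer4_names <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b4 = b, b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4)  # lexicographic AAAA..TTTT
}

#' Tetranucleotide frequencies of one sequence
#'
#' Counts all overlapping 4-mers (step 1) composed solely of A/C/G/T and
#' divides by the number of counted 4-mers. Windows containing ambiguity
#' codes are skipped. If no valid 4-mer exists the profile is undefined and
#' a vector of `NA` is returned.
#'
#' @param seq A single nucleotide sequence of length >= 4.
#' @return A named numeric vector of 256 frequencies (AAAA..TTTT,
#'   lexicographic) summing to 1, or all-`NA` when undefined.
#' @export
#' @examples
#' head(sort(tnf("ACGTACGT"), decreasing = TRUE))
tnf <- function(seq) {
  if (length(seq) != 1L) abort("`tnf()` takes a single sequence")
  seq <- normalize_seq(seq)
  if (nchar(seq) < 4L) abort("sequence must be at least 4 bases long")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(gsub("[^ACGT]", "N", seq)), width = 4L, step = 1L
  )
  total <- sum(counts)
  if (total == 0L) {
    return(setNames(rep(NA_real_, 256L), kmer4_names()))
  }
  counts / total
}

#' TNF and GC profiles for a transcript set
#'
#' @param transcripts Data frame with columns `id` and `seq`.
#' @return A wide tibble: `transcript_id`, `gc` (per-sequence GC fraction),
#'   `n_words` (number of counted 4-mers), then 256 frequency columns
#'   AAAA..TTTT. Undefined profiles have `NA` frequencies.
#' @export
tnf_profiles <- function(transcripts) {
  check_transcripts(transcripts)
  seqs <- normalize_seq(transcripts$seq)
  if (any(nchar(seqs) < 4L)) {
    abort("all sequences must be at least 4 bases long to profile")
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(gsub("[^ACGT]", "N", seqs)), width = 4L, step = 1L
  )
  total <- rowSums(counts)
  freq <- counts / ifelse(total == 0L, NA_real_, total)
  out <- tibble::tibble(
    transcript_id = transcripts$id,
    gc = gc_fraction(seqs),
    n_words = as.integer(total)
  )
  dplyr::bind_cols(out, tibble::as_tibble(freq))
}

#' Partition transcripts into GC-rank classes
#'
#' Ranks profiles by GC ascending (stable: ties keep input order) and splits
#' them into `n_parts` contiguous blocks whose sizes differ by at most one;
#' any remainder goes to the lowest-GC blocks.
#'
#' @param profiles Tibble with a `gc` column (e.g. from [tnf_profiles()]).
#' @param n_parts Number of partitions (default 4).
#' @return The input with an added integer column `gc_partition` (1 =
#'   lowest GC).
#' @export
gc_partition <- function(profiles, n_parts = 4L) {
  n <- nrow(profiles)
  if (n < n_parts) abort("fewer profiles than partitions")
  ord <- order(profiles$gc)  # radix sort: stable, ties keep input order
  sizes <- rep(n %/% n_parts, n_parts)
  r <- n %% n_parts
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  labels <- integer(n)
  labels[ord] <- rep(seq_len(n_parts), times = sizes)
  profiles$gc_partition <- labels
  profiles
}

# PCA with the sign convention that each component's largest-magnitude
# loading is positive.
pca_signed <- function(mat) {
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  p
}

#' Repeated sub-sampled PCA on TNF profiles
#'
#' Draws `reps` sub-samples of `n` transcripts without replacement (seeds
#' `seed + 0 .. seed + reps - 1`) and computes a covariance PCA (centering
#' only, no unit-variance scaling: frequencies are commensurate) on each.
#' Undefined profiles are excluded. Each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param profiles Output of [tnf_profiles()] (optionally after
#'   [gc_partition()]; extra columns are carried through).
#' @param n Sub-sample size (default 1000; all profiles if fewer).
#' @param reps Number of repeated PCAs (default 10).
#' @param seed Integer seed for the first repeat.
#' @return An object of class `tnf_pca`: a tibble with `transcript_id`,
#'   `rep`, `PC1`, `PC2`, `gc` (plus `gc_partition` when present), with an
#'   `explained_variance` attribute (tibble `rep`, `pc1`, `pc2`).
#' @export
tnf_pca <- function(profiles, n = 1000L, reps = 10L, seed = 1L) {
  kmers <- kmer4_names()
  if (!all(kmers %in% names(profiles))) {
    abort("`profiles` must contain the 256 TNF columns (see `tnf_profiles()`)")
  }
  defined <- !is.na(profiles[[kmers[1]]])
  profiles <- profiles[defined, , drop = FALSE]
  if (nrow(profiles) < 2L) abort("need at least 2 defined profiles")
  mat <- as.matrix(profiles[kmers])
  extra <- intersect("gc_partition", names(profiles))
  scores <- vector("list", reps)
  evar <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- withr::with_seed(seed + r - 1L, {
      if (nrow(mat) > n) sample(nrow(mat), n) else seq_len(nrow(mat))
    })
    sub <- mat[idx, , drop = FALSE]
    if (all(abs(sweep(sub, 2, colMeans(sub))) < 1e-12)) {
      sc <- matrix(0, nrow(sub), 2)
      ev <- c(0, 0)
    } else {
      p <- pca_signed(sub)
      sc <- p$x[, 1:2, drop = FALSE]
      tot <- sum(p$sdev^2)
      ev <- (p$sdev[1:2]^2) / tot
    }
    scores[[r]] <- dplyr::bind_cols(
      tibble::tibble(
        transcript_id = profiles$transcript_id[idx],
        rep = r, PC1 = sc[, 1], PC2 = sc[, 2],
        gc = profiles$gc[idx]
      ),
      profiles[idx, extra, drop = FALSE]
    )
    evar[[r]] <- tibble::tibble(rep = r, pc1 = ev[1], pc2 = ev[2])
  }
  out <- dplyr::bind_rows(scores)
  attr(out, "explained_variance") <- dplyr::bind_rows(evar)
  class(out) <- c("tnf_pca", class(out))
  out
}

#' @rdname tnf_pca
#' @param object,x A `tnf_pca` object.
#' @param ... Unused.
#' @export
glance.tnf_pca <- function(x, ...) {
  ev <- attr(x, "explained_variance")
  tibble::tibble(
    reps = max(x$rep), n_per_rep = sum(x$rep == 1L),
    mean_pc1_var = mean(ev$pc1), mean_pc2_var = mean(ev$pc2)
  )
}

#' @rdname tnf_pca
#' @export
autoplot.tnf_pca <- function(object, ...) {
  colour_var <- if ("gc_partition" %in% names(object)) "gc_partition" else "gc"
  ggplot2::ggplot(object, ggplot2::aes(
    .data$PC1, .data$PC2, colour = .data[[colour_var]]
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$rep)) +
    ggplot2::labs(
      x = "PC1", y = "PC2", colour = colour_var,
      title = "Sub-sampled PCA of tetranucleotide frequencies"
    )
}
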