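# Length/GC summary statistics of a transcript set.

#' N[z] contig length
#'
#' The minimum contig length needed to cover z% of the total assembly
#' length: sort lengths descending and return the length at which the
#' cumulative sum first reaches >= z% of the total (the common N50
#' convention, generalised to any z).
#'
#' @param lengths Positive integer vector of contig lengths.
#' @param z Coverage percentage in (0, 100].
#' @return A single length in bases.
#' @export
#' @examples
#' compute_nxx(c(400, 300, 200, 100), 50)
compute_nxx <- function(lengths, z) {
  if (length(lengths) == 0L) abort("`lengths` is empty")
  if (any(lengths < 1)) abort("all lengths must be >= 1")
  check_scalar_number(z, "z")
  if (z <= 0 || z > 100) abort("`z` must be in (0, 100]")
  sorted <- sort(lengths, decreasing = TRUE)
  threshold <- z / 100 * sum(lengths)
  sorted[which(cumsum(sorted) >= threshold)[1]]
}

#' GC fraction of nucleotide sequences
#'
#' (#G + #C) / (#A + #C + #G + #T); IUPAC ambiguity codes are excluded from
#' both numerator and denominator. A sequence with no unambiguous base
#' yields `NA`, not 0.
#'
#' @param seq Character vector of sequences.
#' @return Numeric vector of fractions in \[0, 1\] (or `NA`).
#' @export
#' @examples
#' gc_fraction(c("ATAT", "GCGC", "ACGTN"))
gc_fraction <- function(seq) {
  seq <- normalize_seq(seq)
  gc <- stringr::str_count(seq, "[GC]")
  acgt <- stringr::str_count(seq, "[ACGT]")
  ifelse(acgt == 0L, NA_real_, gc / acgt)
}

#' Summarise a transcript set
#'
#' Assembly-level summary: sequence counts, length statistics, N\[z\]
#' values and pooled GC. Pooled GC is base-weighted over the whole set
#' (the GC of the transcriptome as a whole), not the mean of per-sequence
#' GC values. Size-class counts use length < 200 (strict) and
#' length > 1,000 / > 10,000 (strict).
#'
#' @param transcripts Data frame with columns `id` and `seq`.
#' @param nxx Integer vector of N\[z\] levels to report.
#' @return A one-row tibble with columns `n_seq`, `min_len`, `max_len`,
#'   `mean_len` (exact), `mean_len_int` (integer-rounded for reporting),
#'   `total_len`, `n_below_200`, `n_above_1k`, `n_above_10k`, one `n<z>`
#'   column per requested level, and `gc_pct`.
#' @export
summarize_assembly <- function(transcripts, nxx = c(90, 70, 50, 30, 10)) {
  check_transcripts(transcripts)
  if (nrow(transcripts) == 0L) abort("`transcripts` is empty")
  seqs <- normalize_seq(transcripts$seq)
  len <- nchar(seqs)
  gc <- stringr::str_count(seqs, "[GC]")
  acgt <- stringr::str_count(seqs, "[ACGT]")
  nxx <- sort(unique(as.integer(nxx)), decreasing = TRUE)
  nxx_vals <- vapply(nxx, function(z) compute_nxx(len, z), numeric(1))
  out <- tibble::tibble(
    n_seq = length(len),
    min_len = min(len), max_len = max(len),
    mean_len = mean(len), mean_len_int = as.integer(round(mean(len))),
    total_len = sum(len),
    n_below_200 = sum(len < 200L),
    n_above_1k = sum(len > 1000L),
    n_above_10k = sum(len > 10000L)
  )
  for (i in seq_along(nxx)) out[[paste0("n", nxx[i])]] <- nxx_vals[i]
  out$gc_pct <- if (sum(acgt) == 0L) NA_real_ else 100 * sum(gc) / sum(acgt)
  out
}
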