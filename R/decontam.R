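# Contamination screening of assembled transcripts and score-based read
# filtering. Transcript-level screening works on best BLAST hits against a
# broad nucleotide database; read-level filtering removes reads aligning to
# flagged contaminant genomes with a score above a length-dependent
# threshold. Removal is reported in reads per million (RPM).

#' Best hit per query
#'
#' Highest bit score wins; ties broken by lowest e-value, then earliest
#' file order.
#'
#' @param hits Hit table (see [read_blast6()]).
#' @return One row per query, in order of first appearance.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  first_seen <- match(unique(hits$query_id), hits$query_id)
  hits |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::arrange(dplyr::desc(.data$bit_score), .data$evalue, .data$.file_order) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::arrange(match(.data$query_id, hits$query_id[sort(first_seen)])) |>
    dplyr::select(-".file_order")
}

#' Screen best hits for contaminant organisms
#'
#' Keeps best hits passing conservative e-value and identity thresholds,
#' tallies their subject organism names, and flags the most abundant
#' organisms whose name contains none of the target substrings. Transcripts
#' whose best hit is to a flagged organism are flagged in turn. Hits without
#' an organism name are tallied under "unknown" and never flagged.
#'
#' @param best_hits Output of [best_hit_per_query()].
#' @param evalue_max Maximum e-value (default 1e-50).
#' @param identity_min Minimum percent identity (default 90).
#' @param target_names Substrings identifying the target organism itself
#'   (default "Euglena"); matching organisms are never flagged.
#' @param top_n Number of most abundant non-target organisms to flag
#'   (default 5).
#' @return An object of class `decontam_screen`: a list with
#'   `organism_tally` (tibble `sciname`, `n`, `flagged`),
#'   `flagged_organisms`, `flagged_transcripts` and the parameters.
#' @export
screen_contaminants <- function(best_hits, evalue_max = 1e-50,
                                identity_min = 90,
                                target_names = "Euglena", top_n = 5L) {
  if (identity_min <= 0 || identity_min > 100) abort("`identity_min` must be in (0, 100]")
  kept <- best_hits |>
    dplyr::filter(.data$evalue <= evalue_max, .data$pct_identity >= identity_min) |>
    dplyr::mutate(sciname = dplyr::coalesce(.data$subject_sciname, "unknown"))
  tally <- kept |>
    dplyr::count(.data$sciname, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$sciname)
  is_target <- function(nm) {
    nm != "unknown" &
      Reduce(`|`, lapply(target_names, function(t) stringr::str_detect(nm, stringr::fixed(t))),
             rep(FALSE, length(nm)))
  }
  candidates <- tally |>
    dplyr::filter(!is_target(.data$sciname), .data$sciname != "unknown")
  flagged <- head(candidates$sciname, top_n)
  tally$flagged <- tally$sciname %in% flagged
  structure(
    list(
      organism_tally = tally,
      flagged_organisms = flagged,
      flagged_transcripts = kept$query_id[kept$sciname %in% flagged],
      params = list(
        evalue_max = evalue_max, identity_min = identity_min,
        target_names = target_names, top_n = top_n
      )
    ),
    class = "decontam_screen"
  )
}

#' @export
print.decontam_screen <- function(x, ...) {
  cat("Contaminant screen:", nrow(x$organism_tally), "organism(s) tallied;",
      length(x$flagged_organisms), "flagged;",
      length(x$flagged_transcripts), "transcript(s) flagged\n")
  if (length(x$flagged_organisms) > 0L) {
    cat("Flagged:", paste(x$flagged_organisms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read-removal score threshold
#'
#' The local-alignment score above which a read aligning to a contaminant
#' genome is removed: `20 + 8 * ln(L)` for read length `L` (natural log),
#' the aligner's default minimal local score.
#'
#' @param read_length Read length(s) in bases, >= 1.
#' @return Numeric threshold(s).
#' @export
#' @examples
#' read_removal_threshold(100)
read_removal_threshold <- function(read_length) {
  if (any(read_length < 1)) abort("`read_length` must be >= 1")
  20 + 8.0 * log(read_length)
}

#' Filter reads by alignment score
#'
#' A read is removed iff it is mapped and its alignment score strictly
#' exceeds the length-dependent threshold; boundary scores and unmapped
#' reads are kept.
#'
#' @param alignments Tibble from [read_sam_scores()].
#' @return The input with an added logical column `removed`.
#' @export
filter_reads <- function(alignments) {
  alignments |>
    dplyr::mutate(
      removed = .data$mapped &
        .data$aln_score > read_removal_threshold(.data$read_length)
    )
}

#' Reads-per-million removal rate
#'
#' `floor(removed / total * 1e6)`, the convention that reproduces the
#' printed per-experiment removal rates from pre-processed read counts.
#'
#' @param removed Number of removed reads (0 <= removed <= total).
#' @param total Total (pre-processed) read count, >= 1.
#' @return Integer RPM value(s).
#' @export
#' @examples
#' rpm(9080, 310302570)
rpm <- function(removed, total) {
  if (any(total < 1)) abort("`total` must be >= 1")
  if (any(removed < 0) || any(removed > total)) abort("need 0 <= removed <= total")
  as.integer(floor(removed / total * 1e6))
}

#' Per-study contribution percentages
#'
#' Percentage share of each study's transcript count in a combined
#' (consensus) set: `n / sum(n) * 100`.
#'
#' @param n Non-negative counts.
#' @return Numeric percentages summing to 100.
#' @export
contribution_pct <- function(n) {
  if (any(n < 0)) abort("counts must be non-negative")
  if (sum(n) == 0) abort("counts sum to zero")
  n / sum(n) * 100
}

#' @rdname screen_contaminants
#' @param x A `decontam_screen` object.
#' @param ... Unused.
#' @export
tidy.decontam_screen <- function(x, ...) {
  x$organism_tally
}

#' @rdname screen_contaminants
#' @export
glance.decontam_screen <- function(x, ...) {
  tibble::tibble(
    n_organisms = nrow(x$organism_tally),
    n_flagged_organisms = length(x$flagged_organisms),
    n_flagged_transcripts = length(x$flagged_transcripts)
  )
}
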