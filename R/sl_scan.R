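# Spliced-leader (SL) remnant detection at transcript 5' ends.
#
# In euglenozoans a short leader RNA is trans-spliced onto nuclear
# pre-mRNAs; its remnant on an assembled transcript marks a complete 5'
# end. Assembled transcripts are unoriented, so each transcript and its
# reverse complement are both truncated to a 5' window and scanned for
# maximal exact substrings shared with the SL sequence (wordmatch
# semantics: matches are not anchored at offset 0 -- the 5' constraint is
# the window truncation itself).

# Best maximal common substring (>= min_match) between a window and the SL
# sequence: longest first, then smallest window offset, then smallest SL
# offset. Ambiguity codes never match. Returns NULL or a list.
best_common_substring <- function(window, sl, min_match) {
  wc <- strsplit(window, "", fixed = TRUE)[[1]]
  sc <- strsplit(sl, "", fixed = TRUE)[[1]]
  nw <- length(wc)
  ns <- length(sc)
  if (nw < min_match) return(NULL)
  valid_w <- wc %in% c("A", "C", "G", "T")
  eq <- outer(wc, sc, "==") & valid_w  # sl is validated to be plain ACGT
  best <- NULL
  # runs along diagonals of the match matrix are maximal common substrings
  for (d in (-(ns - 1)):(nw - 1)) {
    i <- max(1L, 1L + d):min(nw, ns + d)
    j <- i - d
    hits <- eq[cbind(i, j)]
    r <- rle(hits)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_match)) {
      cand <- list(
        match_len = r$lengths[k],
        offset = i[starts[k]] - 1L,     # 0-based in the window
        sl_offset = j[starts[k]] - 1L   # 0-based in the SL sequence
      )
      if (is.null(best) ||
          cand$match_len > best$match_len ||
          (cand$match_len == best$match_len && cand$offset < best$offset) ||
          (cand$match_len == best$match_len && cand$offset == best$offset &&
             cand$sl_offset < best$sl_offset)) {
        best <- cand
      }
    }
  }
  best
}

check_sl_config <- function(sl_seq, min_match, window) {
  sl_seq <- normalize_seq(sl_seq)
  if (nchar(sl_seq) < 1L || grepl("[^ACGT]", sl_seq)) {
    abort("`sl_seq` must be a non-empty A/C/G/T sequence")
  }
  if (min_match < 4L) abort("`min_match` must be >= 4")
  if (min_match > nchar(sl_seq)) abort("`min_match` exceeds the SL length")
  if (window < min_match) abort("`window` must be >= `min_match`")
  sl_seq
}

#' Scan transcripts for spliced-leader remnants
#'
#' For each transcript, the forward sequence and its reverse complement are
#' truncated to the first `window` bases and scanned for maximal exact
#' substrings shared with `sl_seq` of length at least `min_match`. At most
#' one match per orientation is reported (the longest, ties broken by
#' smallest window offset), so submatches of a single SL hit do not inflate
#' counts. A transcript may match in both orientations.
#'
#' @param transcripts Data frame with columns `id` and `seq`.
#' @param sl_seq The spliced-leader sequence (plain A/C/G/T; supplied by the
#'   user, typically the 24-nt *Euglena* SL).
#' @param min_match Minimum exact match length; conventional thresholds are
#'   12, 14 and 24 nt.
#' @param window 5' truncation length in bases (default 40).
#' @return A tibble with one row per reported match: `transcript_id`,
#'   `orientation` ("forward"/"reverse"), `match_len`, `offset` (0-based in
#'   the truncated window) and `sl_offset` (0-based in `sl_seq`).
#' @export
scan_sl <- function(transcripts, sl_seq, min_match = 24L, window = 40L) {
  check_transcripts(transcripts)
  sl_seq <- check_sl_config(sl_seq, min_match, window)
  fwd <- substr(normalize_seq(transcripts$seq), 1L, window)
  rev <- substr(revcomp(transcripts$seq), 1L, window)
  one <- function(id, win, orient) {
    m <- best_common_substring(win, sl_seq, min_match)
    if (is.null(m)) return(NULL)
    tibble::tibble(
      transcript_id = id, orientation = orient,
      match_len = m$match_len, offset = m$offset, sl_offset = m$sl_offset
    )
  }
  rows <- c(
    purrr::map2(transcripts$id, fwd, one, orient = "forward"),
    purrr::map2(transcripts$id, rev, one, orient = "reverse")
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      transcript_id = character(), orientation = character(),
      match_len = integer(), offset = integer(), sl_offset = integer()
    ))
  }
  dplyr::arrange(out, match(.data$transcript_id, transcripts$id), .data$orientation)
}

#' Summarise spliced-leader matches
#'
#' Per-orientation match counts, their total, the mean reported match
#' length, and the number of distinct matched transcripts (a transcript
#' matching in both orientations counts twice in `n_total` but once in
#' `n_transcripts_matched`).
#'
#' @param matches Output of [scan_sl()] for one transcript set at one
#'   threshold.
#' @param n_transcripts Number of transcripts scanned.
#' @return A one-row tibble: `n_forward`, `n_reverse`, `n_total`,
#'   `mean_match_len` (`NA` when there are no matches),
#'   `n_transcripts_matched` and `pct_transcripts_matched`.
#' @export
sl_summary <- function(matches, n_transcripts) {
  n_fwd <- sum(matches$orientation == "forward")
  n_rev <- sum(matches$orientation == "reverse")
  n_tot <- n_fwd + n_rev
  tibble::tibble(
    n_forward = n_fwd, n_reverse = n_rev, n_total = n_tot,
    mean_match_len = if (n_tot == 0L) NA_real_ else mean(matches$match_len),
    n_transcripts_matched = length(unique(matches$transcript_id)),
    pct_transcripts_matched =
      100 * length(unique(matches$transcript_id)) / n_transcripts
  )
}
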