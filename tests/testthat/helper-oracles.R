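# Independent oracles, deliberately naive, used to check the package's
# implementations on small inputs.

# Best maximal common substring between `window` and `sl` by exhaustive
# enumeration of all start pairs (O(|w| * |s| * len)).
oracle_sl_best <- function(window, sl, min_match) {
  w <- strsplit(toupper(window), "")[[1]]
  s <- strsplit(toupper(sl), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  best <- NULL
  for (i in seq_along(w)) {
    for (j in seq_along(s)) {
      if (w[i] != s[j] || !(w[i] %in% acgt)) next
      # maximal only: not extendable to the left
      if (i > 1 && j > 1 && w[i - 1] == s[j - 1] && w[i - 1] %in% acgt) next
      len <- 0
      while (i + len <= length(w) && j + len <= length(s) &&
             w[i + len] == s[j + len] && w[i + len] %in% acgt) {
        len <- len + 1
      }
      if (len < min_match) next
      cand <- list(match_len = len, offset = i - 1L, sl_offset = j - 1L)
      if (is.null(best) || cand$match_len > best$match_len ||
          (cand$match_len == best$match_len && cand$offset < best$offset) ||
          (cand$match_len == best$match_len && cand$offset == best$offset &&
             cand$sl_offset < best$sl_offset)) {
        best <- cand
      }
    }
  }
  best
}

# LCA by explicit ancestor-set intersection, deepest common node by
# root-distance (independent of the path-prefix implementation).
oracle_lca <- function(taxids, taxonomy) {
  root <- taxonomy$taxid[taxonomy$taxid == taxonomy$parent]
  parent_of <- stats::setNames(taxonomy$parent, taxonomy$taxid)
  ancestors <- function(t) {
    out <- t
    while (t != root) {
      t <- parent_of[[as.character(t)]]
      out <- c(out, t)
    }
    out
  }
  depth <- function(t) length(ancestors(t))
  common <- Reduce(intersect, lapply(unique(taxids), ancestors))
  common[which.max(vapply(common, depth, numeric(1)))]
}

# Upper-tail hypergeometric by direct enumeration of the pmf.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exhaustive-optimal PAM cost over all medoid subsets of size k.
oracle_pam_cost <- function(d, k) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  min(apply(combs, 2L, function(S) {
    sum(apply(d[, S, drop = FALSE], 1L, min))
  }))
}

random_dissim <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  d
}

random_transcripts <- function(n, len_range = c(30, 120)) {
  tibble::tibble(
    id = sprintf("rt%04d", seq_len(n)),
    seq = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"),
                   sample(len_range[1]:len_range[2], 1), replace = TRUE),
            collapse = "")
    }, character(1))
  )
}

sl_test_seq <- "ACACTTTCTGAGTGTCTATTTTTG"
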