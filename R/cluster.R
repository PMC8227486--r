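# Co-expression clustering: PAM (partitioning around medoids) on the
# squared-correlation dissimilarity d = 1 - r^2, with a Dunn-like ratio
# criterion for choosing the number of clusters k. The d = 1 - r^2 distance
# treats perfectly anti-correlated genes as neighbours, capturing both
# positive and negative co-regulation. PAM here is fully deterministic
# (greedy BUILD seeding + best-improvement SWAP, ties to the lowest index),
# so results are reproducible without a seed.

#' Squared-correlation dissimilarity of gene expression
#'
#' Pearson correlation across samples for every gene pair; dissimilarity
#' `d = 1 - r^2`, so both strong positive and strong negative correlation
#' mean proximity. Zero-variance gene rows are rejected by name.
#'
#' @param mat Wide tibble of per-gene values (typically z-scores), first
#'   column gene ids.
#' @return An object of class `expr_dissim`: list with `d` (gene x gene
#'   dissimilarity), `r` (the underlying correlation matrix) and
#'   `gene_ids`.
#' @export
expr_dissimilarity <- function(mat) {
  m <- expr_matrix(mat)
  if (ncol(m) < 2L) abort("need at least 2 samples per gene")
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance gene row(s): %s",
                  paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  r <- cor(t(m))
  d <- 1 - r^2
  d[d < 0] <- 0  # numerical guard
  diag(d) <- 0
  structure(list(d = d, r = r, gene_ids = rownames(m)), class = "expr_dissim")
}

as_dissim_matrix <- function(d) {
  if (inherits(d, "expr_dissim")) d <- d$d
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("dissimilarity must be square")
  d
}

pam_cost <- function(d, medoids) {
  sum(Reduce(pmin, lapply(medoids, function(j) d[, j])))
}

#' Deterministic PAM clustering
#'
#' Partitioning around medoids on a precomputed dissimilarity matrix. For
#' small problems (at most `exact_limit` candidate medoid sets) the optimal
#' medoid set is found by exhaustive enumeration, so the reported cost is
#' the global minimum; larger problems use greedy BUILD seeding (each added
#' medoid maximises the cost reduction) followed by best-improvement SWAP
#' until no single medoid/non-medoid swap lowers the total cost — the
#' classic PAM local search. All ties break to the lowest index, so the
#' result is deterministic either way. Points are assigned to the nearest
#' medoid (ties to the lowest medoid index); each medoid is labelled to
#' itself.
#'
#' @param d Dissimilarity matrix or an [expr_dissimilarity()] object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param exact_limit Use exhaustive enumeration when `choose(n, k)` does
#'   not exceed this (default 20000); set to 0 to force the local search.
#' @return An object of class `pam_fit`: list with `k`, `medoid_idx`,
#'   `medoid_ids`, `labels` (integer 1..k, named by item id) and
#'   `total_cost`.
#' @export
pam_cluster <- function(d, k, exact_limit = 20000) {
  dm <- as_dissim_matrix(d)
  n <- nrow(dm)
  if (k < 1L || k > n) abort(sprintf("`k` must be in 1..%d", n))
  ids <- rownames(dm)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  if (choose(n, k) <= exact_limit) {
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2L, function(S) pam_cost(dm, S))
    medoids <- sets[, which.min(costs)]  # lexicographically first optimum
  } else {
    # BUILD
    medoids <- which.min(colSums(dm))  # lowest index on ties
    while (length(medoids) < k) {
      dn <- Reduce(pmin, lapply(medoids, function(j) dm[, j]))
      cand <- setdiff(seq_len(n), medoids)
      gain <- vapply(cand, function(j) sum(pmax(dn - dm[, j], 0)), numeric(1))
      medoids <- c(medoids, cand[which.max(gain)])
    }
    cost <- pam_cost(dm, medoids)

    # SWAP: best improvement, ties to lowest (medoid, candidate) index pair
    repeat {
      best <- NULL
      cand <- setdiff(seq_len(n), medoids)
      for (m in sort(medoids)) {
        rest <- setdiff(medoids, m)
        for (h in cand) {
          newcost <- pam_cost(dm, c(rest, h))
          if (newcost < cost - 1e-12 &&
              (is.null(best) || newcost < best$cost - 1e-12)) {
            best <- list(m = m, h = h, cost = newcost)
          }
        }
      }
      if (is.null(best)) break
      medoids <- c(setdiff(medoids, best$m), best$h)
      cost <- best$cost
    }
  }

  medoids <- sort(medoids)
  # nearest medoid; which.min ties to the first (lowest-index) medoid
  labels <- apply(dm[, medoids, drop = FALSE], 1L, which.min)
  labels[medoids] <- seq_along(medoids)  # medoid always labels itself
  names(labels) <- ids
  structure(
    list(
      k = k, medoid_idx = medoids, medoid_ids = ids[medoids],
      labels = labels, total_cost = pam_cost(dm, medoids)
    ),
    class = "pam_fit"
  )
}

#' @export
print.pam_fit <- function(x, ...) {
  cat("PAM fit: k =", x$k, " total cost =", format(x$total_cost, digits = 6), "\n")
  cat("Cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

# Ratio selection statistics for one clustering.
#  within_cor_max: per cluster (>= 2 members), the maximum |r| over distinct
#    member pairs, averaged over those clusters.
#  between_cor_min: per medoid, the minimum |r| to the other medoids,
#    averaged over medoids.
k_selection_stats <- function(r, fit) {
  a <- abs(r)
  within <- vapply(seq_len(fit$k), function(cl) {
    idx <- which(fit$labels == cl)
    if (length(idx) < 2L) return(NA_real_)
    sub <- a[idx, idx, drop = FALSE]
    max(sub[upper.tri(sub)])
  }, numeric(1))
  med <- fit$medoid_idx
  between <- if (fit$k < 2L) NA_real_ else {
    mean(vapply(seq_along(med), function(i) min(a[med[i], med[-i]]), numeric(1)))
  }
  w <- mean(within, na.rm = TRUE)
  tibble::tibble(
    k = fit$k,
    within_cor_max = w,
    between_cor_min = between,
    ratio = between / w,
    n_singleton = sum(tabulate(fit$labels, fit$k) == 1L),
    total_cost = fit$total_cost
  )
}

#' Choose the number of co-expression clusters
#'
#' Runs deterministic PAM on `d = 1 - r^2` for every `k` in
#' `k_min..k_max` and computes, for each solution, the average
#' within-cluster maximal absolute correlation (w-k cor_max), the average
#' between-medoid minimal absolute correlation (b-k cor_min), and their
#' ratio `b / w` -- a reinterpretation of the Dunn index on the correlation
#' scale. The solution with the minimal ratio is selected (ties to the
#' smallest k). A k whose solution is all singletons is skipped with a
#' warning.
#'
#' @param mat Wide tibble of per-gene z-scores (first column gene ids).
#' @param k_min,k_max Scan range (defaults 5 and 75; `k_max < n` genes).
#' @return An object of class `coexpr_clustering`: list with `scan`
#'   (tibble of per-k statistics), `best_k`, `best_fit` (the selected
#'   [pam_cluster()] fit), `dissim` (the [expr_dissimilarity()] object).
#' @export
select_k <- function(mat, k_min = 5L, k_max = 75L) {
  dis <- expr_dissimilarity(mat)
  n <- nrow(dis$d)
  if (k_max >= n) abort("`k_max` must be smaller than the number of genes")
  if (k_min < 2L) abort("`k_min` must be >= 2")
  fits <- list()
  scan <- vector("list", 0L)
  for (k in seq(k_min, k_max)) {
    fit <- pam_cluster(dis, k)
    if (all(tabulate(fit$labels, k) <= 1L)) {
      warn(sprintf("k = %d yields only singleton clusters; skipped", k))
      next
    }
    fits[[as.character(k)]] <- fit
    scan[[length(scan) + 1L]] <- k_selection_stats(dis$r, fit)
  }
  scan <- dplyr::bind_rows(scan)
  if (nrow(scan) == 0L) abort("no usable k in the scan range")
  best_k <- scan$k[which.min(scan$ratio)]  # ties to smallest k (scan ordered)
  structure(
    list(
      scan = scan, best_k = best_k,
      best_fit = fits[[as.character(best_k)]],
      dissim = dis
    ),
    class = "coexpr_clustering"
  )
}

#' @export
print.coexpr_clustering <- function(x, ...) {
  cat("Co-expression clustering over k =", min(x$scan$k), "..", max(x$scan$k), "\n")
  cat("Selected k =", x$best_k, "(minimal b/w correlation ratio =",
      format(min(x$scan$ratio), digits = 4), ")\n")
  invisible(x)
}

#' @rdname select_k
#' @param x,object A `coexpr_clustering` object.
#' @param ... Unused.
#' @export
tidy.coexpr_clustering <- function(x, ...) {
  fit <- x$best_fit
  tibble::tibble(
    gene_id = names(fit$labels),
    cluster = unname(fit$labels),
    is_medoid = names(fit$labels) %in% fit$medoid_ids
  )
}

#' @rdname select_k
#' @export
glance.coexpr_clustering <- function(x, ...) {
  x$scan[x$scan$k == x$best_k, ]
}

#' @rdname select_k
#' @export
autoplot.coexpr_clustering <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(.data$k, .data$ratio)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(
      data = object$scan[object$scan$k == object$best_k, ],
      colour = "red", size = 2
    ) +
    ggplot2::labs(
      x = "number of clusters k",
      y = "between-medoid min |r| / within-cluster max |r|",
      title = "Cluster-number selection (minimum marked)"
    )
}

#' Hierarchical leaf ordering for heatmaps
#'
#' Agglomerative clustering with correlation distance `1 - r` and centroid
#' linkage (Lance-Williams update), as used to order heatmap rows and
#' columns. Returns the dendrogram leaf order.
#'
#' @param mat Wide tibble (first column ids).
#' @param axis Order `"genes"` (rows) or `"samples"` (columns).
#' @return Character vector of ids in leaf order.
#' @export
hcluster_order <- function(mat, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- expr_matrix(mat)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2L) abort("need at least 2 items to order")
  r <- cor(t(m))
  hc <- hclust(as.dist(1 - r), method = "centroid")
  rownames(m)[hc$order]
}
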