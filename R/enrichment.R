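# Term over-representation per co-expression cluster (upper-tail
# hypergeometric test with Benjamini-Hochberg adjustment) and a
# Cohen's-kappa network linking significant terms that share genes.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: drawing `n` genes from a
#' background of `N` of which `K` carry the term, the probability of seeing
#' `k` or more carriers.
#'
#' @param k Observed overlap (vectorised).
#' @param K Background genes with the term.
#' @param n Cluster (draw) size.
#' @param N Background size.
#' @return Probabilities in \[0, 1\].
#' @export
#' @examples
#' hypergeom_upper(4, 5, 4, 10)
hypergeom_upper <- function(k, K, n, N) {
  bad <- k > pmin(K, n) | K > N | n > N | k < 0 | K < 0 | n < 0
  if (any(bad)) abort("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment: sort ascending, multiply by `m/i`, take
#' the cumulative minimum from the largest rank, cap at 1, restore input
#' order.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) abort("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Cohen's kappa between two gene sets
#'
#' Chance-corrected agreement of the two membership indicators over a gene
#' universe, from the 2x2 table (both, a-only, b-only, neither):
#' `kappa = (po - pe) / (1 - pe)`. When `pe = 1` (both indicators
#' constant), kappa is defined as 1 for identical sets and 0 otherwise.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all analysed genes.
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' kappa_score(paste0("g", 1:5), paste0("g", 4:8), paste0("g", 1:10))
kappa_score <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) abort("`universe` is empty")
  a <- unique(set_a)
  b <- unique(set_b)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    abort("sets must be subsets of the universe")
  }
  both <- length(intersect(a, b))
  neither <- N - length(union(a, b))
  po <- (both + neither) / N
  pe <- (length(a) * length(b) + (N - length(a)) * (N - length(b))) / N^2
  if (pe == 1) return(if (setequal(a, b)) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Term over-representation per cluster
#'
#' For each cluster, tests every annotation term whose level lies in
#' `[level_min, level_max]` and whose coverage reaches
#' `min_cluster_fraction` of the cluster's annotated genes, using the
#' upper-tail hypergeometric test against the background of all annotated
#' genes in the analysed set. BH adjustment is applied within each
#' cluster's tested term set; a term is significant iff `p_adj <= alpha`.
#'
#' @param cluster_labels Tibble with columns `gene_id` and `cluster`
#'   (e.g. `tidy()` of a [select_k()] result).
#' @param annotations Annotation tibble (see [read_term_annotations()]).
#' @param level_min,level_max Term-level window (defaults 3 and 12).
#' @param min_cluster_fraction Minimum fraction of the cluster's annotated
#'   genes carrying the term for it to be tested (default 0.03).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return A tibble with one row per tested (cluster, term): `cluster`,
#'   `term_id`, `term_name`, `term_level`, `namespace`, `k_overlap`,
#'   `K_term`, `n_cluster`, `N_bg`, `p`, `p_adj`, `significant`; the
#'   background gene ids are attached as attribute `background`.
#' @export
enrich_clusters <- function(cluster_labels, annotations,
                            level_min = 3L, level_max = 12L,
                            min_cluster_fraction = 0.03, alpha = 0.05) {
  check_annotations(annotations)
  if (min_cluster_fraction <= 0 || min_cluster_fraction >= 1) {
    abort("`min_cluster_fraction` must be in (0, 1)")
  }
  background <- intersect(cluster_labels$gene_id, unique(annotations$gene_id))
  N <- length(background)
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  testable <- ann[ann$term_level >= level_min & ann$term_level <= level_max, , drop = FALSE]
  term_info <- testable |>
    dplyr::distinct(.data$term_id, .data$term_name, .data$term_level, .data$namespace)
  term_genes <- split(testable$gene_id, testable$term_id)

  res <- lapply(sort(unique(cluster_labels$cluster)), function(cl) {
    genes <- intersect(cluster_labels$gene_id[cluster_labels$cluster == cl], background)
    n <- length(genes)
    if (n == 0L) return(NULL)
    overlap <- vapply(term_genes, function(g) length(intersect(g, genes)), integer(1))
    keep <- overlap >= 1L & overlap >= min_cluster_fraction * n
    if (!any(keep)) return(NULL)
    ids <- names(term_genes)[keep]
    p <- hypergeom_upper(overlap[keep], lengths(term_genes)[keep], n, N)
    tibble::tibble(
      cluster = cl, term_id = ids,
      k_overlap = unname(overlap[keep]),
      K_term = unname(lengths(term_genes)[keep]),
      n_cluster = n, N_bg = N,
      p = unname(p), p_adj = bh_adjust(unname(p))
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0L) {
    out <- out |>
      dplyr::left_join(term_info, by = "term_id") |>
      dplyr::mutate(significant = .data$p_adj <= alpha) |>
      dplyr::select(
        "cluster", "term_id", "term_name", "term_level", "namespace",
        "k_overlap", "K_term", "n_cluster", "N_bg", "p", "p_adj", "significant"
      )
  }
  attr(out, "background") <- background
  out
}

#' Kappa-score network over significant terms
#'
#' Builds the term-association network: nodes are the terms significant in
#' at least one cluster; an edge joins two terms whose membership-indicator
#' kappa over the analysed gene universe is at or above `kappa_min`
#' (inclusive). As a simplification of parent-child term fusion, when one
#' significant term's gene set is a subset of another's and the pair is
#' connected, the node table records the more specific (higher-level) term
#' as the label of the pair.
#'
#' @param enrich_results Output of [enrich_clusters()].
#' @param annotations The same annotation tibble used for enrichment.
#' @param kappa_min Edge threshold (default 0.3, inclusive).
#' @param universe Gene universe for kappa; defaults to the background
#'   attached to `enrich_results`.
#' @return An object of class `kappa_network`: list with `edges` (tibble
#'   `term_a`, `term_b`, `kappa`), `nodes` (tibble `term_id`, `degree`,
#'   `component`, `fused_into`) and `params`.
#' @export
build_kappa_network <- function(enrich_results, annotations, kappa_min = 0.3,
                                universe = NULL) {
  if (is.null(universe)) universe <- attr(enrich_results, "background")
  if (is.null(universe)) abort("no gene universe available; pass `universe`")
  terms <- unique(enrich_results$term_id[enrich_results$significant])
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  sets <- lapply(setNames(terms, terms),
                 function(t) unique(ann$gene_id[ann$term_id == t]))
  edges <- tibble::tibble(term_a = character(), term_b = character(), kappa = numeric())
  if (length(terms) >= 2L) {
    pairs <- utils::combn(terms, 2L)
    kap <- apply(pairs, 2L, function(p) kappa_score(sets[[p[1]]], sets[[p[2]]], universe))
    keep <- kap >= kappa_min
    edges <- tibble::tibble(
      term_a = pairs[1, keep], term_b = pairs[2, keep], kappa = kap[keep]
    )
  }
  g <- igraph::graph_from_data_frame(
    edges[c("term_a", "term_b")], directed = FALSE,
    vertices = data.frame(name = terms)
  )
  comp <- igraph::components(g)
  lvl <- enrich_results$term_level[match(terms, enrich_results$term_id)]
  fused <- rep(NA_character_, length(terms))
  for (i in seq_len(nrow(edges))) {
    a <- edges$term_a[i]; b <- edges$term_b[i]
    la <- lvl[match(a, terms)]; lb <- lvl[match(b, terms)]
    if (all(sets[[a]] %in% sets[[b]]) && la > lb) fused[match(b, terms)] <- a
    if (all(sets[[b]] %in% sets[[a]]) && lb > la) fused[match(a, terms)] <- b
  }
  nodes <- tibble::tibble(
    term_id = terms,
    degree = as.integer(igraph::degree(g)[terms]),
    component = as.integer(comp$membership[terms]),
    fused_into = fused
  )
  structure(
    list(
      edges = edges, nodes = nodes,
      params = list(kappa_min = kappa_min, n_universe = length(universe),
                    fusion = "subset-based parent-child simplification")
    ),
    class = "kappa_network"
  )
}

#' @export
print.kappa_network <- function(x, ...) {
  cat("Kappa network:", nrow(x$nodes), "term(s),", nrow(x$edges),
      "edge(s) at kappa >=", x$params$kappa_min, "\n")
  cat("Components:", length(unique(x$nodes$component)), "\n")
  invisible(x)
}

#' @rdname build_kappa_network
#' @param x A `kappa_network` object.
#' @param ... Unused.
#' @export
tidy.kappa_network <- function(x, ...) x$edges

#' @rdname build_kappa_network
#' @export
glance.kappa_network <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$nodes), n_edges = nrow(x$edges),
    n_components = length(unique(x$nodes$component)),
    mean_degree = if (nrow(x$nodes) == 0L) NA_real_ else mean(x$nodes$degree)
  )
}
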