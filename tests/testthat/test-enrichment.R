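test_that("hypergeom_upper matches enumeration and boundary cases", {
  expect_equal(hypergeom_upper(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_upper(0, 3, 4, 10), 1)
  expect_equal(hypergeom_upper(4, 10, 4, 10), 1)  # term covers the universe
  expect_error(hypergeom_upper(5, 4, 10, 10), "inconsistent")

  withr::local_seed(71)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper(k, K, n, N), oracle_hyper_upper(k, K, n, N))
  }
})

test_that("bh_adjust reproduces the step-up hand example and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  withr::local_seed(72)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), seq_along(p))  # order preserved
})

test_that("kappa_score follows the 2x2 worked example and its symmetries", {
  u <- paste0("g", 1:10)
  expect_equal(kappa_score(paste0("g", 1:5), paste0("g", 4:8), u), -0.2)
  expect_equal(kappa_score(paste0("g", 1:4), paste0("g", 1:4), u), 1)
  expect_equal(kappa_score(paste0("g", 1:5), paste0("g", 4:8), u),
               kappa_score(paste0("g", 4:8), paste0("g", 1:5), u))
  # relabeling genes leaves kappa unchanged
  relabel <- setNames(paste0("x", 1:10), u)
  expect_equal(kappa_score(relabel[paste0("g", 1:5)], relabel[paste0("g", 4:8)],
                           unname(relabel)), -0.2)
  # degenerate: both sets equal the universe
  expect_equal(kappa_score(u, u, u), 1)
  expect_error(kappa_score("g1", "g2", character(0)), "empty")
})

test_that("independent random sets have kappa near zero on average", {
  withr::local_seed(73)
  u <- paste0("g", 1:50)
  k <- replicate(400, kappa_score(sample(u, 20), sample(u, 20), u))
  expect_lt(abs(mean(k)), 0.05)
})

mk_ann <- function(term_id, genes, level = 5L, namespace = "GO") {
  tibble::tibble(
    gene_id = genes, term_id = term_id, term_name = term_id,
    term_level = level, namespace = namespace
  )
}

test_that("enrich_clusters filters by level and coverage and finds planted terms", {
  genes <- paste0("g", 1:100)
  labels <- tibble::tibble(gene_id = genes, cluster = rep(1:2, each = 50))
  ann <- dplyr::bind_rows(
    mk_ann("GO:planted", c(paste0("g", 1:15), "g60")),          # 15/50 in cluster 1
    mk_ann("GO:sparse", c("g1", "g51")),                        # below 3% coverage? 1/50 = 2%
    mk_ann("GO:toolow", paste0("g", 40:60), level = 2L),        # outside level window
    mk_ann("GO:background", paste0("g", seq(2, 100, by = 2)))
  )
  res <- enrich_clusters(labels, ann)
  expect_false("GO:toolow" %in% res$term_id)
  expect_false("GO:sparse" %in% res$term_id[res$cluster == 1])
  planted <- res[res$term_id == "GO:planted" & res$cluster == 1, ]
  expect_equal(planted$k_overlap, 15L)
  expect_lte(planted$p_adj, 0.05)
  expect_true(planted$significant)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$k_overlap <= pmin(res$K_term, res$n_cluster)))
  # background = annotated genes only
  expect_equal(unique(res$N_bg), length(unique(ann$gene_id)))
})

test_that("a cluster without annotated genes yields no rows", {
  labels <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                           cluster = c(1, 1, 2, 2))
  ann <- mk_ann("GO:x", c("a", "b"))
  res <- enrich_clusters(labels, ann)
  expect_true(all(res$cluster == 1))
})

test_that("the kappa network links term pairs at or above the threshold", {
  u <- paste0("g", 1:40)
  labels <- tibble::tibble(gene_id = u, cluster = 1L)
  # shared: kappa exactly 0.5 with |A| = |B| = 20, overlap 15; a level-0
  # catch-all term pins the background universe at all 40 genes
  ann <- dplyr::bind_rows(
    mk_ann("GO:a", u[1:20]),
    mk_ann("GO:b", u[c(1:15, 21:25)]),
    mk_ann("GO:c", u[26:28]),
    mk_ann("GO:bg", u, level = 0L)
  )
  res <- enrich_clusters(labels, ann, min_cluster_fraction = 0.01, alpha = 1)
  expect_true(all(c("GO:a", "GO:b", "GO:c") %in% res$term_id))
  expect_equal(kappa_score(u[1:20], u[c(1:15, 21:25)], u), 0.5)

  net <- build_kappa_network(res, ann, kappa_min = 0.5)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$term_a, net$edges$term_b), c("GO:a", "GO:b"))
  expect_equal(net$edges$kappa, 0.5)  # boundary kappa is included

  # identical gene sets give kappa 1
  ann2 <- dplyr::bind_rows(mk_ann("GO:a", u[1:10]), mk_ann("GO:b", u[1:10]))
  res2 <- enrich_clusters(labels, ann2, min_cluster_fraction = 0.01, alpha = 1)
  net2 <- build_kappa_network(res2, ann2, kappa_min = 0.3)
  expect_equal(net2$edges$kappa, 1)

  # disjoint small terms in a large universe: kappa <= 0, no edge
  ann3 <- dplyr::bind_rows(mk_ann("GO:a", u[1:3]), mk_ann("GO:b", u[4:6]))
  res3 <- enrich_clusters(labels, ann3, min_cluster_fraction = 0.01, alpha = 1)
  net3 <- build_kappa_network(res3, ann3, kappa_min = 0.3)
  expect_equal(nrow(net3$edges), 0L)
  expect_equal(glance(net3)$n_components, 2L)
})

test_that("subset terms fuse into the more specific node label", {
  u <- paste0("g", 1:30)
  labels <- tibble::tibble(gene_id = u, cluster = 1L)
  ann <- dplyr::bind_rows(
    mk_ann("GO:parent", u[1:12], level = 4L),
    mk_ann("GO:child", u[1:10], level = 6L),
    mk_ann("GO:bg", u, level = 0L)
  )
  res <- enrich_clusters(labels, ann, min_cluster_fraction = 0.01, alpha = 1)
  net <- build_kappa_network(res, ann, kappa_min = 0.3)
  expect_equal(net$nodes$fused_into[net$nodes$term_id == "GO:parent"], "GO:child")
})
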