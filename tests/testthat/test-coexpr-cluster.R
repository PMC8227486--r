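zmat <- function(values, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(nrow(values)))
  dplyr::bind_cols(tibble::tibble(gene_id = ids),
                   tibble::as_tibble(as.data.frame(values), .name_repair = "minimal"))
}

test_that("dissimilarity treats correlation and anticorrelation as proximity", {
  x <- c(1, 2, 3, 4)
  m <- zmat(rbind(x, 2 * x, -x, c(1, -1, 1, -1) * 0 + c(1, 1, -1, -1)))
  d <- expr_dissimilarity(m)
  expect_equal(d$d[1, 2], 0)
  expect_equal(d$d[1, 3], 0)
  expect_true(all(d$d >= 0 & d$d <= 1))
  expect_equal(unname(diag(d$d)), rep(0, 4))
  expect_equal(d$d, t(d$d))

  # x = [1,-1,1,-1] vs y = [1,1,-1,-1]: r = 0, d = 1
  m2 <- zmat(rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)))
  expect_equal(expr_dissimilarity(m2)$d[1, 2], 1)

  flat <- zmat(rbind(x, c(2, 2, 2, 2)), ids = c("ok", "flatgene"))
  expect_error(expr_dissimilarity(flat), "flatgene")
})

test_that("dissimilarity is invariant under affine transforms of gene rows", {
  withr::local_seed(61)
  v <- matrix(rnorm(5 * 8), 5, 8)
  d1 <- expr_dissimilarity(zmat(v))$d
  d2 <- expr_dissimilarity(zmat(3 * v - 7))$d
  expect_equal(d1, d2)
})

test_that("pam_cluster attains the exhaustive optimum on small problems", {
  withr::local_seed(62)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    k <- sample(2:3, 1)
    d <- random_dissim(n)
    fit <- pam_cluster(d, k)
    expect_equal(fit$total_cost, oracle_pam_cost(d, k), tolerance = 1e-12)
  }
})

test_that("pam_cluster agrees with the reference PAM implementation on cost", {
  skip_if_not_installed("cluster")
  withr::local_seed(63)
  for (i in 1:10) {
    d <- random_dissim(9)
    fit <- pam_cluster(d, 2)
    ref <- cluster::pam(as.dist(d), 2, do.swap = TRUE)
    expect_equal(fit$total_cost, oracle_pam_cost(d, 2), tolerance = 1e-12)
    # the reference local optimum can never beat the exhaustive optimum
    expect_gte(sum(ref$clusinfo[, "av_diss"] * ref$clusinfo[, "size"]) + 1e-12,
               fit$total_cost)
  }
})

test_that("pam degenerate and structural cases behave", {
  d <- random_dissim(5)
  all_self <- pam_cluster(d, 5)
  expect_equal(all_self$total_cost, 0)
  expect_equal(unname(all_self$labels), 1:5)
  expect_error(pam_cluster(d, 6), "k")

  # two well-separated blobs
  blob <- matrix(0.9, 8, 8)
  blob[1:4, 1:4] <- 0.05
  blob[5:8, 5:8] <- 0.05
  diag(blob) <- 0
  fit <- pam_cluster(blob, 2)
  expect_equal(unname(fit$labels), rep(1:2, each = 4))
  expect_equal(fit$total_cost, oracle_pam_cost(blob, 2))

  # medoids label themselves
  expect_equal(unname(fit$labels[fit$medoid_idx]), 1:2)
})

test_that("pam cost is non-increasing in k", {
  withr::local_seed(64)
  d <- random_dissim(12)
  costs <- vapply(2:6, function(k) pam_cluster(d, k)$total_cost, numeric(1))
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("two perfect +/- pairs give ratio 0 at k = 2, selected by tie-break", {
  x <- c(1, -1, 1, -1)
  y <- c(1, 1, -1, -1)
  m <- zmat(rbind(x, -x, y, -y))
  sel <- select_k(m, k_min = 2, k_max = 3)
  expect_equal(sel$best_k, 2L)
  row2 <- sel$scan[sel$scan$k == 2, ]
  expect_equal(row2$within_cor_max, 1)
  expect_equal(row2$between_cor_min, 0)
  expect_equal(row2$ratio, 0)
  expect_equal(sort(as.integer(table(tidy(sel)$cluster))), c(2L, 2L))
  expect_true(all(sel$scan$ratio >= 0))
})

test_that("the k scan reports coherent statistics on simulated clusters", {
  sim <- sim_expression(n_genes = 30, k_clusters = 3, noise_sd = 0.3, seed = 65)
  z <- transform_expression(sim$tpm)
  sel <- select_k(z, k_min = 2, k_max = 5)
  expect_equal(sel$scan$k, 2:5)
  expect_true(all(sel$scan$ratio >= 0))
  expect_true(all(sel$scan$within_cor_max <= 1 & sel$scan$within_cor_max >= 0))
  expect_true(all(sel$scan$between_cor_min <= 1 & sel$scan$between_cor_min >= 0))
  td <- tidy(sel)
  expect_equal(nrow(td), 30)
  expect_equal(sum(td$is_medoid), sel$best_k)
  expect_equal(glance(sel)$k, sel$best_k)
})

test_that("hcluster_order merges identical rows first and respects permutation", {
  withr::local_seed(66)
  base <- matrix(rnorm(4 * 6), 4, 6)
  base[2, ] <- base[1, ]  # identical pair
  m <- zmat(base, ids = c("a", "a2", "b", "c"))
  ord <- hcluster_order(m, "genes")
  expect_equal(abs(diff(match(c("a", "a2"), ord))), 1)

  perm <- c(3, 1, 4, 2)
  ord_perm <- hcluster_order(m[perm, ], "genes")
  expect_setequal(ord_perm, ord)

  ord_s <- hcluster_order(m, "samples")
  expect_setequal(ord_s, names(m)[-1])
})
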