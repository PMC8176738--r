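test_that("PCA embedding is deterministic and exact on planar data", {
  set.seed(50)
  # points exactly in a 2-plane embedded in 5-dim gene space
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  scores <- matrix(rnorm(40), 20, 2) * 3
  v <- scores %*% t(basis)
  expr <- make_std_expr(v)
  emb <- reduce_dimensions(expr, d = 2, method = "pca", seed = 1)
  # reconstruction from 2 PCs is exact (up to standardization, still rank 2)
  z <- expr_values(expr)
  pc <- prcomp(z, center = FALSE, rank. = 2)
  recon <- pc$x %*% t(pc$rotation)
  expect_equal(recon, z, tolerance = 1e-8)
  emb2 <- reduce_dimensions(expr, d = 2, method = "pca", seed = 1)
  expect_identical(emb$coords, emb2$coords)
  expect_error(reduce_dimensions(expr, d = 5), "smaller than")
  expect_error(reduce_dimensions(expr, d = 1), ">= 2")
})

test_that("a pluggable reducer drives the tsne method and is validated", {
  expr <- make_std_expr(matrix(rnorm(60), 20, 3))
  expect_error(reduce_dimensions(expr, d = 2, method = "tsne"), "reducer")
  fake <- function(values, d, seed) values[, seq_len(d)] * 1.0
  emb <- reduce_dimensions(expr, d = 2, method = "tsne", reducer = fake)
  expect_identical(dim(emb$coords), c(20L, 2L))
  expect_true(all(is.finite(emb$coords)))
})

test_that("PAM separates well-separated clouds and is swap-optimal", {
  set.seed(60)
  cloud1 <- matrix(rnorm(40, sd = 0.3), 20, 2)
  cloud2 <- matrix(rnorm(30, sd = 0.3), 15, 2) + 10
  coords <- rbind(cloud1, cloud2)
  rownames(coords) <- sprintf("c%03d", 1:35)
  emb <- structure(list(coords = coords, method = "pca", seed = 1),
                   class = "embedding")
  cl <- cluster_pam(emb, k = 2)
  expect_identical(unique(cl$labels[1:20]), 1L)    # cloud 1 = one cluster
  expect_identical(unique(cl$labels[21:35]), 2L)   # cloud 2 = the other
  expect_identical(cl$labels[cl$medoids], 1:2)
  # brute force: no single swap lowers the total dissimilarity
  dmat <- as.matrix(dist(coords))
  expect_true(pam_swap_optimal(dmat, cl$medoids))
  expect_equal(cl$cost, pam_cost(dmat, cl$medoids))
  # determinism
  expect_identical(cluster_pam(emb, k = 2)$labels, cl$labels)
})

test_that("PAM is swap-optimal on unstructured data and matches cluster::pam cost", {
  skip_if_not_installed("cluster")
  set.seed(61)
  coords <- matrix(rnorm(60), 30, 2,
                   dimnames = list(sprintf("c%03d", 1:30), NULL))
  emb <- structure(list(coords = coords, method = "pca", seed = 1),
                   class = "embedding")
  dmat <- as.matrix(dist(coords))
  for (k in c(3, 5)) {
    cl <- cluster_pam(emb, k = k)
    expect_true(pam_swap_optimal(dmat, cl$medoids))
    ref <- cluster::pam(dist(coords), k = k)
    # both are local optima of the same objective; costs should agree closely
    expect_lte(cl$cost, ref$objective[["swap"]] * nrow(coords) * 1.001)
  }
})

test_that("each point as its own medoid gives zero cost", {
  coords <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE,
                   dimnames = list(paste0("c", 1:4), NULL))
  emb <- structure(list(coords = coords, method = "pca", seed = 1),
                   class = "embedding")
  cl <- cluster_pam(emb, k = 4)
  expect_equal(cl$cost, 0)
  expect_identical(sort(cl$medoids), 1:4)
  expect_error(cluster_pam(emb, k = 5), "exceed")
})

test_that("MST handles forced geometries and matches exhaustive enumeration", {
  mk_emb <- function(coords) {
    rownames(coords) <- sprintf("c%03d", seq_len(nrow(coords)))
    structure(list(coords = coords, method = "pca", seed = 1),
              class = "embedding")
  }
  mk_cl <- function(n) structure(list(labels = seq_len(n), medoids = seq_len(n),
                                      k = n, cost = 0, seed = 1),
                                 class = "clustering")
  # 3 collinear medoids -> path through the middle
  emb <- mk_emb(matrix(c(0, 0, 5, 0, 10, 0), 3, 2, byrow = TRUE))
  tree <- build_mst(mk_cl(3), emb)
  expect_identical(nrow(tree$edges), 2L)
  deg <- tabulate(c(tree$edges$from, tree$edges$to), 3)
  expect_identical(deg, c(1L, 2L, 1L))
  # k=2 -> the single edge
  emb2 <- mk_emb(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  tree2 <- build_mst(mk_cl(2), emb2)
  expect_equal(tree2$edges$length, 5)
  # random medoids, k <= 7: weight equals the exhaustive-enumeration optimum
  for (seed in 1:3) {
    set.seed(seed + 70)
    k <- sample(4:7, 1)
    coords <- matrix(rnorm(k * 3), k, 3)
    tr <- build_mst(mk_cl(k), mk_emb(coords))
    expect_identical(nrow(tr$edges), k - 1L)
    expect_equal(sum(tr$edges$length), mst_exhaustive_weight(coords),
                 tolerance = 1e-10)
  }
})

test_that("MST agrees with igraph on larger medoid sets", {
  skip_if_not_installed("igraph")
  set.seed(75)
  k <- 12
  coords <- matrix(rnorm(k * 3), k, 3,
                   dimnames = list(sprintf("c%03d", 1:k), NULL))
  emb <- structure(list(coords = coords, method = "pca", seed = 1),
                   class = "embedding")
  cl <- structure(list(labels = 1:k, medoids = 1:k, k = k, cost = 0, seed = 1),
                  class = "clustering")
  tree <- build_mst(cl, emb)
  g <- igraph::graph_from_adjacency_matrix(as.matrix(dist(coords)),
                                           weighted = TRUE, mode = "undirected")
  ref <- igraph::mst(g)
  expect_equal(sum(tree$edges$length), sum(igraph::E(ref)$weight),
               tolerance = 1e-10)
})

test_that("root selection maximizes pooled marker expression with index tie-break", {
  v <- matrix(0, 6, 2, dimnames = list(paste0("c", 1:6), c("MARK", "OTHER")))
  v[3:4, "MARK"] <- 5   # cells of cluster 2
  expr <- expression_matrix(v, state = "log1p")
  cl <- structure(list(labels = rep(1:3, each = 2), medoids = c(1L, 3L, 5L),
                       k = 3, cost = 0, seed = 1), class = "clustering")
  expect_identical(choose_root(cl, expr, gene_set("MARK")), 2L)
  # all clusters equal -> lowest index
  expect_identical(choose_root(cl, expression_matrix(v * 0, state = "log1p"),
                               gene_set("MARK")), 1L)
  # two markers disagreeing: pooled mean decides
  v2 <- v
  v2[1:2, "OTHER"] <- 2   # weaker marker in cluster 1
  expr2 <- expression_matrix(v2, state = "log1p")
  expect_identical(choose_root(cl, expr2, gene_set(c("MARK", "OTHER"))), 2L)
  expect_warning(choose_root(cl, expr, gene_set(c("MARK", "GONE"))), "missing")
  expect_error(choose_root(cl, expr, gene_set("GONE")), "no marker")
})

test_that("pseudotime assignment follows the root-to-leaf path", {
  # path graph 1-2-3 rooted at an end
  tree <- structure(list(k = 3,
                         edges = data.frame(from = c(1, 2), to = c(2, 3),
                                            length = c(1, 1)),
                         root = NA_integer_), class = "trajectory_tree")
  cl <- structure(list(labels = c(1L, 1L, 2L, 3L, 3L), medoids = c(1L, 3L, 4L),
                       k = 3, cost = 0, seed = 1), class = "clustering")
  ids <- paste0("c", 1:5)
  ct <- assign_pseudotime(tree, 1, cl, ids)
  expect_identical(ct$T, 3L)
  expect_identical(unname(ct$t_hat[ids]), c(1L, 1L, 2L, 3L, 3L))
  expect_identical(ct$trajectory, c(1, 2, 3))
  expect_identical(ct$excluded_cells, character(0))
  # star rooted at the center: on-path clusters get {1,2}, rest excluded
  star <- structure(list(k = 4,
                         edges = data.frame(from = c(1, 1, 1), to = 2:4,
                                            length = rep(1, 3)),
                         root = NA_integer_), class = "trajectory_tree")
  cl4 <- structure(list(labels = 1:4, medoids = 1:4, k = 4, cost = 0, seed = 1),
                   class = "clustering")
  ct2 <- assign_pseudotime(star, 1, cl4, paste0("s", 1:4), leaf = 3)
  expect_identical(ct2$T, 2L)
  expect_identical(sort(names(ct2$t_hat)), c("s1", "s3"))
  expect_setequal(ct2$excluded_cells, c("s2", "s4"))
  expect_error(assign_pseudotime(star, 2, cl4, paste0("s", 1:4), leaf = 1),
               "not a leaf")
  expect_error(assign_pseudotime(star, 1, cl4, paste0("s", 1:4), leaf = 1),
               "differ")
})

test_that("pseudotime recovers simulated linear trajectories", {
  taus <- vapply(1:10, function(seed) {
    sim <- simulate_trajectory(k_clusters = 5, cells_per_cluster = 30,
                               seed = seed)
    std <- standardize(sim$expr)
    res <- infer_pseudotime(std$expr, gene_set("STEM"), k = 5, d = 3, seed = seed)
    assigned <- names(res$times$t_hat)
    truth <- sim$true_time[match(assigned, rownames(sim$expr))]
    abs(cor(res$times$t_hat[assigned], truth, method = "kendall"))
  }, numeric(1))
  expect_gte(mean(taus >= 0.9), 0.9)
})

test_that("silhouette utility prefers the true cluster count on separated data", {
  set.seed(80)
  centers <- matrix(c(0, 0, 8, 0, 4, 7), 3, 2, byrow = TRUE)
  coords <- centers[rep(1:3, each = 15), ] + matrix(rnorm(90, sd = 0.4), 45, 2)
  rownames(coords) <- sprintf("c%03d", 1:45)
  emb <- structure(list(coords = coords, method = "pca", seed = 1),
                   class = "embedding")
  sug <- suggest_k(emb, k_range = 2:5)
  expect_identical(attr(sug, "best"), 3L)
})
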