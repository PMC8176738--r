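#' Reduce expression to a low-dimensional embedding
#'
#' Pseudotime staging operates in a low-dimensional embedding of the
#' standardized expression matrix. PCA (the default) is deterministic and
#' used throughout the test suite; t-SNE matches common single-cell
#' practice and is delegated to a user-supplied reducer function, since
#' its internals are outside this package's scope.
#'
#' @param expr standardized `expression_matrix`.
#' @param d embedding dimension (default 3, >= 2).
#' @param method `"pca"` or `"tsne"`.
#' @param seed integer seed; recorded and used so results are reproducible
#'   for any stochastic reducer (PCA ignores it beyond recording).
#' @param reducer for `method = "tsne"`: a `function(values, d, seed)`
#'   returning a cells x d coordinate matrix (e.g. a wrapper around an
#'   external t-SNE implementation).
#' @return An `embedding`: list with `coords` (cells x d, row names = cell
#'   IDs), `method`, `seed`.
#' @export
reduce_dimensions <- function(expr, d = 3L, method = c("pca", "tsne"),
                              seed = 1L, reducer = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  method <- match.arg(method)
  if (expr_state(expr) != "standardized")
    stop("reduce_dimensions requires standardized expression")
  d <- as.integer(d)
  if (d < 2) stop("embedding dimension d must be >= 2")
  if (d >= ncol(expr)) stop("d must be smaller than the number of genes")
  v <- expr_values(expr)
  if (method == "pca") {
    set.seed(seed)
    pc <- stats::prcomp(v, center = FALSE, scale. = FALSE, rank. = d)
    coords <- pc$x[, seq_len(d), drop = FALSE]
    # fix sign convention so the embedding is unique: largest-|loading|
    # entry of each component is positive
    for (c in seq_len(d)) {
      ld <- pc$rotation[, c]
      if (ld[which.max(abs(ld))] < 0) coords[, c] <- -coords[, c]
    }
  } else {
    if (is.null(reducer))
      stop("method='tsne' needs a `reducer` function(values, d, seed); ",
           "supply one wrapping your preferred t-SNE implementation")
    set.seed(seed)
    coords <- reducer(v, d, seed)
    if (!is.matrix(coords) || nrow(coords) != nrow(v) || ncol(coords) != d)
      stop("reducer must return a cells x d matrix")
  }
  rownames(coords) <- rownames(v)
  colnames(coords) <- paste0("dim", seq_len(d))
  structure(list(coords = coords, method = method, seed = seed),
            class = "embedding")
}

#' Partition around medoids (PAM) in embedding space
#'
#' Classic BUILD + SWAP PAM on Euclidean distances. BUILD greedily seeds k
#' medoids; SWAP repeatedly applies the best cost-reducing
#' (medoid, non-medoid) exchange until no swap lowers the total
#' dissimilarity. Entirely deterministic (ties broken by lowest index);
#' the seed argument is recorded for interface symmetry with stochastic
#' reducers.
#'
#' @param emb an [reduce_dimensions()] embedding.
#' @param k number of clusters (2 <= k <= number of distinct points).
#' @param seed recorded in the result; the algorithm itself is
#'   deterministic.
#' @return A `clustering`: list with `labels` (per-cell cluster in 1..k),
#'   `medoids` (cell indices, one per cluster; the medoid of cluster c has
#'   label c), `k`, `cost` (total distance of points to their medoids).
#' @export
cluster_pam <- function(emb, k, seed = 1L) {
  stopifnot(inherits(emb, "embedding"))
  x <- emb$coords
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k cannot exceed the number of cells")
  dmat <- as.matrix(stats::dist(x))
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct points")

  # BUILD: first medoid minimizes total distance; each next medoid gives
  # the largest reduction in total distance-to-nearest-medoid
  medoids <- integer(0)
  dnear <- rep(Inf, n)
  for (step in seq_len(k)) {
    if (step == 1) {
      best <- which.min(colSums(dmat))
    } else {
      red <- vapply(seq_len(n), function(cand)
        if (cand %in% medoids) -Inf else sum(pmax(dnear - dmat[, cand], 0)),
        numeric(1))
      best <- which.max(red)
    }
    medoids <- c(medoids, unname(best))
    dnear <- pmin(dnear, dmat[, best])
  }

  # SWAP: best-improvement exchanges until convergence
  repeat {
    assign_near <- nearest_two(dmat, medoids)
    best_delta <- 0
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      m <- medoids[mi]
      d1 <- assign_near$d1; d2 <- assign_near$d2
      is_m <- assign_near$i1 == m
      for (h in seq_len(n)) {
        if (h %in% medoids) next
        dh <- dmat[, h]
        # cost change of replacing medoid m by h
        new_d <- ifelse(is_m, pmin(d2, dh), pmin(d1, dh))
        delta <- sum(new_d) - sum(d1)
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
  }

  medoids <- sort(unname(medoids))
  labels <- apply(dmat[, medoids, drop = FALSE], 1, which.min)
  labels[medoids] <- seq_along(medoids)   # medoid of cluster c has label c
  structure(list(labels = as.integer(labels), medoids = medoids, k = k,
                 cost = sum(dmat[cbind(seq_len(n), medoids[labels])]),
                 seed = seed),
            class = "clustering")
}

# nearest and second-nearest medoid distances per point
nearest_two <- function(dmat, medoids) {
  dm <- dmat[, medoids, drop = FALSE]
  ord1 <- apply(dm, 1, which.min)
  d1 <- dm[cbind(seq_len(nrow(dm)), ord1)]
  dm2 <- dm
  dm2[cbind(seq_len(nrow(dm)), ord1)] <- Inf
  ord2 <- apply(dm2, 1, which.min)
  d2 <- dm2[cbind(seq_len(nrow(dm)), ord2)]
  list(d1 = d1, d2 = d2, i1 = medoids[ord1])
}

#' Silhouette-based suggestion for the number of clusters
#'
#' Runs [cluster_pam()] over a range of k and reports the mean silhouette
#' width of each, as a guide when no biologically motivated k is at hand.
#'
#' @param emb an embedding.
#' @param k_range integer vector of candidate k values.
#' @return data.frame with columns `k` and `mean_silhouette`, plus
#'   attribute `best` (k with the highest mean silhouette).
#' @export
suggest_k <- function(emb, k_range = 2:10) {
  stopifnot(inherits(emb, "embedding"))
  dmat <- as.matrix(stats::dist(emb$coords))
  res <- vapply(k_range, function(k) {
    cl <- cluster_pam(emb, k)
    mean(silhouette_widths(dmat, cl$labels))
  }, numeric(1))
  out <- data.frame(k = k_range, mean_silhouette = res)
  attr(out, "best") <- k_range[which.max(res)]
  out
}

silhouette_widths <- function(dmat, labels) {
  n <- nrow(dmat)
  ks <- sort(unique(labels))
  vapply(seq_len(n), function(i) {
    own <- labels[i]
    same <- which(labels == own)
    a <- if (length(same) > 1) mean(dmat[i, setdiff(same, i)]) else 0
    b <- min(vapply(setdiff(ks, own),
                    function(c2) mean(dmat[i, labels == c2]), numeric(1)))
    if (length(same) > 1) (b - a) / max(a, b) else 0
  }, numeric(1))
}

#' Minimum spanning tree over cluster medoids
#'
#' Kruskal's algorithm on Euclidean distances between medoid coordinates;
#' equal-weight edges are taken in lexicographic (i, j) order, so the tree
#' is deterministic.
#'
#' @param clust a [cluster_pam()] clustering.
#' @param emb the embedding the clustering was computed in.
#' @return A `trajectory_tree`: list with `k`, `edges` (data.frame
#'   `from`, `to`, `length`, with `from < to`) and `root` (`NA` until
#'   rooted by [assign_pseudotime()]).
#' @export
build_mst <- function(clust, emb) {
  stopifnot(inherits(clust, "clustering"), inherits(emb, "embedding"))
  k <- clust$k
  if (k < 2) stop("need at least 2 clusters")
  coords <- emb$coords[clust$medoids, , drop = FALSE]
  cand <- utils::combn(k, 2)
  len <- sqrt(colSums((t(coords[cand[1, ], , drop = FALSE]) -
                       t(coords[cand[2, ], , drop = FALSE]))^2))
  ord <- order(len, cand[1, ], cand[2, ])
  parent <- seq_len(k)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  from <- to <- integer(0); w <- numeric(0)
  for (e in ord) {
    ra <- find(cand[1, e]); rb <- find(cand[2, e])
    if (ra != rb) {
      parent[ra] <- rb
      from <- c(from, cand[1, e]); to <- c(to, cand[2, e]); w <- c(w, len[e])
      if (length(from) == k - 1) break
    }
  }
  structure(list(k = k,
                 edges = data.frame(from = from, to = to, length = w),
                 root = NA_integer_),
            class = "trajectory_tree")
}

tree_adjacency <- function(tree) {
  adj <- vector("list", tree$k)
  for (e in seq_len(nrow(tree$edges))) {
    a <- tree$edges$from[e]; b <- tree$edges$to[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

# BFS hop distances and parents from a root
tree_bfs <- function(tree, root) {
  adj <- tree_adjacency(tree)
  dist <- rep(NA_integer_, tree$k)
  parent <- rep(NA_integer_, tree$k)
  dist[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (nb in adj[[v]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[v] + 1L
        parent[nb] <- v
        queue <- c(queue, nb)
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Choose the root (stem-cell) cluster by marker expression
#'
#' The trajectory root is the cluster whose member cells have the highest
#' mean expression of the supplied stem-cell marker genes (pooled over
#' cells and markers). Ties break to the lowest cluster index. Markers
#' missing from the expression matrix are dropped with a warning; no
#' overlap at all is an error.
#'
#' @param clust a clustering.
#' @param expr an `expression_matrix` aligned (same cell order) with the
#'   embedding the clustering was built from.
#' @param stem_markers a [gene_set()] of stem-cell marker genes.
#' @return Root cluster index.
#' @export
choose_root <- function(clust, expr, stem_markers) {
  stopifnot(inherits(clust, "clustering"), inherits(expr, "expression_matrix"),
            inherits(stem_markers, "gene_set"))
  markers <- stem_markers$members
  present <- markers[markers %in% colnames(expr)]
  if (length(present) == 0)
    stop("no marker gene of set '", stem_markers$name, "' is in the expression matrix")
  if (length(present) < length(markers))
    warning("markers missing from expression matrix: ",
            paste(setdiff(markers, present), collapse = ", "))
  v <- expr_values(expr)[, present, drop = FALSE]
  means <- vapply(seq_len(clust$k),
                  function(c) mean(v[clust$labels == c, , drop = FALSE]),
                  numeric(1))
  which.max(means)   # which.max takes the first (lowest index) on ties
}

#' Assign integer pseudotime along a root-to-leaf trajectory
#'
#' Roots the medoid tree at the stem-cell cluster, follows the unique path
#' to the chosen leaf, and stamps cells of the cluster at hop distance h
#' with time bin `t_hat = h + 1`. Cells in clusters off that path belong
#' to other branches of the lineage and are excluded from this
#' trajectory's assignment (reported in `excluded_cells`, never silently).
#' `T` equals the number of clusters on the path.
#'
#' @param tree a [build_mst()] tree.
#' @param root root cluster index (see [choose_root()]).
#' @param clust the clustering the tree was built from.
#' @param cell_ids cell IDs in clustering order (e.g.
#'   `rownames(emb$coords)`).
#' @param leaf terminal cluster index, or `"auto"` for the farthest leaf
#'   from the root by hop count (ties to the lowest index).
#' @return A [cell_times()] with `trajectory` = ordered cluster path and
#'   off-path cells listed in `excluded_cells`.
#' @export
assign_pseudotime <- function(tree, root, clust, cell_ids, leaf = "auto") {
  stopifnot(inherits(tree, "trajectory_tree"), inherits(clust, "clustering"))
  if (!root %in% seq_len(tree$k)) stop("root is not a tree node")
  bfs <- tree_bfs(tree, root)
  adj <- tree_adjacency(tree)
  degree <- lengths(adj)
  if (identical(leaf, "auto")) {
    leaf <- which.max(bfs$dist)   # farthest node from the root is a leaf
  } else {
    leaf <- as.integer(leaf)
    if (!leaf %in% seq_len(tree$k)) stop("leaf is not a tree node")
    if (leaf == root) stop("leaf must differ from the root")
    if (degree[leaf] != 1) stop("cluster ", leaf, " is not a leaf of the tree")
  }
  path <- leaf
  while (path[1] != root) path <- c(bfs$parent[path[1]], path)
  hop <- stats::setNames(seq_along(path) - 1L, path)
  on_path <- clust$labels %in% path
  t_hat <- hop[as.character(clust$labels[on_path])] + 1L
  names(t_hat) <- cell_ids[on_path]
  cell_times(t_hat, trajectory = path,
             excluded_cells = cell_ids[!on_path])
}

#' One-call pseudotime staging
#'
#' Convenience pipeline: [reduce_dimensions()] -> [cluster_pam()] ->
#' [build_mst()] -> [choose_root()] -> [assign_pseudotime()].
#'
#' @inheritParams reduce_dimensions
#' @inheritParams cluster_pam
#' @param stem_markers a [gene_set()] of root markers.
#' @param leaf terminal cluster or `"auto"`.
#' @return List with `times` (a [cell_times()]), `embedding`,
#'   `clustering`, `tree`, `root`.
#' @export
infer_pseudotime <- function(expr, stem_markers, k, d = 3L,
                             method = c("pca", "tsne"), seed = 1L,
                             leaf = "auto", reducer = NULL) {
  emb <- reduce_dimensions(expr, d = d, method = method, seed = seed,
                           reducer = reducer)
  clust <- cluster_pam(emb, k = k, seed = seed)
  tree <- build_mst(clust, emb)
  root <- choose_root(clust, expr, stem_markers)
  times <- assign_pseudotime(tree, root, clust, rownames(emb$coords), leaf = leaf)
  list(times = times, embedding = emb, clustering = clust, tree = tree,
       root = root)
}
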