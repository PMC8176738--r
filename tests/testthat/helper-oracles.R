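# Independent oracles used to validate the implementation.

# High-precision solver for F(beta) = ||y - X beta||^2 + lambda ||D beta||_1
# via the dual box-constrained QP: v* = argmax_{|v|_inf <= lambda} g(v) with
# beta(v) = beta_ols - (X'X)^{-1} D' v / 2, solved by long-run projected
# gradient ascent. A different formulation and algorithm from the primal
# ADMM it checks. Requires X of full column rank.
genlasso_oracle <- function(X, y, Dm, lambda, iters = 300000, gap_tol = 1e-11) {
  X <- as.matrix(X)
  Dd <- as.matrix(Dm)
  XtXi <- solve(crossprod(X))
  beta_ols <- as.numeric(XtXi %*% crossprod(X, y))
  H <- Dd %*% XtXi %*% t(Dd) / 2
  cvec <- as.numeric(Dd %*% beta_ols)
  L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  primal_obj <- function(b) sum((y - X %*% b)^2) + lambda * sum(abs(Dd %*% b))
  beta_of <- function(v) beta_ols - as.numeric(XtXi %*% (t(Dd) %*% v)) / 2
  v <- numeric(nrow(Dd))
  if (lambda > 0 && L > 0) {
    for (i in seq_len(iters)) {
      v <- pmin(pmax(v + (cvec - as.numeric(H %*% v)) / L, -lambda), lambda)
      if (i %% 2000 == 0) {
        b <- beta_of(v)
        dual_val <- sum((y - X %*% b)^2) + sum(v * (Dd %*% b))
        if (primal_obj(b) - dual_val < gap_tol * max(1, primal_obj(b))) break
      }
    }
  }
  b <- beta_of(v)
  list(beta = b, obj = primal_obj(b))
}

# Exhaustive minimum-spanning-tree oracle: minimum total weight over every
# spanning tree, by enumerating all (k-1)-subsets of the candidate edges.
mst_exhaustive_weight <- function(coords) {
  k <- nrow(coords)
  cand <- utils::combn(k, 2)
  len <- sqrt(colSums((t(coords[cand[1, ], , drop = FALSE]) -
                       t(coords[cand[2, ], , drop = FALSE]))^2))
  ne <- ncol(cand)
  best <- Inf
  for (sel in utils::combn(ne, k - 1, simplify = FALSE)) {
    parent <- seq_len(k)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    merged <- 0
    for (e in sel) {
      ra <- find(cand[1, e]); rb <- find(cand[2, e])
      if (ra != rb) { parent[ra] <- rb; merged <- merged + 1 }
    }
    if (merged == k - 1) best <- min(best, sum(len[sel]))
  }
  best
}

# total PAM cost of an arbitrary medoid set
pam_cost <- function(dmat, medoids) {
  sum(apply(dmat[, medoids, drop = FALSE], 1, min))
}

# TRUE if no single (medoid, non-medoid) exchange lowers the cost
pam_swap_optimal <- function(dmat, medoids, tol = 1e-10) {
  base <- pam_cost(dmat, medoids)
  n <- nrow(dmat)
  for (mi in seq_along(medoids)) {
    for (h in setdiff(seq_len(n), medoids)) {
      trial <- medoids
      trial[mi] <- h
      if (pam_cost(dmat, trial) < base - tol) return(FALSE)
    }
  }
  TRUE
}

# standardized expression matrix from a plain numeric matrix (test plumbing)
make_std_expr <- function(v, cells = sprintf("c%03d", seq_len(nrow(v))),
                          genes = sprintf("g%03d", seq_len(ncol(v)))) {
  dimnames(v) <- list(cells, genes)
  z <- scale(v)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  expression_matrix(z, state = "standardized")
}

# design bundle straight from components (bypasses the io pipeline)
make_design <- function(X, y, bin, target = "TG",
                        predictors = sprintf("G%03d", seq_len(ncol(X)))) {
  structure(list(X = X, y = y, bin = as.integer(bin),
                 predictors = predictors, target = target,
                 T = max(as.integer(bin))),
            class = "design_bundle")
}

# dense expansion of a design to the (p-1)*T column space (time-major)
expand_design_dense <- function(design) {
  p1 <- ncol(design$X)
  out <- matrix(0, nrow(design$X), p1 * design$T)
  for (c in seq_len(nrow(design$X)))
    out[c, (design$bin[c] - 1) * p1 + seq_len(p1)] <- design$X[c, ]
  out
}

# random solvable instance for solver tests: balanced bins so every
# per-bin block (and hence the expanded design) has full column rank
random_instance <- function(seed, n = 30, p1 = 4, T_bins = 3,
                            mixed_weights = TRUE) {
  set.seed(seed)
  stopifnot(n >= (p1 + 1) * T_bins)
  bin <- sort(rep_len(seq_len(T_bins), n))
  X <- matrix(rnorm(n * p1), n, p1)
  beta_true <- rnorm(p1) * rbinom(p1, 1, 0.5)
  y <- as.numeric(X %*% beta_true) + rnorm(n, sd = 0.5)
  w <- if (mixed_weights) sample(c(1, 0.25, 0.625), p1, replace = TRUE) else rep(1, p1)
  list(design = make_design(X, y, bin), w = w)
}
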