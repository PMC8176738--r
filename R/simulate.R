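#' Deterministic child seeds from one master seed
#'
#' All generators fan out from a single user seed: component `idx` uses
#' `(seed * 48271 + idx) mod (2^31 - 1)` (a Lehmer-style mix), so the same
#' master seed always reproduces the full dataset while components stay
#' decoupled.
#'
#' @param seed master integer seed.
#' @param idx component index (>= 0).
#' @return A child seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, idx) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(idx)
  as.integer(s %% 2147483646) + 1L
}

#' Simulate ground-truth time-varying coefficients
#'
#' Draws `k` true regulators uniformly among the `p - 1` predictor genes.
#' Each regulator switches on at a uniformly drawn changepoint bin `t0`
#' and from then on carries a constant coefficient with magnitude
#' `Uniform[effect_range]` and random sign; before `t0` (and for all
#' non-regulators at all times) the coefficient is exactly zero. This is
#' the piecewise-constant, sparse, smoothly varying structure the fused
#' penalty is designed to recover.
#'
#' @param p number of genes (target + `p - 1` predictors).
#' @param T_bins number of time bins.
#' @param k number of true regulators (`k < p`).
#' @param effect_range magnitude range `c(lo, hi)`, `0 < lo <= hi`.
#' @param noise_sd Gaussian noise sd of the forward model (default 0.5).
#' @param seed integer seed.
#' @return A `ground_truth`: list with `b_star` (T x (p-1)),
#'   `true_regulators` (predictor indices), `changepoints`, `noise_sd`,
#'   `effect_range`, `seed`, `predictors`, `target` (gene IDs).
#' @export
simulate_truth <- function(p, T_bins, k, effect_range = c(0.5, 1),
                           noise_sd = 0.5, seed = 1L) {
  if (k >= p) stop("k must be smaller than p")
  if (k < 0) stop("k must be >= 0")
  stopifnot(length(effect_range) == 2, effect_range[1] > 0,
            effect_range[1] <= effect_range[2], noise_sd >= 0)
  p1 <- p - 1L
  predictors <- sprintf("G%04d", seq_len(p1))
  set.seed(child_seed(seed, 1))
  regs <- sort(sample.int(p1, k))
  b_star <- matrix(0, nrow = T_bins, ncol = p1,
                   dimnames = list(paste0("t", seq_len(T_bins)), predictors))
  changepoints <- integer(0)
  if (k > 0) {
    mag <- stats::runif(k, effect_range[1], effect_range[2])
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    changepoints <- sample.int(T_bins, k, replace = TRUE)
    for (r in seq_len(k))
      b_star[changepoints[r]:T_bins, regs[r]] <- sgn[r] * mag[r]
    names(changepoints) <- predictors[regs]
  }
  structure(list(b_star = b_star, true_regulators = regs,
                 changepoints = changepoints, noise_sd = noise_sd,
                 effect_range = effect_range, seed = seed,
                 predictors = predictors, target = "TARGET"),
            class = "ground_truth")
}

#' Simulate expression from the forward model
#'
#' Per cell in bin t: predictors `x ~ iid N(0, 1)`, target
#' `y = b_star[t, ] . x + eps`, `eps ~ N(0, noise_sd^2)` — the linear
#' model with Gaussian errors underlying the network fit. The assembled
#' matrix (target gene first, then predictors) is returned on the raw
#' count-like scale via `expm1` clipped at zero, so the full io pipeline
#' (log1p then standardization) is exercised downstream; the un-clipped
#' model-scale matrix is kept in `latent` for noise-free checks.
#'
#' @param truth a [simulate_truth()] object.
#' @param cells_per_bin cells in each time bin (>= 1).
#' @param ar1_rho within-block AR(1) correlation of the predictors
#'   (default 0 = independent). Non-zero values produce correlated
#'   predictor blocks, the stress scenario in which lasso selection
#'   becomes unstable and consistency aggregation earns its keep.
#' @param block_size size of each correlated predictor block (used when
#'   `ar1_rho > 0`; correlation never crosses block boundaries).
#' @param seed integer seed.
#' @return List with `expr` (raw-scale `expression_matrix`), `times`
#'   (a [cell_times()]), `latent` (model-scale matrix), `truth`.
#' @export
simulate_expression <- function(truth, cells_per_bin, ar1_rho = 0,
                                block_size = 10L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), cells_per_bin >= 1,
            ar1_rho >= 0, ar1_rho < 1, block_size >= 1)
  T_bins <- nrow(truth$b_star)
  p1 <- ncol(truth$b_star)
  n <- T_bins * cells_per_bin
  set.seed(child_seed(seed, 2))
  bin <- rep(seq_len(T_bins), each = cells_per_bin)
  X <- matrix(stats::rnorm(n * p1), nrow = n, ncol = p1)
  if (ar1_rho > 0) {
    # within each block, column k = rho * column (k-1) + sqrt(1-rho^2) * innov,
    # so every column stays standard normal with corr(j, j') = rho^|j - j'|
    for (j in 2:p1) {
      if ((j - 1) %% block_size == 0) next   # first column of a new block
      X[, j] <- ar1_rho * X[, j - 1] + sqrt(1 - ar1_rho^2) * X[, j]
    }
  }
  eps <- stats::rnorm(n, sd = truth$noise_sd)
  y <- rowSums(X * truth$b_star[bin, , drop = FALSE]) + eps
  latent <- cbind(y, X)
  cell_ids <- sprintf("cell%05d", seq_len(n))
  dimnames(latent) <- list(cell_ids, c(truth$target, truth$predictors))
  raw <- pmax(expm1(latent), 0)
  times <- cell_times(stats::setNames(bin, cell_ids))
  list(expr = expression_matrix(raw, state = "raw"),
       times = times, latent = latent, truth = truth)
}

#' Simulate binding priors concentrated on the true regulators
#'
#' Emulates footprinting posteriors: each true regulator receives a
#' high-confidence entry `p ~ Uniform[0.9, 1]` with probability
#' `fidelity` (otherwise no entry); each non-regulator receives a
#' sub-threshold entry `p ~ Uniform[0, p_min)` with probability
#' `background` (noise that the weighting rule must ignore).
#'
#' @param truth a [simulate_truth()] object.
#' @param fidelity probability a true regulator gets an evidence entry.
#' @param background probability a non-regulator gets a sub-threshold
#'   entry.
#' @param p_min the evidence cutoff the background entries stay below.
#' @param seed integer seed.
#' @return A [binding_priors()] table keyed to `truth$target`.
#' @export
simulate_priors <- function(truth, fidelity = 1, background = 0,
                            p_min = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            fidelity >= 0, fidelity <= 1, background >= 0, background <= 1)
  p1 <- length(truth$predictors)
  set.seed(child_seed(seed, 3))
  reg <- character(0); prob <- numeric(0)
  is_reg <- seq_len(p1) %in% truth$true_regulators
  take_reg <- is_reg & stats::runif(p1) < fidelity
  take_bg <- !is_reg & stats::runif(p1) < background
  if (any(take_reg)) {
    reg <- c(reg, truth$predictors[take_reg])
    prob <- c(prob, stats::runif(sum(take_reg), 0.9, 1))
  }
  if (any(take_bg)) {
    reg <- c(reg, truth$predictors[take_bg])
    prob <- c(prob, stats::runif(sum(take_bg), 0, p_min - 1e-9))
  }
  binding_priors(reg, rep(truth$target, length(reg)), prob)
}

#' Simulate a full dataset (truth + expression + priors)
#'
#' @inheritParams simulate_truth
#' @inheritParams simulate_expression
#' @inheritParams simulate_priors
#' @return List with `expr`, `times`, `priors`, `truth`, `latent`.
#' @export
simulate_dataset <- function(p = 201, T_bins = 5, k = 5,
                             effect_range = c(0.5, 1), noise_sd = 0.5,
                             cells_per_bin = 100, fidelity = 1,
                             background = 0, p_min = 0.5, ar1_rho = 0,
                             block_size = 10L, seed = 1L) {
  truth <- simulate_truth(p, T_bins, k, effect_range, noise_sd, seed)
  ds <- simulate_expression(truth, cells_per_bin, ar1_rho = ar1_rho,
                             block_size = block_size, seed = seed)
  priors <- simulate_priors(truth, fidelity, background, p_min, seed)
  list(expr = ds$expr, times = ds$times, priors = priors, truth = truth,
       latent = ds$latent)
}

#' Simulate a drifting-cluster developmental trajectory
#'
#' Emulates the geometry pseudotime staging assumes: `k_clusters` cluster
#' means advance by `drift` along a fixed random unit direction in
#' `dim`-dimensional gene space (optionally with a branch leaving the
#' midpoint at a right angle), and cells scatter around their cluster
#' mean with isotropic Gaussian noise of sd `noise_sd`. With
#' `drift >> noise_sd` the chain of clusters is well separated and the
#' PAM + MST pipeline should recover the ordering; `drift = 0` is the
#' negative control under which the ordering is unidentifiable.
#'
#' @param k_clusters number of clusters along the trajectory (>= 2).
#' @param cells_per_cluster cells per cluster.
#' @param drift distance between adjacent cluster means, in units of the
#'   per-gene noise sd (default 5). Note that after per-gene
#'   standardization the signal spread of each gene is capped at one sd,
#'   so cluster separation in the embedding grows with `sqrt(dim)` rather
#'   than with `drift` once `drift` is a few noise sd; `dim` is the lever
#'   that controls how resolved the clusters are.
#' @param dim dimensionality of the simulated gene space (default 50,
#'   emulating a trajectory driven by tens of genes; see `drift` for why
#'   this, not the drift distance, sets the cluster resolution).
#' @param noise_sd isotropic noise sd (default 1).
#' @param branch if `TRUE`, the second half of the clusters leaves the
#'   midpoint along an orthogonal direction.
#' @param stem_marker if `TRUE` (default), append a `"STEM"` gene whose
#'   mean expression decreases linearly from the first cluster to the
#'   last, emulating a stem-cell marker for [choose_root()].
#' @param seed integer seed.
#' @return List with `expr` (an `expression_matrix` on the log1p scale,
#'   ready for [standardize()]), `true_time` (per-cell cluster order
#'   1..k), `means` (cluster mean matrix).
#' @export
simulate_trajectory <- function(k_clusters, cells_per_cluster, drift = 5,
                                dim = 50, noise_sd = 1, branch = FALSE,
                                stem_marker = TRUE, seed = 1L) {
  if (k_clusters < 2) stop("need at least 2 clusters")
  set.seed(child_seed(seed, 4))
  dir1 <- stats::rnorm(dim); dir1 <- dir1 / sqrt(sum(dir1^2))
  means <- outer(0:(k_clusters - 1), dir1) * drift
  if (branch) {
    dir2 <- stats::rnorm(dim)
    dir2 <- dir2 - sum(dir2 * dir1) * dir1
    dir2 <- dir2 / sqrt(sum(dir2^2))
    mid <- ceiling(k_clusters / 2)
    for (c in (mid + 1):k_clusters)
      means[c, ] <- means[mid, ] + (c - mid) * drift * dir2
  }
  if (stem_marker)
    means <- cbind(means, drift * (k_clusters - seq_len(k_clusters)) / 2)
  n <- k_clusters * cells_per_cluster
  true_time <- rep(seq_len(k_clusters), each = cells_per_cluster)
  coords <- means[true_time, , drop = FALSE] +
    matrix(stats::rnorm(n * ncol(means), sd = noise_sd), nrow = n)
  gene_ids <- sprintf("G%04d", seq_len(dim))
  if (stem_marker) gene_ids <- c(gene_ids, "STEM")
  dimnames(coords) <- list(sprintf("cell%05d", seq_len(n)), gene_ids)
  list(expr = expression_matrix(coords, state = "log1p"),
       true_time = true_time, means = means)
}
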