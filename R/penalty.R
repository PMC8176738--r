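#' Penalty configuration
#'
#' Parameters of the binding-weighted generalized-lasso penalty.
#'
#' @param lambda overall sparsity level (> 0). Default 20, the value found
#'   optimal for this model family in earlier work on the same likelihood.
#' @param eta maximum down-weighting factor (> 1): a regulator with maximal
#'   binding evidence has its penalty rows scaled down to `1/eta`. Default 4.
#' @param p_min minimum binding probability treated as evidence, in (0, 1).
#'   Probabilities below `p_min` (or absent) leave the weight at 1. Default
#'   0.5: footprinting posteriors are strongly bimodal, so a mid-scale cut
#'   separates the evidence mode from background. Prominently configurable.
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(lambda = 20, eta = 4, p_min = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single non-negative number")
  if (!is.numeric(eta) || length(eta) != 1 || !(eta > 1))
    stop("eta must be a single number > 1")
  if (!is.numeric(p_min) || length(p_min) != 1 || !(p_min > 0 && p_min < 1))
    stop("p_min must be in (0, 1)")
  structure(list(lambda = lambda, eta = eta, p_min = p_min),
            class = "penalty_config")
}

#' Penalty weight from a binding probability
#'
#' Maps a regulator-to-target binding probability `p_ji` to the shared
#' magnitude of that regulator's rows in the penalty matrix:
#' `1/eta + (eta-1)/eta * log(p_ji)/log(p_min)` when `p_ji >= p_min`
#' (natural logs), and 1 otherwise. Absent evidence (`NA`) also gives 1.
#' The weight is continuous at `p_min`, decreases monotonically to `1/eta`
#' at `p_ji = 1`, and scales linearly in `log(p_ji)` so the penalty stays
#' on the log-probability scale of the likelihood it augments.
#'
#' @param p_ji binding probability in \[0, 1\], or `NA` for no evidence;
#'   vectorized.
#' @param cfg a [penalty_config()].
#' @return Numeric weights in \[1/eta, 1\].
#' @export
binding_weight <- function(p_ji, cfg = penalty_config()) {
  stopifnot(inherits(cfg, "penalty_config"))
  if (any(!is.na(p_ji) & (p_ji < 0 | p_ji > 1)))
    stop("binding probabilities must be in [0, 1]")
  w <- rep(1, length(p_ji))
  idx <- which(!is.na(p_ji) & p_ji >= cfg$p_min)
  if (length(idx))
    w[idx] <- 1 / cfg$eta +
      (cfg$eta - 1) / cfg$eta * log(p_ji[idx]) / log(cfg$p_min)
  w
}

#' Per-predictor weight vector for one target gene
#'
#' Looks up each predictor's binding probability against the target and
#' converts it via [binding_weight()]. Predictors without an entry get
#' weight 1.
#'
#' @param target target gene ID (must not appear among `predictors`).
#' @param predictors ordered character vector of predictor gene IDs.
#' @param priors a [binding_priors()] table.
#' @param cfg a [penalty_config()].
#' @return Numeric vector of weights aligned with `predictors` (named).
#' @export
build_weight_vector <- function(target, predictors, priors, cfg = penalty_config()) {
  stopifnot(inherits(priors, "binding_priors"))
  if (target %in% predictors)
    stop("target gene '", target, "' must not be among the predictors")
  p <- prior_lookup(priors, predictors, rep(target, length(predictors)))
  stats::setNames(binding_weight(p, cfg), predictors)
}

#' Build the generalized-lasso penalty matrix D
#'
#' For `p1 = length(w)` predictor genes and `T` time bins, builds the
#' sparse `(2T-1) * p1` by `p1 * T` matrix whose rows encode sparsity
#' within time (one entry `w_j` per gene per bin) and sparsity across time
#' (`+w_j` / `-w_j` for the same gene at adjacent bins). All `2T-1` rows of
#' gene `j` share the single magnitude `w_j`. Coefficients are indexed
#' time-major: coefficient (t, j) sits at column `(t-1) * p1 + j`, i.e.
#' the vectorization of the transposed T x p1 coefficient matrix.
#'
#' @param w per-gene weight vector (see [build_weight_vector()]).
#' @param T_bins number of time bins (>= 1).
#' @return An object of class `penalty_matrix`: a list with `D` (sparse
#'   `dgCMatrix`), `p1`, `T_bins` and `weights`.
#' @export
build_penalty_matrix <- function(w, T_bins) {
  p1 <- length(w)
  if (p1 == 0) stop("weight vector must be non-empty")
  if (!is.numeric(T_bins) || length(T_bins) != 1 || T_bins < 1)
    stop("T_bins must be a positive integer")
  T_bins <- as.integer(T_bins)
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive and finite")
  # within-time rows: row (t-1)*p1+j has w_j at column (t-1)*p1+j
  n_within <- p1 * T_bins
  i_w <- seq_len(n_within)
  j_w <- seq_len(n_within)
  x_w <- rep(w, times = T_bins)
  # across-time rows: for t in 2..T, gene j: +w_j at (t-1)*p1+j, -w_j at (t-2)*p1+j
  if (T_bins > 1) {
    n_across <- p1 * (T_bins - 1)
    row_a <- n_within + seq_len(n_across)
    t_idx <- rep(2:T_bins, each = p1)
    g_idx <- rep(seq_len(p1), times = T_bins - 1)
    i_a <- c(row_a, row_a)
    j_a <- c((t_idx - 1) * p1 + g_idx, (t_idx - 2) * p1 + g_idx)
    x_a <- c(rep(w, T_bins - 1), -rep(w, T_bins - 1))
  } else {
    i_a <- j_a <- x_a <- numeric(0)
  }
  D <- Matrix::sparseMatrix(i = c(i_w, i_a), j = c(j_w, j_a), x = c(x_w, x_a),
                            dims = c((2 * T_bins - 1) * p1, p1 * T_bins))
  structure(list(D = D, p1 = p1, T_bins = T_bins, weights = w),
            class = "penalty_matrix")
}

#' @export
print.penalty_matrix <- function(x, ...) {
  cat(sprintf("<penalty_matrix> %d x %d (p-1=%d genes, T=%d bins)\n",
              nrow(x$D), ncol(x$D), x$p1, x$T_bins))
  invisible(x)
}

#' Map a (time, gene) coefficient to its column index in vec(b^T)
#' @param t time bin, `j` gene index, `p1` number of predictor genes.
#' @param j,p1 see above.
#' @return Integer column index `(t-1)*p1 + j`.
#' @export
coef_index <- function(t, j, p1) (t - 1L) * p1 + j
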