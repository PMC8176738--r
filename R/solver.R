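#' Solver configuration
#'
#' @param tol_abs absolute stopping tolerance on the ADMM residuals
#'   (default 1e-6).
#' @param tol_rel relative stopping tolerance (default 1e-4).
#' @param max_iter iteration cap (default 5000); hitting it flags
#'   non-convergence in the fit report but still returns the iterate.
#' @param rho initial ADMM penalty parameter (default 1).
#' @param tau edge threshold on standardized coefficients (default 0.05):
#'   fitted `|b|` below `tau` is treated as trivially small and removed by
#'   [threshold_coefficients()].
#' @param adapt_rho if `TRUE` (default), rho is rebalanced during the run
#'   (doubled/halved when the primal and dual residuals drift more than a
#'   factor of 10 apart, checked every 10 iterations), refactorizing the
#'   cached system on each change. Deterministic; set `FALSE` to keep rho
#'   fixed.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(tol_abs = 1e-6, tol_rel = 1e-4, max_iter = 5000,
                          rho = 1, tau = 0.05, adapt_rho = TRUE) {
  vals <- c(tol_abs = tol_abs, tol_rel = tol_rel, max_iter = max_iter, rho = rho)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("tol_abs, tol_rel, max_iter and rho must all be positive")
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  structure(list(tol_abs = tol_abs, tol_rel = tol_rel,
                 max_iter = as.integer(max_iter), rho = rho, tau = tau,
                 adapt_rho = isTRUE(adapt_rho)),
            class = "solver_config")
}

#' Assemble the per-target regression design
#'
#' Groups cells by their pseudotime bin and sets up the response (target
#' gene) and predictor block (all other retained genes) for one local
#' model fit. Cells without a time assignment are excluded with a warning;
#' an empty time bin is an error because the fused penalty needs every
#' adjacent-bin pair.
#'
#' @param expr a standardized `expression_matrix`.
#' @param times a [cell_times()] assignment.
#' @param target target gene ID (must be among the expression genes).
#' @return A `design_bundle`: list with `X` (cells x (p-1) predictor
#'   matrix), `y` (target values), `bin` (per-cell time bin), `predictors`,
#'   `target`, `T`.
#' @export
assemble_design <- function(expr, times, target) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(times, "cell_times"))
  if (expr_state(expr) != "standardized")
    stop("assemble_design requires standardized expression")
  genes <- colnames(expr)
  if (!target %in% genes) stop("target gene '", target, "' not in expression matrix")
  cells <- rownames(expr)
  assigned <- cells[cells %in% names(times$t_hat)]
  if (length(assigned) < length(cells))
    warning(length(cells) - length(assigned),
            " cell(s) without a time assignment excluded from the design")
  if (length(assigned) == 0) stop("no cells with time assignments")
  bin <- unname(times$t_hat[assigned])
  counts <- tabulate(bin, nbins = times$T)
  if (any(counts == 0))
    stop("empty time bin ", which(counts == 0)[1], " (of T=", times$T, ")")
  v <- expr_values(expr)[assigned, , drop = FALSE]
  predictors <- setdiff(genes, target)
  structure(list(X = v[, predictors, drop = FALSE],
                 y = unname(v[, target]),
                 bin = bin,
                 predictors = predictors,
                 target = target,
                 T = times$T),
            class = "design_bundle")
}

# expand the cells x p1 predictor block to the sparse cells x (p1*T) design
# in which each cell's row occupies its own time bin's column block
expand_design <- function(design) {
  p1 <- length(design$predictors)
  n <- nrow(design$X)
  i <- rep(seq_len(n), each = p1)
  j <- as.vector(vapply(seq_len(n),
                        function(c) (design$bin[c] - 1L) * p1 + seq_len(p1),
                        integer(p1)))
  Matrix::sparseMatrix(i = i, j = j, x = as.vector(t(design$X)),
                       dims = c(n, p1 * design$T))
}

#' Fit the time-varying model for one target gene
#'
#' Minimizes, over the T x (p-1) coefficient matrix b,
#' `sum_cells (y_c - b[t(c), ] . x_c)^2 + lambda * || D vec(t(b)) ||_1`
#' by ADMM with splitting `z = D vec(t(b))`: the quadratic update solves a
#' sparse linear system through a Cholesky factorization of
#' `2 X'X + rho D'D` computed once, and the z update is soft-thresholding.
#' The residual sum runs over every cell, each using the coefficient row
#' of its own time bin (this reduces to one term per bin when each bin
#' holds one cell); bins are not reweighted by size. The intercept is
#' identically 0 on standardized data and is not penalized. The solver is
#' deterministic: zero initialization, no randomness.
#'
#' @param design a [assemble_design()] bundle.
#' @param D a [build_penalty_matrix()] result matching the design
#'   (`D$p1 == length(design$predictors)`, `D$T_bins == design$T`).
#' @param cfg a [penalty_config()] (supplies lambda).
#' @param scfg a [solver_config()].
#' @return A `tv_fit`: list with `b` (T x (p-1) matrix, predictor gene
#'   columns), `intercept` (0), `lambda`, `target`, `predictors`, and
#'   `report` (iterations, converged, objective, primal/dual residuals).
#' @export
fit_target <- function(design, D, cfg = penalty_config(), scfg = solver_config()) {
  stopifnot(inherits(design, "design_bundle"), inherits(D, "penalty_matrix"),
            inherits(cfg, "penalty_config"), inherits(scfg, "solver_config"))
  p1 <- length(design$predictors)
  if (D$p1 != p1 || D$T_bins != design$T)
    stop("penalty matrix dimensions do not match the design (p-1=", p1,
         ", T=", design$T, ")")
  lambda <- cfg$lambda
  rho <- scfg$rho
  Dm <- D$D
  X <- expand_design(design)
  y <- design$y
  ncols <- ncol(Dm)
  m <- nrow(Dm)

  XtX <- Matrix::crossprod(X)
  Xty <- as.numeric(Matrix::crossprod(X, y))
  DtD <- Matrix::crossprod(Dm)
  factorize <- function(rho)
    Matrix::Cholesky(Matrix::forceSymmetric(2 * XtX + rho * DtD),
                     LDL = FALSE, perm = TRUE)
  ch <- factorize(rho)

  beta <- numeric(ncols)
  z <- numeric(m)
  u <- numeric(m)
  Dt <- Matrix::t(Dm)
  obj_first <- NA_real_
  it <- 0L
  converged <- FALSE
  pri <- dual <- NA_real_
  repeat {
    it <- it + 1L
    rhs <- 2 * Xty + rho * as.numeric(Dt %*% (z - u))
    beta <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    Dbeta <- as.numeric(Dm %*% beta)
    z_old <- z
    z <- soft_threshold(Dbeta + u, lambda / rho)
    u <- u + Dbeta - z
    pri <- sqrt(sum((Dbeta - z)^2))
    dual <- rho * sqrt(sum(as.numeric(Dt %*% (z - z_old))^2))
    if (it == 1L) {
      r <- y - as.numeric(X %*% beta)
      obj_first <- sum(r^2) + lambda * sum(abs(Dbeta))
    }
    eps_pri <- sqrt(m) * scfg$tol_abs +
      scfg$tol_rel * max(sqrt(sum(Dbeta^2)), sqrt(sum(z^2)))
    eps_dual <- sqrt(ncols) * scfg$tol_abs +
      scfg$tol_rel * rho * sqrt(sum(as.numeric(Dt %*% u)^2))
    if (pri <= eps_pri && dual <= eps_dual) { converged <- TRUE; break }
    if (it >= scfg$max_iter) break
    # residual balancing (checked every 10 iterations): keep the primal
    # and dual residuals within a factor of 10 of each other
    if (scfg$adapt_rho && it %% 10L == 0L) {
      if (pri > 10 * dual) {
        rho <- rho * 2; u <- u / 2; ch <- factorize(rho)
      } else if (dual > 10 * pri) {
        rho <- rho / 2; u <- u * 2; ch <- factorize(rho)
      }
    }
  }
  if (!converged)
    warning("ADMM did not converge for target '", design$target,
            "' within ", scfg$max_iter, " iterations")
  resid <- y - as.numeric(X %*% beta)
  objective <- sum(resid^2) + lambda * sum(abs(as.numeric(Dm %*% beta)))
  b <- t(matrix(beta, nrow = p1))
  dimnames(b) <- list(paste0("t", seq_len(design$T)), design$predictors)
  structure(list(b = b, intercept = 0, lambda = lambda,
                 target = design$target, predictors = design$predictors,
                 thresholded = FALSE, tau = NA_real_,
                 report = list(iterations = it, converged = converged,
                               objective = objective,
                               objective_first_iter = obj_first,
                               primal_residual = pri, dual_residual = dual)),
            class = "tv_fit")
}

soft_threshold <- function(x, kappa) sign(x) * pmax(abs(x) - kappa, 0)

#' @export
print.tv_fit <- function(x, ...) {
  nz <- sum(x$b != 0)
  cat(sprintf("<tv_fit> target=%s, T=%d, p-1=%d, %s, %d non-zero coefficients%s\n",
              x$target, nrow(x$b), ncol(x$b),
              if (x$report$converged) sprintf("converged in %d iterations", x$report$iterations)
              else sprintf("NOT converged (%d iterations)", x$report$iterations),
              nz, if (x$thresholded) sprintf(" (tau=%g)", x$tau) else ""))
  invisible(x)
}

#' Remove trivially small coefficients
#'
#' Sets entries with `|b| < tau` to exactly zero. The network edge set is
#' read off the thresholded coefficients.
#'
#' @param fit a `tv_fit`.
#' @param tau non-negative threshold on the standardized-coefficient scale.
#' @return The fit with small entries zeroed and `thresholded = TRUE`.
#' @export
threshold_coefficients <- function(fit, tau = solver_config()$tau) {
  stopifnot(inherits(fit, "tv_fit"))
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  fit$b[abs(fit$b) < tau] <- 0
  fit$thresholded <- TRUE
  fit$tau <- tau
  fit
}

#' Fit a panel of target genes
#'
#' Fits each target's local model independently (local decomposability of
#' the global network), so results do not depend on execution order or on
#' the degree of parallelism. Targets absent from the expression matrix
#' are skipped with a warning.
#'
#' @param targets a [gene_set()] or character vector of target gene IDs.
#' @param expr standardized `expression_matrix`.
#' @param times a [cell_times()] assignment.
#' @param priors a [binding_priors()] table (may be empty for flat weights).
#' @param cfg a [penalty_config()].
#' @param scfg a [solver_config()].
#' @param threads number of worker processes (forked; 1 = serial).
#' @return Named list of `tv_fit` objects, one per fitted target.
#' @export
fit_panel <- function(targets, expr, times, priors = binding_priors(),
                      cfg = penalty_config(), scfg = solver_config(),
                      threads = 1L) {
  if (inherits(targets, "gene_set")) targets <- targets$members
  targets <- as.character(targets)
  present <- targets %in% colnames(expr)
  if (any(!present))
    warning("skipping ", sum(!present), " target(s) not in the expression matrix: ",
            paste(utils::head(targets[!present], 5), collapse = ", "))
  targets <- targets[present]
  if (length(targets) == 0) return(stats::setNames(list(), character()))
  fit_one <- function(tg) {
    design <- assemble_design(expr, times, tg)
    w <- build_weight_vector(tg, design$predictors, priors, cfg)
    D <- build_penalty_matrix(w, design$T)
    fit_target(design, D, cfg, scfg)
  }
  fits <- if (threads > 1L) {
    parallel::mclapply(targets, fit_one, mc.cores = threads)
  } else {
    lapply(targets, fit_one)
  }
  stats::setNames(fits, targets)
}

#' Upper bound on the penalty level that zeroes all coefficients
#'
#' Returns `max over (t, j) of 2 |X' y|_(t,j) / w_j`, a lambda at or above
#' which the all-zero coefficient matrix is optimal (the within-time rows
#' of D alone can then absorb the gradient of the loss at 0).
#'
#' @param design a [assemble_design()] bundle.
#' @param w per-predictor weight vector.
#' @return A single lambda value.
#' @export
lambda_zero_bound <- function(design, w = rep(1, length(design$predictors))) {
  X <- expand_design(design)
  Xty <- abs(as.numeric(Matrix::crossprod(X, design$y)))
  max(2 * Xty / rep(w, times = design$T))
}
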