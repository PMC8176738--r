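hi_prec <- solver_config(tol_abs = 1e-10, tol_rel = 1e-10, max_iter = 100000)

test_that("assemble_design groups cells by bin and excludes the target", {
  set.seed(10)
  v <- matrix(rnorm(18), 6, 3)
  expr <- make_std_expr(v, genes = c("TG", "GA", "GB"))
  times <- cell_times(setNames(rep(1:2, each = 3), rownames(expr)))
  d <- assemble_design(expr, times, "TG")
  expect_identical(d$predictors, c("GA", "GB"))
  expect_identical(dim(d$X), c(6L, 2L))
  expect_identical(d$T, 2L)
  expect_false("TG" %in% d$predictors)

  # unassigned cell excluded with warning; empty bin errors
  times_part <- cell_times(setNames(c(1L, 1L, 1L, 2L, 2L), rownames(expr)[1:5]))
  expect_warning(d2 <- assemble_design(expr, times_part, "TG"), "excluded")
  expect_identical(nrow(d2$X), 5L)
  # all of bin 2's cells missing from the expression matrix -> empty bin
  expr3 <- make_std_expr(v[1:3, ], genes = c("TG", "GA", "GB"))
  expect_error(assemble_design(expr3, times, "TG"), "empty time bin 2")
})

test_that("unpenalized single-bin fit matches ordinary least squares", {
  set.seed(20)
  n <- 25; p1 <- 4
  X <- matrix(rnorm(n * p1), n, p1)
  y <- rnorm(n)
  design <- make_design(X, y, rep(1L, n))
  D <- build_penalty_matrix(rep(1, p1), 1)
  fit <- fit_target(design, D, penalty_config(lambda = 0), hi_prec)
  ols <- qr.solve(X, y)
  expect_equal(unname(fit$b[1, ]), unname(ols), tolerance = 1e-6)
})

test_that("lambda at the zero bound annihilates all coefficients", {
  for (seed in c(5, 6)) {
    inst <- random_instance(seed)
    D <- build_penalty_matrix(inst$w, inst$design$T)
    lmax <- lambda_zero_bound(inst$design, inst$w)
    fit <- fit_target(inst$design, D, penalty_config(lambda = lmax * 1.001),
                      hi_prec)
    expect_true(all(abs(fit$b) < 1e-8))
  }
})

test_that("ADMM objective agrees with the independent dual-QP oracle", {
  inst <- random_instance(11)
  D <- build_penalty_matrix(inst$w, inst$design$T)
  fit <- fit_target(inst$design, D, penalty_config(lambda = 3), hi_prec)
  orc <- genlasso_oracle(expand_design_dense(inst$design), inst$design$y,
                         D$D, 3)
  expect_lt(abs(fit$report$objective - orc$obj) / orc$obj, 1e-6)
  # reported objective is the objective of the reported coefficients
  vecb <- as.numeric(t(fit$b))
  recomputed <- sum((inst$design$y -
                       expand_design_dense(inst$design) %*% vecb)^2) +
    3 * sum(abs(as.numeric(D$D %*% vecb)))
  expect_equal(fit$report$objective, recomputed, tolerance = 1e-8)
  expect_lte(fit$report$objective, fit$report$objective_first_iter + 1e-10)
})

test_that("single-bin mixed-weight fit matches the glmnet coordinate-descent oracle", {
  skip_if_not_installed("glmnet")
  set.seed(30)
  n <- 40; p1 <- 5
  X <- matrix(rnorm(n * p1), n, p1)
  y <- as.numeric(X %*% c(1, -0.5, 0, 0, 0.8)) + rnorm(n, sd = 0.3)
  w <- c(1, 0.25, 1, 0.625, 1)
  lambda <- 4
  design <- make_design(X, y, rep(1L, n))
  D <- build_penalty_matrix(w, 1)
  fit <- fit_target(design, D, penalty_config(lambda = lambda), hi_prec)
  # glmnet: (1/(2n))RSS + lam_g * sum(pf_j |b_j|), pf rescaled to sum to p1
  lam_g <- lambda * sum(w) / (2 * n * p1)
  g <- glmnet::glmnet(X, y, lambda = lam_g, penalty.factor = w,
                      standardize = FALSE, intercept = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(fit$b[1, ]), as.numeric(g$beta), tolerance = 1e-4)
})

test_that("fused fits never increase total variation relative to per-bin lassos", {
  for (seed in 1:10) {
    inst <- random_instance(seed + 100, n = 36, p1 = 4, T_bins = 3)
    lambda <- 2
    D <- build_penalty_matrix(inst$w, inst$design$T)
    fused <- fit_target(inst$design, D, penalty_config(lambda = lambda), hi_prec)
    # independent per-bin weighted lassos at the same lambda
    b_ind <- matrix(NA_real_, inst$design$T, 4)
    for (t in seq_len(inst$design$T)) {
      sel <- inst$design$bin == t
      d_t <- make_design(inst$design$X[sel, , drop = FALSE],
                         inst$design$y[sel], rep(1L, sum(sel)))
      D_t <- build_penalty_matrix(inst$w, 1)
      b_ind[t, ] <- fit_target(d_t, D_t, penalty_config(lambda = lambda),
                               hi_prec)$b[1, ]
    }
    tv <- function(b) sum(abs(b[-1, , drop = FALSE] - b[-nrow(b), , drop = FALSE]))
    expect_lte(tv(fused$b), tv(b_ind) + 1e-8)
  }
})

test_that("binding evidence for a true regulator never shrinks its coefficient", {
  for (seed in 1:10) {
    set.seed(seed + 200)
    n <- 60; p1 <- 6; Tb <- 2
    X <- matrix(rnorm(n * p1), n, p1)
    bin <- rep(1:Tb, each = n / Tb)
    y <- as.numeric(X[, 1] * 0.8) + rnorm(n, sd = 0.5)
    design <- make_design(X, y, bin)
    cfg <- penalty_config(lambda = 15, eta = 4)
    flat <- rep(1, p1)
    with_prior <- flat; with_prior[1] <- binding_weight(1, cfg)
    f0 <- fit_target(design, build_penalty_matrix(flat, Tb), cfg, hi_prec)
    f1 <- fit_target(design, build_penalty_matrix(with_prior, Tb), cfg, hi_prec)
    expect_gte(max(abs(f1$b[, 1])), max(abs(f0$b[, 1])) - 1e-8)
  }
})

test_that("the fit is invariant to permuting cells within time bins", {
  inst <- random_instance(7, n = 30, p1 = 4, T_bins = 3)
  D <- build_penalty_matrix(inst$w, inst$design$T)
  cfg <- penalty_config(lambda = 2)
  f1 <- fit_target(inst$design, D, cfg, hi_prec)
  set.seed(1)
  perm <- sample(length(inst$design$y))
  design_p <- make_design(inst$design$X[perm, , drop = FALSE],
                          inst$design$y[perm], inst$design$bin[perm])
  f2 <- fit_target(design_p, D, cfg, hi_prec)
  expect_equal(f1$b, f2$b, tolerance = 1e-10)
})

test_that("thresholding zeroes exactly the sub-tau entries", {
  inst <- random_instance(3)
  D <- build_penalty_matrix(inst$w, inst$design$T)
  fit <- fit_target(inst$design, D, penalty_config(lambda = 2), hi_prec)
  fit$b[1, 1:3] <- c(0.5, 0.004, -0.3)
  th <- threshold_coefficients(fit, 0.01)
  expect_equal(unname(th$b[1, 1:3]), c(0.5, 0, -0.3))
  expect_true(all(abs(th$b[th$b != 0]) >= 0.01))
  same <- threshold_coefficients(fit, 0)
  expect_equal(same$b, fit$b)
  allz <- threshold_coefficients(fit, max(abs(fit$b)) + 1)
  expect_true(all(allz$b == 0))
  expect_error(threshold_coefficients(fit, -1), ">= 0")
})

test_that("panel fits are independent and parallelism-invariant", {
  set.seed(40)
  v <- matrix(rnorm(40 * 6), 40, 6)
  expr <- make_std_expr(v, genes = c("T1", "T2", paste0("G", 1:4)))
  times <- cell_times(setNames(rep(1:2, each = 20), rownames(expr)))
  cfg <- penalty_config(lambda = 5)
  panel <- fit_panel(c("T1", "T2"), expr, times, cfg = cfg)
  single <- fit_target(assemble_design(expr, times, "T1"),
                       build_penalty_matrix(
                         build_weight_vector("T1", setdiff(colnames(expr), "T1"),
                                             binding_priors(), cfg),
                         times$T), cfg, solver_config())
  expect_equal(panel[["T1"]]$b, single$b)
  par2 <- fit_panel(c("T1", "T2"), expr, times, cfg = cfg, threads = 2L)
  expect_identical(lapply(panel, `[[`, "b"), lapply(par2, `[[`, "b"))
  expect_warning(skip <- fit_panel(c("T1", "NOPE"), expr, times, cfg = cfg),
                 "skipping")
  expect_identical(names(skip), "T1")
  expect_identical(fit_panel(character(), expr, times), setNames(list(), character()))
})
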