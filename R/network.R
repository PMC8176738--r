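#' Time-varying network container
#'
#' A set of directed, time-stamped, signed edges
#' (regulator -> target at time t with coefficient weight).
#'
#' @param regulator,target character vectors of gene IDs.
#' @param time integer time bins.
#' @param coefficient signed non-zero weights.
#' @return An object of class `tv_network` (a data.frame).
#' @export
tv_network <- function(regulator = character(), target = character(),
                       time = integer(), coefficient = numeric()) {
  stopifnot(length(regulator) == length(target),
            length(target) == length(time),
            length(time) == length(coefficient))
  if (any(regulator == target)) stop("self-edges are not allowed")
  if (any(coefficient == 0)) stop("edges must carry non-zero coefficients")
  if (length(time) && any(time < 1)) stop("time bins must be >= 1")
  structure(data.frame(regulator = as.character(regulator),
                       target = as.character(target),
                       time = as.integer(time),
                       coefficient = as.numeric(coefficient),
                       stringsAsFactors = FALSE),
            class = c("tv_network", "data.frame"))
}

#' Extract network edges from a thresholded fit
#'
#' Each non-zero coefficient `b[t, j]` of the local model around a target
#' gene becomes one edge regulator j -> target at time t, keeping the
#' signed coefficient as the edge weight.
#'
#' @param fit a `tv_fit` that has been through [threshold_coefficients()].
#' @return A `tv_network`.
#' @export
edges_from_fit <- function(fit) {
  stopifnot(inherits(fit, "tv_fit"))
  if (!isTRUE(fit$thresholded))
    stop("fit must be thresholded first (see threshold_coefficients)")
  nz <- which(fit$b != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(tv_network())
  tv_network(regulator = fit$predictors[nz[, "col"]],
             target = rep(fit$target, nrow(nz)),
             time = nz[, "row"],
             coefficient = fit$b[nz])
}

#' Combine per-target networks
#' @param nets list of `tv_network` objects.
#' @return A single `tv_network`.
#' @export
combine_networks <- function(nets) {
  nets <- nets[vapply(nets, nrow, integer(1)) > 0]
  if (length(nets) == 0) return(tv_network())
  df <- do.call(rbind, lapply(nets, as.data.frame))
  tv_network(df$regulator, df$target, df$time, df$coefficient)
}

#' Regulator consistency over a gene set
#'
#' The lasso family can select different, equally well-fitting predictor
#' sets on perturbed inputs; a regulator that is picked across many
#' per-target fits over a coherent gene set is a robust call. This counts,
#' for each regulator, how many gene-set members it regulates at time `t`.
#'
#' @param nets a `tv_network` or a (possibly named) list of per-target
#'   `tv_network` objects.
#' @param set a [gene_set()] of target genes.
#' @param t time bin at which to count; defaults to the final bin present
#'   in the edges, mirroring the convention of reading regulator
#'   consistency off the end of the trajectory.
#' @return data.frame `regulator`, `count`, `targets` (comma-joined
#'   member IDs), sorted by descending count then alphabetically;
#'   zero-count regulators are omitted.
#' @export
aggregate_consistency <- function(nets, set, t = NULL) {
  stopifnot(inherits(set, "gene_set"))
  net <- if (inherits(nets, "tv_network")) nets else combine_networks(nets)
  if (nrow(net) == 0)
    return(data.frame(regulator = character(), count = integer(),
                      targets = character(), stringsAsFactors = FALSE))
  if (is.null(t)) t <- max(net$time)
  sel <- net[net$time == t & net$target %in% set$members, , drop = FALSE]
  sel <- unique(sel[, c("regulator", "target")])
  if (nrow(sel) == 0)
    return(data.frame(regulator = character(), count = integer(),
                      targets = character(), stringsAsFactors = FALSE))
  split_targets <- split(sel$target, sel$regulator)
  out <- data.frame(regulator = names(split_targets),
                    count = lengths(split_targets),
                    targets = vapply(split_targets, function(x)
                      paste(sort(x), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-regulation partition for a pair of regulators
#'
#' Splits the gene-set targets regulated at time `t` into those connected
#' to both regulators, only the first, or only the second.
#'
#' @param nets a `tv_network` or list of per-target networks.
#' @param tf_a,tf_b two distinct regulator IDs.
#' @param set a [gene_set()] restricting the targets considered.
#' @param t time bin (default: final bin present).
#' @return List with sorted character vectors `both`, `only_a`, `only_b`
#'   (pairwise disjoint), plus `tf_a`, `tf_b`, `time`.
#' @export
coregulation_partition <- function(nets, tf_a, tf_b, set, t = NULL) {
  stopifnot(inherits(set, "gene_set"))
  if (identical(tf_a, tf_b)) stop("tf_a and tf_b must differ")
  net <- if (inherits(nets, "tv_network")) nets else combine_networks(nets)
  if (is.null(t)) t <- if (nrow(net)) max(net$time) else 1L
  sel <- net[net$time == t & net$target %in% set$members, , drop = FALSE]
  ta <- unique(sel$target[sel$regulator == tf_a])
  tb <- unique(sel$target[sel$regulator == tf_b])
  list(tf_a = tf_a, tf_b = tf_b, time = t,
       both = sort(intersect(ta, tb)),
       only_a = sort(setdiff(ta, tb)),
       only_b = sort(setdiff(tb, ta)))
}

#' Correlation-threshold co-expression baseline
#'
#' The standard static alternative: connect the target gene to every gene
#' whose expression correlation (Pearson or Spearman) passes
#' `|rho| >= rho_threshold` over the supplied cells (typically the cells
#' of one time bin). The resulting edge set is a co-expression network
#' and carries no time-variation beyond the choice of cells.
#'
#' @param expr an `expression_matrix` already restricted to the cells of
#'   interest (at least 3 cells).
#' @param target target gene ID.
#' @param rho_threshold threshold in (0, 1].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `gene`, `rho` for the genes passing the threshold,
#'   sorted by decreasing `|rho|`.
#' @export
correlation_baseline <- function(expr, target, rho_threshold = 0.5,
                                 method = c("pearson", "spearman")) {
  stopifnot(inherits(expr, "expression_matrix"))
  method <- match.arg(method)
  if (!(rho_threshold > 0 && rho_threshold <= 1))
    stop("rho_threshold must be in (0, 1]")
  if (nrow(expr) < 3) stop("need at least 3 cells")
  if (!target %in% colnames(expr)) stop("target gene '", target, "' not found")
  v <- expr_values(expr)
  ty <- v[, target]
  if (stats::sd(ty) == 0) stop("target gene has zero variance in these cells")
  others <- setdiff(colnames(v), target)
  rho <- suppressWarnings(
    as.numeric(stats::cor(v[, others, drop = FALSE], ty, method = method)))
  names(rho) <- others
  keep <- !is.na(rho) & abs(rho) >= rho_threshold
  out <- data.frame(gene = others[keep], rho = unname(rho[keep]),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$rho), out$gene), , drop = FALSE]
}

#' Edge-recovery AUROC against a known truth
#'
#' Ranks predictor genes by a score (typically `max_t |b_hat[t, j]|`) and
#' computes the area under the ROC curve for recovering the true
#' regulators, via the rank-sum (Mann-Whitney) identity.
#'
#' @param score numeric score per predictor.
#' @param is_regulator logical truth per predictor.
#' @return AUROC in \[0, 1\].
#' @export
edge_recovery_auroc <- function(score, is_regulator) {
  stopifnot(length(score) == length(is_regulator))
  is_regulator <- as.logical(is_regulator)
  n1 <- sum(is_regulator); n0 <- sum(!is_regulator)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative labels")
  r <- rank(score)
  (sum(r[is_regulator]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
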