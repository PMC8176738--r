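#' Expression matrix container
#'
#' A cells x genes numeric matrix with cell IDs as row names, gene IDs as
#' column names, and a `state` flag recording which transforms have been
#' applied. The canonical pipeline is raw counts -> `log1p_transform()` ->
#' `standardize()`; model fitting requires the standardized state.
#'
#' @param values numeric matrix, cells in rows, genes in columns; must carry
#'   row and column names (cell and gene IDs).
#' @param state one of `"raw"`, `"log1p"`, `"standardized"`.
#' @return An object of class `expression_matrix` (a named numeric matrix
#'   with a `state` attribute).
#' @export
expression_matrix <- function(values, state = c("raw", "log1p", "standardized")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  cell_ids <- rownames(values)
  gene_ids <- colnames(values)
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("`values` must have cell IDs as rownames and gene IDs as colnames")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell IDs: ", paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (state == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw expression values must be non-negative")
  if (state == "standardized") {
    mu <- colMeans(values)
    sdv <- apply(values, 2, stats::sd)
    if (any(abs(mu) > 1e-8) || any(abs(sdv - 1) > 1e-8))
      stop("standardized state requires per-gene mean 0 and sd 1 (tolerance 1e-8)")
  }
  structure(values, state = state, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes, state=%s\n",
              nrow(x), ncol(x), expr_state(x)))
  invisible(x)
}

#' State of an expression matrix
#' @param expr an `expression_matrix`.
#' @return `"raw"`, `"log1p"` or `"standardized"`.
#' @export
expr_state <- function(expr) attr(expr, "state")

# strip class/attrs down to a plain matrix
expr_values <- function(expr) {
  v <- unclass(expr)
  attr(v, "state") <- NULL
  v
}

#' Read an expression matrix
#'
#' Dense TSV (header row of gene IDs, first column of cell IDs) or
#' MatrixMarket sparse (`.mtx`) with sidecar `<path>.rows` / `<path>.cols`
#' files holding cell and gene IDs, one per line.
#'
#' @param path path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @return An `expression_matrix` with `state = "raw"`.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "mtx") {
    rows_path <- paste0(path, ".rows")
    cols_path <- paste0(path, ".cols")
    if (!file.exists(rows_path) || !file.exists(cols_path))
      stop("mtx input requires sidecar files: ", rows_path, " and ", cols_path)
    m <- as.matrix(Matrix::readMM(path))
    cell_ids <- readLines(rows_path)
    gene_ids <- readLines(cols_path)
    if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids))
      stop("mtx dimensions do not match sidecar ID files")
    dimnames(m) <- list(cell_ids, gene_ids)
  } else {
    dt <- tryCatch(
      data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE),
      error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
    if (ncol(dt) < 2) stop("malformed expression TSV (need cell ID column plus genes): ", path)
    hdr <- names(dt)
    # fread mangles duplicated header names; re-read the raw header to detect them
    raw_hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    gene_ids <- raw_hdr[-1]
    if (anyDuplicated(gene_ids))
      stop("duplicate gene IDs in header: ",
           paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    cell_ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    dimnames(m) <- list(cell_ids, gene_ids)
  }
  expression_matrix(m, state = "raw")
}

#' Write an expression matrix as TSV
#' @param expr an `expression_matrix`.
#' @param path output path.
#' @param id_column name for the first (cell ID) column.
#' @export
write_expression <- function(expr, path, id_column = "cell_id") {
  df <- data.frame(rownames(expr), expr_values(expr), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  atomic_write(path, function(p)
    data.table::fwrite(df, p, sep = "\t", quote = FALSE))
  invisible(path)
}

#' Log-transform expression values
#'
#' Applies the natural-log transform `v -> log(v + 1)` elementwise, the
#' scale on which the time-varying linear model is defined.
#'
#' @param expr an `expression_matrix` with `state = "raw"`.
#' @return An `expression_matrix` with `state = "log1p"`.
#' @export
log1p_transform <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr_state(expr) != "raw")
    stop("log1p_transform requires state='raw' (got '", expr_state(expr), "')")
  v <- expr_values(expr)
  if (any(v < 0)) stop("negative values are outside the domain of log1p")
  expression_matrix(log1p(v), state = "log1p")
}

#' Standardize expression gene-wise
#'
#' Z-scores each gene over all cells (globally, not per time bin, so that
#' one coefficient scale applies across the whole trajectory and the fused
#' penalty compares like with like). Genes with zero variance are dropped
#' and reported. The variance denominator is n - 1 (the [stats::sd()]
#' convention), fixed and documented here.
#'
#' @param expr an `expression_matrix` with `state = "log1p"`.
#' @return A list with elements `expr` (standardized `expression_matrix`),
#'   `center` and `scale` (named per-gene means and sds of the retained
#'   genes) and `dropped` (IDs of zero-variance genes removed).
#' @export
standardize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr_state(expr) != "log1p")
    stop("standardize requires state='log1p' (got '", expr_state(expr), "')")
  v <- expr_values(expr)
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  dropped <- colnames(v)[sdv == 0 | !is.finite(sdv)]
  keep <- setdiff(colnames(v), dropped)
  if (length(keep) == 0) stop("all genes have zero variance")
  if (length(dropped))
    message("standardize: dropped ", length(dropped), " zero-variance gene(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  v <- v[, keep, drop = FALSE]
  z <- sweep(sweep(v, 2, mu[keep]), 2, sdv[keep], `/`)
  list(expr = expression_matrix(z, state = "standardized"),
       center = mu[keep], scale = sdv[keep], dropped = dropped)
}

#' Binding-prior table
#'
#' Sparse map from (regulator, target) gene pairs to DNA-binding
#' probabilities in \[0, 1\] (e.g. posterior probabilities from a
#' footprinting model of DNase-seq data). Absent pairs carry no evidence
#' and are looked up as `NA`, which downstream penalty weighting treats as
#' weight 1.
#'
#' @param regulator,target character vectors of gene IDs.
#' @param probability numeric vector in \[0, 1\].
#' @return An object of class `binding_priors`.
#' @export
binding_priors <- function(regulator = character(), target = character(),
                           probability = numeric()) {
  stopifnot(length(regulator) == length(target),
            length(target) == length(probability))
  bad <- which(!is.finite(probability) | probability < 0 | probability > 1)
  if (length(bad))
    stop("binding probability outside [0,1] at entry ", bad[1],
         " (", regulator[bad[1]], " -> ", target[bad[1]], ": ", probability[bad[1]], ")")
  key <- paste(regulator, target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (regulator, target) pairs in binding priors")
  lookup <- probability
  names(lookup) <- key
  structure(list(regulator = as.character(regulator),
                 target = as.character(target),
                 probability = probability,
                 lookup = lookup),
            class = "binding_priors")
}

#' @export
print.binding_priors <- function(x, ...) {
  cat(sprintf("<binding_priors> %d entries, %d regulators, %d targets\n",
              length(x$probability), length(unique(x$regulator)),
              length(unique(x$target))))
  invisible(x)
}

#' Look up binding probabilities
#' @param priors a `binding_priors` table.
#' @param regulator,target gene IDs (recycled to common length).
#' @return Numeric vector of probabilities; `NA` where no evidence exists.
#' @export
prior_lookup <- function(priors, regulator, target) {
  stopifnot(inherits(priors, "binding_priors"))
  unname(priors$lookup[paste(regulator, target, sep = "\r")])
}

#' Read a binding-prior table from a 3-column TSV
#'
#' Columns: regulator ID, target ID, probability. A header row is detected
#' (third field non-numeric) and skipped.
#'
#' @param path TSV path.
#' @return A `binding_priors` table.
#' @export
read_binding_priors <- function(path) {
  if (!file.exists(path)) stop("binding-prior file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = "auto", data.table = FALSE,
                          colClasses = list(character = 1:2))
  if (nrow(dt) == 0) return(binding_priors())
  if (ncol(dt) != 3)
    stop("binding-prior file must have 3 columns (regulator, target, probability): ", path)
  p <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad))
    stop("invalid binding probability at data row ", bad[1], " of ", path,
         " (value '", dt[[3]][bad[1]], "')")
  binding_priors(dt[[1]], dt[[2]], p)
}

#' Write a binding-prior table
#' @param priors a `binding_priors` table.
#' @param path output TSV path.
#' @export
write_binding_priors <- function(priors, path) {
  df <- data.frame(regulator = priors$regulator, target = priors$target,
                   probability = priors$probability, stringsAsFactors = FALSE)
  atomic_write(path, function(p)
    data.table::fwrite(df, p, sep = "\t", quote = FALSE))
  invisible(path)
}

#' Gene-set container
#' @param members character vector of gene IDs (order preserved; duplicates
#'   rejected).
#' @param name optional label.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- as.character(members)
  if (anyDuplicated(members))
    stop("duplicate gene IDs in gene set '", name, "'")
  structure(list(name = name, members = members), class = "gene_set")
}

#' Read a gene set (one gene ID per line)
#' @param path file path; blank lines are ignored.
#' @param name label for the set; defaults to the file base name.
#' @return A `gene_set`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  gene_set(ids, name = if (is.null(name)) tools::file_path_sans_ext(basename(path)) else name)
}

#' Read/write cell time-bin assignments
#'
#' TSV with columns `cell_id` and `t_hat` (integer bins 1..T).
#' @param path file path.
#' @return For `read_times`, a `cell_times` object.
#' @export
read_times <- function(path) {
  if (!file.exists(path)) stop("time-assignment file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("cell_id", "t_hat") %in% names(dt)))
    stop("time-assignment TSV needs columns cell_id and t_hat: ", path)
  t_hat <- as.integer(dt$t_hat)
  names(t_hat) <- as.character(dt$cell_id)
  cell_times(t_hat)
}

#' @rdname read_times
#' @param times a `cell_times` object.
#' @export
write_times <- function(times, path) {
  stopifnot(inherits(times, "cell_times"))
  df <- data.frame(cell_id = names(times$t_hat), t_hat = unname(times$t_hat),
                   stringsAsFactors = FALSE)
  atomic_write(path, function(p)
    data.table::fwrite(df, p, sep = "\t", quote = FALSE))
  invisible(path)
}

#' Cell time-bin assignment container
#'
#' @param t_hat named integer vector (names = cell IDs) of time bins; bins
#'   must cover 1..T with T = max(t_hat).
#' @param trajectory optional ordered cluster path root -> leaf.
#' @param excluded_cells optional IDs of cells off the chosen trajectory.
#' @return An object of class `cell_times` with fields `t_hat`, `T`,
#'   `trajectory`, `excluded_cells`.
#' @export
cell_times <- function(t_hat, trajectory = NULL, excluded_cells = character()) {
  t_hat <- stats::setNames(as.integer(t_hat), names(t_hat))
  if (is.null(names(t_hat)) || anyDuplicated(names(t_hat)))
    stop("t_hat must be named by unique cell IDs")
  if (length(t_hat) == 0 || any(is.na(t_hat)) || any(t_hat < 1))
    stop("time bins must be positive integers")
  T_bins <- max(t_hat)
  if (!all(seq_len(T_bins) %in% t_hat))
    stop("time bins must cover 1..T without gaps")
  structure(list(t_hat = t_hat, T = T_bins, trajectory = trajectory,
                 excluded_cells = as.character(excluded_cells)),
            class = "cell_times")
}

#' @export
print.cell_times <- function(x, ...) {
  cat(sprintf("<cell_times> %d cells over T=%d bins (%d excluded)\n",
              length(x$t_hat), x$T, length(x$excluded_cells)))
  invisible(x)
}

#' Write a time-varying network as TSV
#'
#' Columns `regulator`, `target`, `time`, `coefficient`; rows ordered by
#' time, then regulator ID, then target ID, so output is deterministic.
#'
#' @param net a `tv_network` (see [edges_from_fit()]).
#' @param path output path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "tv_network"))
  df <- as.data.frame(net)
  df <- df[order(df$time, df$regulator, df$target), , drop = FALSE]
  atomic_write(path, function(p)
    data.table::fwrite(df, p, sep = "\t", quote = FALSE))
  invisible(path)
}

#' Read a time-varying network TSV
#' @param path file written by [write_network()].
#' @return A `tv_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("regulator", "target")))
  needed <- c("regulator", "target", "time", "coefficient")
  if (!all(needed %in% names(dt)))
    stop("network TSV needs columns ", paste(needed, collapse = ", "), ": ", path)
  tv_network(dt$regulator, dt$target, as.integer(dt$time), dt$coefficient)
}

# write via a temp file in the destination directory, then rename (atomic on
# the same filesystem) so partial files are never observed
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}
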