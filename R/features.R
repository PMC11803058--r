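#' Compute 2D molecular descriptors
#'
#' The full RDKit 2D descriptor block (constitutional, topological, VSA,
#' logP-type; > 200 columns) keyed on canonical SMILES, so enumerated
#' (SE-augmented) duplicates of one molecule get bit-identical rows. Columns
#' containing any non-finite value are masked with reason `"nonfinite"`;
#' constant columns with reason `"zero-variance"`. Molecules the descriptor
#' engine fails on are flagged in `row_ok` and excluded from training with a
#' warning.
#'
#' @param table an [rt_dataset] (or character vector of SMILES).
#' @return a `feature_matrix`: list with `X` (numeric matrix, one row per
#'   record), `mask` (data.frame `name`, `retained`, `reason`), `row_ok`
#'   (logical).
#' @export
compute_descriptors <- function(table) {
  smiles <- if (inherits(table, "rt_dataset")) table$smiles_canonical else canonicalize(table)
  X <- chem_descriptors(smiles)
  row_ok <- rowSums(is.na(X)) < ncol(X)
  if (any(!row_ok)) {
    warning(sum(!row_ok), " molecule(s) failed descriptor computation and are flagged")
  }
  Xok <- X[row_ok, , drop = FALSE]
  nonfinite <- apply(Xok, 2, anyNA)
  constant <- !nonfinite & apply(Xok, 2, function(v) {
    length(v) < 2 || max(v) - min(v) == 0
  })
  mask <- data.frame(
    name = colnames(X),
    retained = !(nonfinite | constant),
    reason = ifelse(nonfinite, "nonfinite", ifelse(constant, "zero-variance", "")),
    stringsAsFactors = FALSE
  )
  structure(list(X = X, mask = mask, row_ok = row_ok), class = "feature_matrix")
}

#' Select descriptor columns for regression
#'
#' A deterministic three-stage cascade: (1) drop zero-variance columns;
#' (2) among each pair with absolute Pearson correlation above
#' `cor_threshold`, drop the member with the lower absolute correlation to
#' the response (ties break to the lexicographically smaller name);
#' (3) rank the survivors by absolute correlation to the response and keep
#' the top `min(n_remaining, max(min_keep, floor(n_rows / rows_per_feature)))`.
#'
#' @param fm a `feature_matrix` from [compute_descriptors()].
#' @param y numeric response (retention times), aligned with rows of `fm$X`.
#' @param cor_threshold redundancy cutoff on |Pearson r| (default 0.95).
#' @param min_keep lower bound on the final count (default 10).
#' @param rows_per_feature rows required per retained feature (default 5).
#' @return a `selection_report`: list with counts `n_input`,
#'   `n_after_variance`, `n_after_correlation`, `n_final` and
#'   `selected_names` (ordered by decreasing |corr to y|).
#' @export
select_features <- function(fm, y, cor_threshold = 0.95, min_keep = 10L,
                            rows_per_feature = 5L) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$X[fm$row_ok, , drop = FALSE]
  y <- y[fm$row_ok]
  if (nrow(X) < 10) stopf("need at least 10 rows for feature selection (got %d)", nrow(X))
  n_input <- ncol(X)
  keep <- fm$mask$name[fm$mask$retained]
  # re-check variance on the rows actually used
  keep <- keep[apply(X[, keep, drop = FALSE], 2, function(v) max(v) - min(v) > 0)]
  n_after_variance <- length(keep)
  if (n_after_variance == 0) {
    stopf("all columns eliminated at the variance stage; relax the thresholds")
  }
  Xv <- X[, keep, drop = FALSE]
  ry <- abs(suppressWarnings(stats::cor(Xv, y)))[, 1]
  ry[is.na(ry)] <- 0
  # redundancy pruning: greedy over pairs above threshold, keeping the member
  # more correlated to y; deterministic via lexicographic ordering
  C <- abs(suppressWarnings(stats::cor(Xv)))
  C[is.na(C)] <- 0
  ord <- order(-ry, keep) # strongest (then alphabetical) considered first
  kept <- character(0)
  for (i in ord) {
    nm <- keep[i]
    if (all(C[nm, kept] <= cor_threshold)) kept <- c(kept, nm)
  }
  n_after_correlation <- length(kept)
  n_final <- min(n_after_correlation,
                 max(as.integer(min_keep), nrow(X) %/% as.integer(rows_per_feature)))
  n_final <- max(n_final, 1L)
  sel <- kept[order(-ry[kept], kept)][seq_len(n_final)]
  structure(
    list(
      n_input = n_input,
      n_after_variance = n_after_variance,
      n_after_correlation = n_after_correlation,
      n_final = n_final,
      selected_names = sel
    ),
    class = "selection_report"
  )
}

# Train-set standardization; sd 0 guarded to 1 so columns stay finite.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd, names = colnames(X))
}

apply_scaler <- function(scaler, X) {
  X <- X[, scaler$names, drop = FALSE]
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}
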