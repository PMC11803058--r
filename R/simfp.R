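#' Extended-connectivity (circular) fingerprints
#'
#' Computes ECFP-style binary fingerprints as sets of on-bit indices in
#' `[0, nbits)`. Deterministic for a given canonical SMILES, radius and
#' width; invariant to the SMILES rendering of the molecule.
#'
#' @param mol an [rt_dataset] or character vector of SMILES.
#' @param radius Morgan radius (default 2, i.e. ECFP4).
#' @param nbits folded width, a power of two (default 2048).
#' @return a list of `bit_fingerprint` objects (`on_bits` sorted 0-based
#'   integer vector, plus `nbits`, `radius`); a single object when `mol` has
#'   length 1.
#' @export
ecfp <- function(mol, radius = 2L, nbits = 2048L) {
  if (nbits <= 0 || bitwAnd(as.integer(nbits), as.integer(nbits) - 1L) != 0) {
    stopf("nbits must be a positive power of two (got %s)", nbits)
  }
  smiles <- if (inherits(mol, "rt_dataset")) mol$smiles_canonical else canonicalize(mol)
  bits <- chem_ecfp_bits(smiles, radius = radius, nbits = nbits)
  fps <- lapply(bits, function(b) {
    if (is.null(b)) stopf("fingerprint computation failed")
    structure(
      list(on_bits = sort(unique(as.integer(b))), nbits = as.integer(nbits),
           radius = as.integer(radius)),
      class = "bit_fingerprint"
    )
  })
  if (length(fps) == 1) fps[[1]] else fps
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|A intersect B| / |A union B|`, in `[0, 1]`. Two empty fingerprints have
#' similarity 0 by convention (no evidence of similarity). The printed form
#' of this coefficient sometimes carries a spurious factor of 2 in the
#' numerator; the standard Jaccard form implemented here is the only one
#' bounded by 1 and hence compatible with similarity thresholds in `[0, 1]`.
#'
#' @param a,b `bit_fingerprint` objects of equal `nbits`.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "bit_fingerprint"), inherits(b, "bit_fingerprint"))
  if (a$nbits != b$nbits) stopf("fingerprint widths differ: %d vs %d", a$nbits, b$nbits)
  na <- length(a$on_bits)
  nb <- length(b$on_bits)
  if (na == 0 && nb == 0) return(0)
  ni <- length(intersect(a$on_bits, b$on_bits))
  ni / (na + nb - ni)
}

# Sparse bit matrix (nbits x n) from a list of fingerprints.
fp_sparse <- function(fps) {
  nbits <- fps[[1]]$nbits
  lens <- vapply(fps, function(f) length(f$on_bits), integer(1))
  Matrix::sparseMatrix(
    i = unlist(lapply(fps, function(f) f$on_bits)) + 1L,
    j = rep(seq_along(fps), lens),
    x = 1,
    dims = c(nbits, length(fps))
  )
}

#' All-pairs similarity between two fingerprint collections
#'
#' Vectorized (sparse cross-product) computation of the full similarity
#' matrix; `tanimoto()` on each pair is the reference semantics.
#'
#' @param fps_a,fps_b lists of `bit_fingerprint`s with common `nbits`.
#' @param metric `"tanimoto"` (default) or `"cosine"`.
#' @return numeric matrix of dim `length(fps_a) x length(fps_b)`.
#' @export
similarity_matrix <- function(fps_a, fps_b = fps_a, metric = c("tanimoto", "cosine")) {
  metric <- match.arg(metric)
  if (!length(fps_a) || !length(fps_b)) return(matrix(0, length(fps_a), length(fps_b)))
  if (fps_a[[1]]$nbits != fps_b[[1]]$nbits) stopf("fingerprint widths differ")
  A <- fp_sparse(fps_a)
  B <- fp_sparse(fps_b)
  inter <- as.matrix(Matrix::crossprod(A, B))
  ca <- Matrix::colSums(A)
  cb <- Matrix::colSums(B)
  if (metric == "tanimoto") {
    denom <- outer(ca, cb, "+") - inter
  } else {
    denom <- sqrt(outer(ca, cb))
  }
  out <- ifelse(denom > 0, inter / denom, 0)
  dimnames(out) <- NULL
  out
}

#' Between-class structural similarity summary
#'
#' Mean pairwise fingerprint similarity between every pair of compound
#' classes (the data behind a class-similarity heatmap): entry (i, j) is the
#' mean similarity over the full cross-product of class i's and class j's
#' fingerprints, subsampled to `max_per_class` molecules per class under a
#' fixed seed. Classes are ordered by average-linkage hierarchical clustering
#' on `1 - similarity`; dispersion of the off-diagonal entries is summarized
#' by quartiles and by the fraction below 0.5.
#'
#' @param class_tables named list of [rt_dataset]s (>= 2, non-empty).
#' @param radius,nbits fingerprint parameters.
#' @param max_per_class per-class subsample cap (default 200).
#' @param seed subsample seed.
#' @param metric `"tanimoto"` or `"cosine"`.
#' @return a `class_similarity_summary`: list with `matrix` (symmetric, unit
#'   diagonal), `order` (clustering permutation), `quartiles` (named Q1/Q2/Q3),
#'   `frac_below_half`.
#' @export
class_similarity_summary <- function(class_tables, radius = 2L, nbits = 2048L,
                                     max_per_class = 200L, seed = 1L,
                                     metric = c("tanimoto", "cosine")) {
  metric <- match.arg(metric)
  if (length(class_tables) < 2) stopf("need at least 2 classes to summarize")
  if (any(vapply(class_tables, nrow, integer(1)) == 0)) stopf("empty class table")
  labels <- names(class_tables)
  fps <- lapply(seq_along(class_tables), function(i) {
    tab <- class_tables[[i]]
    smi <- unique(tab$smiles_canonical)
    if (length(smi) > max_per_class) {
      idx <- with_seed(derive_seed(seed, paste0("simsub:", labels[i])),
                       sample.int(length(smi), max_per_class))
      smi <- smi[idx]
    }
    f <- ecfp(smi, radius = radius, nbits = nbits)
    if (inherits(f, "bit_fingerprint")) list(f) else f
  })
  k <- length(fps)
  M <- matrix(1, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      M[i, j] <- M[j, i] <- mean(similarity_matrix(fps[[i]], fps[[j]], metric = metric))
    }
  }
  ord <- if (k > 2) {
    stats::hclust(stats::as.dist(1 - M), method = "average")$order
  } else {
    seq_len(k)
  }
  off <- M[upper.tri(M)]
  structure(
    list(
      matrix = M,
      order = ord,
      quartiles = stats::quantile(off, c(0.25, 0.5, 0.75), names = FALSE),
      frac_below_half = mean(off < 0.5)
    ),
    class = "class_similarity_summary"
  )
}

#' @export
print.class_similarity_summary <- function(x, ...) {
  k <- nrow(x$matrix)
  cat("Between-class similarity summary (", k, " classes)\n", sep = "")
  cat(sprintf(
    "  off-diagonal quartiles: Q1=%.3f Q2=%.3f Q3=%.3f; %.1f%% below 0.5\n",
    x$quartiles[1], x$quartiles[2], x$quartiles[3], 100 * x$frac_below_half
  ))
  cat("  clustering order:", paste(rownames(x$matrix)[x$order], collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.class_similarity_summary <- function(x, ...) {
  M <- x$matrix[x$order, x$order]
  graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), t(M)[, rev(seq_len(nrow(M)))],
    axes = FALSE, xlab = "", ylab = "", zlim = c(0, 1),
    main = "Between-class fingerprint similarity", ...
  )
  graphics::axis(1, seq_len(ncol(M)), colnames(M), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(M)), rev(rownames(M)), las = 2, cex.axis = 0.6)
  invisible(x)
}
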