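#' Enumerate alternative SMILES renderings of a molecule
#'
#' SMILES enumeration (SE) produces up to `k` randomized atom-order
#' renderings per molecule, each a valid SMILES that canonicalizes back to
#' the parent's canonical form, each distinct as a string from that canonical
#' form and from the other variants. Graphs admitting fewer distinct
#' renderings (e.g. methane) return fewer than `k`; the retry budget is
#' `10 * k` randomized draws per molecule.
#'
#' @param smiles character vector of SMILES.
#' @param k variants requested per molecule (>= 0).
#' @param seed integer seed; derivation is per-molecule, so results do not
#'   depend on batch composition.
#' @return a list of character vectors (one per input molecule); a single
#'   character vector when `smiles` has length 1.
#' @export
enumerate_smiles <- function(smiles, k = 5L, seed = 1L) {
  stopifnot(k >= 0)
  can <- canonicalize(smiles)
  out <- chem_enumerate(can, k = k, seed = seed)
  if (length(out) == 1) out[[1]] else out
}

#' Expand a training set by similarity-thresholded active learning
#'
#' Topology-guided active learning (Topo-AL): labeled pool compounds whose
#' maximum fingerprint similarity to the current training set reaches the
#' threshold `tau` are recruited into training with their own measured
#' retention times. Pool compounds whose canonical SMILES occurs anywhere in
#' `test_like` (validation plus test) are removed first — the leakage guard —
#' as are pool compounds already present in training.
#'
#' @param train an [rt_dataset] (current training records).
#' @param pool an [rt_dataset] of labeled candidates (must carry `rt`).
#' @param test_like an [rt_dataset] of held-out records (or `NULL`).
#' @param tau similarity threshold in (0, 1]; inclusion is `>= tau`.
#' @param radius,nbits fingerprint parameters.
#' @param metric similarity metric (see [similarity_matrix()]).
#' @return an [rt_dataset]: `train` plus recruited records tagged
#'   `topo_al_added`.
#' @export
topo_al_expand <- function(train, pool, test_like = NULL, tau = 0.5,
                           radius = 2L, nbits = 2048L,
                           metric = c("tanimoto", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(tau > 0, tau <= 1)
  if (anyNA(pool$rt)) stopf("Topo-AL pool records must carry a measured rt")
  banned <- unique(c(
    train$smiles_canonical,
    if (!is.null(test_like)) test_like$smiles_canonical
  ))
  pool <- pool[!(pool$smiles_canonical %in% banned), , drop = FALSE]
  if (nrow(pool) == 0) return(train)
  fp_train <- ecfp(unique(train$smiles_canonical), radius = radius, nbits = nbits)
  if (inherits(fp_train, "bit_fingerprint")) fp_train <- list(fp_train)
  fp_pool <- ecfp(pool$smiles_canonical, radius = radius, nbits = nbits)
  if (inherits(fp_pool, "bit_fingerprint")) fp_pool <- list(fp_pool)
  S <- similarity_matrix(fp_pool, fp_train, metric = metric)
  max_sim <- apply(S, 1, max)
  add <- pool[max_sim >= tau, , drop = FALSE]
  if (nrow(add)) {
    add <- add[!duplicated(add$smiles_canonical), , drop = FALSE]
    add$provenance <- "topo_al_added"
    add$id <- paste0(add$id, "_al")
  }
  as_rt_dataset(rbind_rt(train, add))
}

#' Augmentation configuration
#'
#' @param k SMILES-enumeration multiple (default 5, the value at which model
#'   gain saturates on the motivating data).
#' @param tau Topo-AL similarity threshold in (0, 1] (default 0.5), or `NA`
#'   to disable Topo-AL.
#' @param guard_enabled monitor validation error and stop augmenting when it
#'   rises (default `TRUE`).
#' @param guard_tolerance relative validation-MAE increase over the best seen
#'   that triggers the stop (default 0.01).
#' @param seed integer seed.
#' @return an `augment_config` list.
#' @export
augment_config <- function(k = 5L, tau = 0.5, guard_enabled = TRUE,
                           guard_tolerance = 0.01, seed = 1L) {
  stopifnot(k >= 0, is.na(tau) || (tau > 0 && tau <= 1))
  structure(
    list(
      k = as.integer(k), tau = tau, guard_enabled = isTRUE(guard_enabled),
      guard_tolerance = guard_tolerance, seed = as.integer(seed)
    ),
    class = "augment_config"
  )
}

# Default guard probe: ridge regression on the module's feature interface.
# Cheap and deterministic; returns validation MAE.
default_fit_probe <- function(train, val) {
  fm <- compute_descriptors(train)
  sel <- select_features(fm, train$rt)
  Xtr <- fm$X[fm$row_ok, sel$selected_names, drop = FALSE]
  ytr <- train$rt[fm$row_ok]
  scaler <- fit_scaler(Xtr)
  Xs <- apply_scaler(scaler, Xtr)
  fit <- fit_ridge(Xs, ytr, lambda = 1)
  fmv <- compute_descriptors(val)
  Xv <- apply_scaler(scaler, fmv$X[, sel$selected_names, drop = FALSE])
  Xv[!is.finite(Xv)] <- 0
  mean(abs(predict_ridge(fit, Xv) - val$rt))
}

#' Guarded training-set augmentation
#'
#' Applies SMILES enumeration at multiples m = 1..k (and Topo-AL once, at
#' m = 1), monitoring a fast probe model's validation MAE after every step
#' (including the unaugmented baseline). If the MAE rises by more than
#' `guard_tolerance` relative to the best seen, augmentation stops early and
#' the best-scoring set is returned ("over-augmentation" guard). With the
#' guard disabled the full k multiples are applied unconditionally and the
#' final set is returned.
#'
#' @param train,val [rt_dataset]s: the training records to augment and the
#'   validation records scored by the probe.
#' @param pool labeled pool for Topo-AL (or `NULL` to skip).
#' @param test_like held-out records whose canonical SMILES must never enter
#'   training (validation plus test).
#' @param config an [augment_config()].
#' @param fit_probe `function(train, val) -> validation MAE`; default is a
#'   ridge fit on selected descriptors.
#' @param radius,nbits fingerprint parameters for Topo-AL.
#' @return an `augmented_set`: list with `table` (the augmented
#'   [rt_dataset]), `counts` (`n_original`, `n_se`, `n_topo_al`) and `log`
#'   (per-iteration probe metrics; `NULL` rows where the guard did not run).
#' @export
guarded_augment <- function(train, val, pool = NULL, test_like = NULL,
                            config = augment_config(), fit_probe = NULL,
                            radius = 2L, nbits = 2048L) {
  stopifnot(inherits(config, "augment_config"))
  use_guard <- config$guard_enabled
  if (use_guard && is.null(fit_probe)) fit_probe <- default_fit_probe
  k <- config$k

  # Pre-draw up to k distinct renderings per original training molecule;
  # multiple m uses the first m of them.
  parents <- train[train$provenance == "original", , drop = FALSE]
  variants <- if (k > 0) {
    chem_enumerate(parents$smiles_canonical, k = k, seed = config$seed)
  } else {
    replicate(nrow(parents), character(0), simplify = FALSE)
  }

  build_set <- function(m, with_topo) {
    base <- train
    if (with_topo && !is.null(pool) && !is.na(config$tau)) {
      base <- topo_al_expand(base, pool, test_like,
        tau = config$tau, radius = radius, nbits = nbits
      )
    }
    if (m > 0) {
      se_rows <- do.call(rbind, lapply(seq_len(nrow(parents)), function(i) {
        v <- utils::head(variants[[i]], m)
        if (!length(v)) return(NULL)
        # SE duplicates inherit the parent row (same rt, same canonical form)
        row <- as.data.frame(parents[rep(i, length(v)), , drop = FALSE])
        row$id <- paste0(parents$id[i], "_se", seq_along(v))
        row$smiles_raw <- v
        row$provenance <- "se_augmented"
        row
      }))
      if (!is.null(se_rows)) base <- as_rt_dataset(rbind_rt(base, se_rows))
    }
    base
  }

  want_topo <- !is.null(pool) && !is.na(config$tau)
  steps <- 0:k
  log <- data.frame(multiple = integer(0), n_rows = integer(0), val_mae = numeric(0))
  best <- NULL
  best_mae <- Inf
  last_set <- NULL
  for (m in steps) {
    set_m <- build_set(m, with_topo = want_topo && (m >= 1 || k == 0))
    last_set <- set_m
    if (!use_guard) next
    mae <- fit_probe(set_m, val)
    log <- rbind(log, data.frame(multiple = m, n_rows = nrow(set_m), val_mae = mae))
    if (mae < best_mae) {
      best_mae <- mae
      best <- set_m
    } else if (mae > best_mae * (1 + config$guard_tolerance)) {
      break
    }
  }
  out <- if (use_guard) best else last_set
  counts <- c(
    n_original = sum(out$provenance == "original"),
    n_se = sum(out$provenance == "se_augmented"),
    n_topo_al = sum(out$provenance == "topo_al_added")
  )
  structure(
    list(table = out, counts = counts, log = if (use_guard) log else NULL),
    class = "augmented_set"
  )
}
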