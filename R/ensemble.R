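#' Regression metrics for retention-time prediction
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2); `y_true` must
#'   be strictly positive (MAPE is relative to it).
#' @return an `rt_metrics` list: `mae` and `medae` in seconds, `mape` as a
#'   dimensionless fraction, `r2` the coefficient of determination.
#' @export
rt_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("y_true and y_pred lengths differ")
  if (length(y_true) < 2) stopf("need at least 2 observations")
  if (any(y_true <= 0)) stopf("y_true must be strictly positive for MAPE")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stopf("zero-variance y_true: R2 undefined")
  d <- y_pred - y_true
  structure(
    list(
      mae = mean(abs(d)),
      medae = stats::median(abs(d)),
      mape = mean(abs(d) / y_true),
      r2 = 1 - sum(d^2) / ss_tot
    ),
    class = "rt_metrics"
  )
}

#' @export
print.rt_metrics <- function(x, ...) {
  cat(sprintf(
    "MAE %.3f s | MedAE %.3f s | MAPE %.2f%% | R2 %.4f\n",
    x$mae, x$medae, 100 * x$mape, x$r2
  ))
  invisible(x)
}

#' Train one per-class expert submodel (OPSRT selection)
#'
#' Every registered algorithm undergoes a seeded random hyperparameter search
#' of at most `budget` configurations (the first being the algorithm's
#' default), each scored by MAE on the class validation split. The global
#' argmin over (algorithm, configuration) becomes the class's optimal
#' prediction submodel; ties resolve to the earlier registry entry. The full
#' search log is retained so the argmin property is auditable.
#'
#' @param class_train,class_val [rt_dataset]s for this class.
#' @param class_id subclass label (or `"residual"`).
#' @param registry from [default_registry()].
#' @param budget max configurations per algorithm (default 20).
#' @param seed integer seed.
#' @param fp_radius,fp_nbits fingerprint parameters for the routing
#'   fingerprints stored with the submodel.
#' @return an `rt_submodel`: algorithm name, hyperparameters, selected
#'   feature names, scaler statistics, fitted estimator, `val_mae`, `val_r2`,
#'   the training fingerprints used for routing, and the search log.
#' @export
train_submodel <- function(class_train, class_val, class_id = "class",
                           registry = default_registry(), budget = 20L,
                           seed = 1L, fp_radius = 2L, fp_nbits = 2048L) {
  if (nrow(class_val) < 1) stopf("class '%s': empty validation set", class_id)
  fm <- compute_descriptors(class_train)
  sel <- select_features(fm, class_train$rt)
  Xtr <- fm$X[fm$row_ok, sel$selected_names, drop = FALSE]
  ytr <- class_train$rt[fm$row_ok]
  scaler <- fit_scaler(Xtr)
  Xs <- apply_scaler(scaler, Xtr)
  fmv <- compute_descriptors(class_val)
  Xv <- apply_scaler(scaler, fmv$X[, sel$selected_names, drop = FALSE])
  Xv[!is.finite(Xv)] <- 0
  yv <- class_val$rt

  log <- list()
  best <- NULL
  for (alg in names(registry)) {
    entry <- registry[[alg]]
    cfgs <- with_seed(derive_seed(seed, paste0("hp:", class_id, ":", alg)), {
      lapply(seq_len(budget), function(i) entry$sample_config(default = (i == 1)))
    })
    for (ci in seq_along(cfgs)) {
      fit_seed <- derive_seed(seed, paste0("fit:", class_id, ":", alg, ":", ci))
      model <- tryCatch(entry$fit(Xs, ytr, cfgs[[ci]], fit_seed), error = function(e) NULL)
      if (is.null(model)) next
      pred <- tryCatch(entry$predict(model, Xv), error = function(e) NULL)
      if (is.null(pred) || anyNA(pred)) next
      mae <- mean(abs(pred - yv))
      log[[length(log) + 1]] <- data.frame(
        algorithm = alg, config = ci, val_mae = mae, stringsAsFactors = FALSE
      )
      if (is.null(best) || mae < best$val_mae) {
        r2 <- if (length(yv) >= 2 && stats::var(yv) > 0) {
          1 - sum((pred - yv)^2) / sum((yv - mean(yv))^2)
        } else {
          NA_real_
        }
        best <- list(
          algorithm = alg, hyperparams = cfgs[[ci]], model = model,
          val_mae = mae, val_r2 = r2
        )
      }
    }
  }
  if (is.null(best)) stopf("class '%s': every candidate fit failed", class_id)
  fps <- ecfp(unique(class_train$smiles_canonical), radius = fp_radius, nbits = fp_nbits)
  if (inherits(fps, "bit_fingerprint")) fps <- list(fps)
  structure(
    list(
      class_id = class_id,
      algorithm = best$algorithm,
      hyperparams = best$hyperparams,
      selected_features = sel$selected_names,
      selection_report = sel,
      scaler = scaler,
      model = best$model,
      predict_fun = registry[[best$algorithm]]$predict,
      val_mae = best$val_mae,
      val_r2 = best$val_r2,
      n_train = nrow(class_train),
      train_fingerprints = fps,
      search_log = do.call(rbind, log)
    ),
    class = "rt_submodel"
  )
}

# Core trainer operating on an explicit split (used by train_ensemble and by
# the paired-design ablation harness, which must reuse one split across arms).
train_ensemble_core <- function(splits, rules, aug, min_size, registry, budget,
                                seed, fp_radius, fp_nbits, pool = NULL,
                                verbose = FALSE) {
  part <- partition_by_class(splits$train, rules, min_size = min_size)
  tables <- part$classes
  if (nrow(part$residual) >= 3) tables$residual <- part$residual
  if (!length(tables)) stopf("no class reaches min_size and residual is too small")

  val_asg <- assign_class(splits$val, rules)
  test_like <- as_rt_dataset(rbind_rt(splits$val, splits$test))
  if (is.null(pool)) pool <- splits$train

  submodels <- list()
  aug_logs <- list()
  for (cl in names(tables)) {
    cl_train <- tables[[cl]]
    cl_val <- if (cl == "residual") {
      as_rt_dataset(splits$val[!(val_asg$subclass %in% names(part$classes)), , drop = FALSE])
    } else {
      as_rt_dataset(splits$val[val_asg$subclass == cl, , drop = FALSE])
    }
    # a class with no validation representative is scored on the pooled split
    if (nrow(cl_val) == 0) cl_val <- splits$val
    aug_cl <- aug
    aug_cl$seed <- derive_seed(aug$seed, paste0("aug:", cl))
    aset <- guarded_augment(cl_train, cl_val,
      pool = pool, test_like = test_like,
      config = aug_cl, radius = fp_radius, nbits = fp_nbits
    )
    aug_logs[[cl]] <- list(counts = aset$counts, log = aset$log)
    if (verbose) {
      message(sprintf(
        "class %-35s train %4d -> %4d (se %d, topo %d)", cl,
        nrow(cl_train), nrow(aset$table), aset$counts["n_se"], aset$counts["n_topo_al"]
      ))
    }
    submodels[[cl]] <- train_submodel(aset$table, cl_val,
      class_id = cl, registry = registry, budget = budget,
      seed = derive_seed(seed, paste0("train:", cl)),
      fp_radius = fp_radius, fp_nbits = fp_nbits
    )
    if (verbose) {
      message(sprintf(
        "  OPSRT: %s (val MAE %.2f s)", submodels[[cl]]$algorithm, submodels[[cl]]$val_mae
      ))
    }
  }
  winners <- vapply(submodels, function(s) s$algorithm, character(1))
  structure(
    list(
      submodels = submodels,
      ruleset = rules,
      routing = list(mode = "taxonomy_first", sim_fallback_top_m = 5L, min_route_sim = 0),
      fp_params = list(radius = fp_radius, nbits = fp_nbits),
      config = list(
        augment = aug, min_size = min_size, budget = budget, seed = seed,
        registry = names(default_registry()) # advisory; entries live in the object
      ),
      registry = NULL,
      winner_fractions = table(winners) / length(winners),
      augment_log = aug_logs,
      splits = splits
    ),
    class = "rt_ensemble"
  )
}

#' Train a class-partitioned retention-time ensemble
#'
#' The full pipeline: deterministic 8:1:1 split by canonical SMILES,
#' partition of the training fold into functional-group subclasses, guarded
#' per-class augmentation (SMILES enumeration plus Topo-AL against the
#' all-class training pool, with strict exclusion of validation/test
#' molecules), per-class expert selection over the candidate registry, and
#' assembly into a routable ensemble.
#'
#' @param data an [rt_dataset] of `original` labeled records (>= 30).
#' @param rules an `rt_ruleset` (default: the shipped rule file).
#' @param aug an [augment_config()].
#' @param split_ratios train/val/test proportions (default 0.8/0.1/0.1).
#' @param min_size minimum class size for a dedicated submodel (default 15).
#' @param registry candidate algorithms, see [default_registry()].
#' @param budget hyperparameter configurations per algorithm (default 20).
#' @param seed integer seed controlling split, augmentation and search.
#' @param fp_radius,fp_nbits routing-fingerprint parameters.
#' @param verbose print per-class progress.
#' @return an `rt_ensemble`; the held-out `val`/`test` folds are attached as
#'   `$splits` for downstream evaluation.
#' @export
train_ensemble <- function(data, rules = default_ruleset(), aug = augment_config(),
                           split_ratios = c(0.8, 0.1, 0.1), min_size = 15L,
                           registry = default_registry(), budget = 20L, seed = 1L,
                           fp_radius = 2L, fp_nbits = 2048L, verbose = FALSE) {
  if (nrow(data) < 30) stopf("need at least 30 records to train (got %d)", nrow(data))
  splits <- split_dataset(data, ratios = split_ratios, seed = seed)
  model <- train_ensemble_core(splits, rules, aug, min_size, registry, budget,
    seed, fp_radius, fp_nbits,
    verbose = verbose
  )
  model
}

#' Route a query molecule to a submodel
#'
#' The discriminant stage: taxonomy first — if the query's subclass has a
#' submodel and its maximum fingerprint similarity to that submodel's
#' training set reaches `min_route_sim`, route there. Otherwise fall back to
#' the submodel maximizing the mean of the top-m similarities between the
#' query and each submodel's training fingerprints; ties break to the larger
#' training class, then lexicographic class id.
#'
#' @param query an [rt_dataset] (queries) or character vector of SMILES.
#' @param model an `rt_ensemble`.
#' @return data.frame with `class_id` and `route_mode` (`"taxonomy"` or
#'   `"similarity_fallback"`) per query.
#' @export
route <- function(query, model) {
  stopifnot(inherits(model, "rt_ensemble"))
  tab <- if (inherits(query, "rt_dataset")) query else
    rt_dataset(id = paste0("q", seq_along(query)), smiles = query)
  asg <- assign_class(tab, model$ruleset)
  fps <- ecfp(tab$smiles_canonical,
    radius = model$fp_params$radius, nbits = model$fp_params$nbits
  )
  if (inherits(fps, "bit_fingerprint")) fps <- list(fps)
  classes <- names(model$submodels)
  m <- model$routing$sim_fallback_top_m
  floor_sim <- model$routing$min_route_sim
  n_train <- vapply(model$submodels, function(s) s$n_train, numeric(1))
  # per-submodel similarity blocks, computed once per batch
  simblocks <- lapply(classes, function(cl) {
    similarity_matrix(fps, model$submodels[[cl]]$train_fingerprints)
  })
  names(simblocks) <- classes
  out <- data.frame(
    class_id = character(nrow(tab)), route_mode = character(nrow(tab)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(tab))) {
    cl <- asg$subclass[i]
    if (cl %in% classes && max(simblocks[[cl]][i, ]) >= floor_sim) {
      out$class_id[i] <- cl
      out$route_mode[i] <- "taxonomy"
      next
    }
    score <- vapply(classes, function(cc) {
      s <- sort(simblocks[[cc]][i, ], decreasing = TRUE)
      mean(utils::head(s, m))
    }, numeric(1))
    top <- which(score == max(score))
    if (length(top) > 1) top <- top[order(-n_train[top], classes[top])][1]
    out$class_id[i] <- classes[top]
    out$route_mode[i] <- "similarity_fallback"
  }
  out
}

#' Predict retention times for query molecules
#'
#' Each query is routed to a submodel, its stored feature list is recomputed,
#' scaled with the stored training statistics, and regressed. Unparseable
#' SMILES yield a per-row error record rather than aborting the batch; output
#' rows align one-to-one with input rows.
#'
#' @param object an `rt_ensemble`.
#' @param newdata an [rt_dataset], a data.frame with `id` and `smiles`
#'   columns, or a character vector of SMILES.
#' @param ... unused.
#' @return data.frame: `id`, `smiles`, `predicted_rt`, `class_super`,
#'   `class_sub`, `submodel_algorithm`, `route_mode`, `error`.
#' @export
predict.rt_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "rt_dataset")) {
    ids <- newdata$id
    smiles <- newdata$smiles_raw
  } else if (is.data.frame(newdata)) {
    stopifnot(all(c("id", "smiles") %in% names(newdata)))
    ids <- as.character(newdata$id)
    smiles <- as.character(newdata$smiles)
  } else {
    smiles <- as.character(newdata)
    ids <- paste0("q", seq_along(smiles))
  }
  can <- chem_canonicalize(smiles)
  ok <- !is.na(can)
  out <- data.frame(
    id = ids, smiles = smiles, predicted_rt = NA_real_,
    class_super = NA_character_, class_sub = NA_character_,
    submodel_algorithm = NA_character_, route_mode = NA_character_,
    error = ifelse(ok, NA_character_, "unparseable SMILES"),
    stringsAsFactors = FALSE
  )
  if (!any(ok)) return(out)
  tab <- as_rt_dataset(data.frame(
    id = ids[ok], smiles_raw = smiles[ok], smiles_canonical = can[ok],
    rt = NA_real_, provenance = "original", stringsAsFactors = FALSE
  ))
  asg <- assign_class(tab, object$ruleset)
  routing <- route(tab, object)
  idx_ok <- which(ok)
  out$class_super[idx_ok] <- asg$superclass
  out$class_sub[idx_ok] <- asg$subclass
  out$route_mode[idx_ok] <- routing$route_mode
  for (cl in unique(routing$class_id)) {
    rows <- which(routing$class_id == cl)
    sm <- object$submodels[[cl]]
    fm <- compute_descriptors(tab[rows, , drop = FALSE])
    X <- apply_scaler(sm$scaler, fm$X[, sm$selected_features, drop = FALSE])
    X[!is.finite(X)] <- 0
    pred <- sm$predict_fun(sm$model, X)
    out$predicted_rt[idx_ok[rows]] <- pred
    out$submodel_algorithm[idx_ok[rows]] <- sm$algorithm
  }
  out
}

#' Evaluate an ensemble on labeled molecules
#'
#' @param model an `rt_ensemble`.
#' @param data an [rt_dataset] with measured `rt` (defaults to the model's
#'   held-out test split).
#' @return an [rt_metrics] report over the successfully predicted rows.
#' @export
evaluate_ensemble <- function(model, data = model$splits$test) {
  preds <- stats::predict(model, data)
  keep <- !is.na(preds$predicted_rt)
  rt_metrics(data$rt[keep], preds$predicted_rt[keep])
}

#' @export
print.rt_ensemble <- function(x, ...) {
  cat("Class-partitioned retention-time ensemble\n")
  cat("  submodels:", length(x$submodels), "|",
      "routing:", x$routing$mode, "\n")
  wf <- sort(x$winner_fractions, decreasing = TRUE)
  cat("  winning algorithms:",
      paste(sprintf("%s %.0f%%", names(wf), 100 * as.numeric(wf)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rt_ensemble <- function(object, ...) {
  df <- do.call(rbind, lapply(object$submodels, function(s) {
    data.frame(
      class_id = s$class_id, n_train = s$n_train, algorithm = s$algorithm,
      n_features = length(s$selected_features),
      val_mae = s$val_mae, val_r2 = s$val_r2, stringsAsFactors = FALSE
    )
  }))
  rownames(df) <- NULL
  df
}

#' Four-arm data-augmentation ablation
#'
#' A paired design: within each seed the split (and Topo-AL pool) is fixed,
#' and only the augmentation arm varies — `none` (no augmentation), `se`
#' (SMILES enumeration only), `topo_al` (similarity recruitment only), `both`.
#' Reports per-arm, per-seed test metrics plus per-arm means.
#'
#' @param data an [rt_dataset], or a `function(seed)` returning a list with
#'   `train`, `val`, `test` and optionally `pool` (a pre-built sparse regime).
#' @param arms subset of `c("none", "se", "topo_al", "both")`.
#' @param seeds integer vector (>= 2 seeds).
#' @param k,tau augmentation parameters for the active arms.
#' @param ... passed to the trainer (`registry`, `budget`, `min_size`,
#'   `rules`, ...).
#' @return an `rt_ablation`: data.frame of per-arm/per-seed metrics with a
#'   `summary` attribute of per-arm means and sds.
#' @export
ablate <- function(data, arms = c("none", "se", "topo_al", "both"), seeds = 1:5,
                   k = 5L, tau = 0.5, rules = default_ruleset(), min_size = 15L,
                   registry = default_registry(), budget = 20L,
                   fp_radius = 2L, fp_nbits = 2048L, guard_enabled = FALSE) {
  arms <- match.arg(arms, several.ok = TRUE)
  if (length(seeds) < 2) stopf("ablation needs at least 2 seeds")
  arm_cfg <- list(
    none = list(k = 0L, tau = NA_real_),
    se = list(k = k, tau = NA_real_),
    topo_al = list(k = 0L, tau = tau),
    both = list(k = k, tau = tau)
  )
  rows <- list()
  for (seed in seeds) {
    if (is.function(data)) {
      regime <- data(seed)
      splits <- list(train = regime$train, val = regime$val, test = regime$test)
      pool <- regime$pool
    } else {
      splits <- split_dataset(data, seed = seed)
      pool <- NULL
    }
    for (arm in arms) {
      cfg <- arm_cfg[[arm]]
      aug <- augment_config(
        k = cfg$k, tau = cfg$tau,
        guard_enabled = guard_enabled, seed = derive_seed(seed, "ablate-aug")
      )
      model <- train_ensemble_core(splits, rules, aug, min_size, registry,
        budget, derive_seed(seed, "ablate-train"), fp_radius, fp_nbits,
        pool = pool
      )
      met <- evaluate_ensemble(model, splits$test)
      rows[[length(rows) + 1]] <- data.frame(
        arm = arm, seed = seed, mae = met$mae, medae = met$medae,
        mape = met$mape, r2 = met$r2, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(res, res$arm), function(d) {
    data.frame(
      arm = d$arm[1], mean_mae = mean(d$mae), sd_mae = stats::sd(d$mae),
      mean_r2 = mean(d$r2), stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  structure(res, summary = agg, class = c("rt_ablation", "data.frame"))
}
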