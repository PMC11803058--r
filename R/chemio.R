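#' Construct a molecule dataset table
#'
#' The central data container: one row per molecule record, carrying the raw
#' and canonical SMILES, the retention time in seconds, and a provenance tag
#' distinguishing original measurements from augmentation products.
#'
#' @param id character vector of unique record identifiers.
#' @param smiles character vector of SMILES strings as supplied.
#' @param rt numeric retention times in seconds (strictly positive), or `NA`
#'   for query (prediction-time) records.
#' @param provenance one of `"original"`, `"se_augmented"`, `"topo_al_added"`
#'   per record.
#' @param canonicalize if `TRUE` (default) canonical forms are computed
#'   through the RDKit bridge; rows whose SMILES fail to parse or whose `rt`
#'   is non-positive are dropped and counted in `attr(x, "n_rejected")`.
#' @return an `rt_dataset`: a data.frame with columns `id`, `smiles_raw`,
#'   `smiles_canonical`, `rt`, `provenance`.
#' @export
rt_dataset <- function(id, smiles, rt = NA_real_, provenance = "original",
                       canonicalize = TRUE) {
  n <- length(smiles)
  df <- data.frame(
    id = as.character(id),
    smiles_raw = as.character(smiles),
    smiles_canonical = NA_character_,
    rt = rep_len(as.numeric(rt), n),
    provenance = rep_len(as.character(provenance), n),
    stringsAsFactors = FALSE
  )
  n_rejected <- 0L
  if (canonicalize && n > 0) {
    df$smiles_canonical <- chem_canonicalize(df$smiles_raw)
    bad <- is.na(df$smiles_canonical) | (!is.na(df$rt) & df$rt <= 0)
    n_rejected <- sum(bad)
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$id)) stopf("duplicate record ids in dataset")
  rownames(df) <- NULL
  structure(df,
    class = c("rt_dataset", "data.frame"),
    n_rejected = n_rejected
  )
}

as_rt_dataset <- function(df) {
  stopifnot(all(c("id", "smiles_raw", "smiles_canonical", "rt", "provenance") %in% names(df)))
  rownames(df) <- NULL
  structure(df, class = c("rt_dataset", "data.frame"))
}

#' Read a molecule table from CSV or SMI text
#'
#' CSV files must carry header columns `id`, `smiles` and (except for query
#' files) `rt`; SMI files are one `SMILES<TAB>id` pair per line. Rows whose
#' SMILES cannot be parsed, or whose retention time is non-positive, are
#' dropped; the count of dropped rows is attached as `attr(x, "n_rejected")`.
#'
#' @param path file path.
#' @param format `"csv"` or `"smi"`.
#' @param rt_unit `"s"` (default) or `"min"`; minutes are converted to
#'   seconds at ingest.
#' @return an [rt_dataset].
#' @export
read_dataset <- function(path, format = c("csv", "smi"), rt_unit = c("s", "min")) {
  format <- match.arg(format)
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stopf("input file does not exist: %s", path)
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(raw))) {
      stopf("CSV must have header columns 'id' and 'smiles' (got: %s)",
            paste(names(raw), collapse = ", "))
    }
    rt <- if ("rt" %in% names(raw)) as.numeric(raw$rt) else rep(NA_real_, nrow(raw))
    id <- raw$id
    smiles <- raw$smiles
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    smiles <- vapply(parts, `[`, character(1), 1L)
    id <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))
    id[is.na(id)] <- paste0("mol", seq_along(id))[is.na(id)]
    rt <- rep(NA_real_, length(smiles))
  }
  if (rt_unit == "min") rt <- rt * 60
  tab <- rt_dataset(id = id, smiles = smiles, rt = rt)
  if (nrow(tab) == 0) stopf("no parseable rows in %s", path)
  tab
}

#' Write a molecule table to CSV
#'
#' @param table an [rt_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, path) {
  utils::write.csv(
    data.frame(
      id = table$id, smiles = table$smiles_canonical,
      rt = table$rt, provenance = table$provenance
    ),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Canonicalize SMILES strings
#'
#' Deterministic toolkit canonical form; idempotent. Two renderings of the
#' same molecular graph (including Kekulé vs aromatic notation) map to one
#' string.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES.
#' @export
canonicalize <- function(smiles) {
  out <- chem_canonicalize(smiles)
  if (anyNA(out)) {
    stopf("invalid SMILES: %s", paste(smiles[is.na(out)], collapse = ", "))
  }
  out
}

#' Split a dataset into train/validation/test
#'
#' Deterministic 8:1:1 (by default) partition, disjoint and exhaustive by
#' canonical SMILES: duplicate renderings of one molecule always land in the
#' same fold. Fold sizes are floors of the ratios with the remainder assigned
#' to the training fold.
#'
#' @param table an [rt_dataset] of `original` records.
#' @param ratios three non-negative numbers summing to 1.
#' @param seed integer seed; identical seeds give identical partitions.
#' @return list with elements `train`, `val`, `test` (each an [rt_dataset]).
#' @export
split_dataset <- function(table, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9) stopf("split ratios must sum to 1")
  if (!all(table$provenance == "original")) {
    stopf("split_dataset expects only provenance='original' records (split precedes augmentation)")
  }
  keys <- unique(table$smiles_canonical)
  n <- length(keys)
  if (n < 3) stopf("dataset too small to split: %d unique molecules (need >= 3)", n)
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  n_train <- n - n_val - n_test # remainder goes to train
  rng <- with_seed(derive_seed(seed, "split"), sample.int(n))
  keys <- keys[rng]
  fold <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  assignment <- stats::setNames(fold, keys)
  pick <- function(f) as_rt_dataset(table[assignment[table$smiles_canonical] == f, , drop = FALSE])
  list(train = pick("train"), val = pick("val"), test = pick("test"))
}

CLASSRT_SCHEMA_VERSION <- 1L

#' Persist a trained ensemble to a directory
#'
#' Writes a JSON manifest (the compatibility contract: schema version,
#' taxonomy rule hash, feature lists, routing configuration) plus one
#' serialized estimator per class. [load_model()] restores an ensemble whose
#' predictions are bit-identical.
#'
#' @param model an `rt_ensemble` from [train_ensemble()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "rt_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    schema_version = CLASSRT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("classrt")),
    ruleset_hash = model$ruleset$hash,
    routing = model$routing,
    fp_params = model$fp_params,
    classes = names(model$submodels),
    features = lapply(model$submodels, function(s) s$selected_features)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  saveRDS(model, file.path(dir, "ensemble.rds"))
  invisible(manifest)
}

#' @rdname save_model
#' @param dir directory written by [save_model()].
#' @export
load_model <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stopf("missing manifest.json in %s: not a model directory", dir)
  manifest <- jsonlite::fromJSON(mf)
  if (!identical(as.integer(manifest$schema_version), CLASSRT_SCHEMA_VERSION)) {
    stopf(
      "model schema version %s is incompatible with this package (expects %d)",
      manifest$schema_version, CLASSRT_SCHEMA_VERSION
    )
  }
  readRDS(file.path(dir, "ensemble.rds"))
}
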