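# Shared lazily-built fixtures. Everything is generated in code (no stored
# data); the cache keeps the backend subprocess traffic low across files.
.fix <- new.env(parent = emptyenv())

# 4-family library, 30 molecules each, 10 s noise.
fix_lib <- function() {
  if (is.null(.fix$lib)) {
    .fix$lib <- generate_library(synth_config(
      n_classes = 4L, per_class = 30L, noise_sd = 10, seed = 42L
    ))
  }
  .fix$lib
}

# A small but real ensemble: fast registry subset, one config each.
fix_model <- function() {
  if (is.null(.fix$model)) {
    .fix$model <- train_ensemble(
      fix_lib()$data,
      aug = augment_config(k = 1L, tau = NA, guard_enabled = FALSE, seed = 42L),
      registry = default_registry(c("ridge_linear", "knn")),
      budget = 1L, min_size = 10L, seed = 42L
    )
  }
  .fix$model
}

# Construct a bit fingerprint without the toolkit (for set-arithmetic tests).
make_fp <- function(on_bits, nbits = 2048L) {
  structure(
    list(on_bits = sort(unique(as.integer(on_bits))), nbits = as.integer(nbits),
         radius = 2L),
    class = "bit_fingerprint"
  )
}

# Write a small molecules CSV and return its path.
write_mol_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Write a rule TSV and return its path.
write_rule_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
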