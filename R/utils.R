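# Stage-specific seed derivation: one user seed fans out to independent,
# reproducible per-stage streams. Kept strictly below 2^31.
derive_seed <- function(seed, stage) {
  h <- digest::digest2int(paste0(stage, "::", seed))
  as.integer(abs(h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind two record tables, aligning columns (union, NA-filled).
rbind_rt <- function(a, b) {
  if (is.null(b) || nrow(b) == 0) return(a)
  if (is.null(a) || nrow(a) == 0) return(b)
  cols <- union(names(a), names(b))
  for (cc in setdiff(cols, names(a))) a[[cc]] <- NA
  for (cc in setdiff(cols, names(b))) b[[cc]] <- NA
  out <- rbind(as.data.frame(a)[cols], as.data.frame(b)[cols])
  rownames(out) <- NULL
  out
}

# Evaluate expr under a local RNG state so package internals never disturb
# the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
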