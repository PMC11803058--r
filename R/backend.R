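# Session-level caches for toolkit results. Keys are canonical-enough strings
# (the raw SMILES for canonicalization; canonical SMILES + params elsewhere),
# so repeated pipeline stages and SE duplicates never re-pay the subprocess.
.classrt <- new.env(parent = emptyenv())
.classrt$canon <- new.env(parent = emptyenv())
.classrt$fp <- new.env(parent = emptyenv())
.classrt$desc <- new.env(parent = emptyenv())
.classrt$desc_names <- NULL

chem_python <- function() {
  py <- getOption("classrt.python", Sys.getenv("CLASSRT_PYTHON", ""))
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the RDKit bridge", call. = FALSE)
  py
}

chem_backend_script <- function() {
  p <- system.file("python", "chem_backend.py", package = "classrt")
  if (!nzchar(p)) stop("chem_backend.py not found in the installed package", call. = FALSE)
  p
}

# One batched round-trip to the RDKit backend. `payload` is a named list;
# returns the parsed JSON response (vectors not simplified to matrices).
chem_call <- function(op, payload) {
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(c(list(op = op), payload), req,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  status <- suppressWarnings(system2(chem_python(), c(chem_backend_script(), req, resp),
    stdout = FALSE, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(resp)) {
    stop("RDKit backend call failed (op=", op, ", status=", status, ")", call. = FALSE)
  }
  out <- jsonlite::fromJSON(resp, simplifyVector = TRUE, simplifyMatrix = FALSE,
    simplifyDataFrame = FALSE
  )
  if (!is.null(out$error)) stop("RDKit backend error: ", out$error, call. = FALSE)
  out
}

# Vectorized canonicalization with cache; invalid SMILES -> NA.
chem_canonicalize <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  key <- smiles
  hit <- vapply(key, function(k) !is.na(k) && nzchar(k) &&
    !is.null(.classrt$canon[[k]]), logical(1))
  out[hit] <- vapply(key[hit], function(k) .classrt$canon[[k]], character(1))
  todo <- which(!hit & !is.na(smiles) & nzchar(smiles))
  if (length(todo)) {
    res <- chem_call("canonicalize", list(smiles = as.list(smiles[todo])))
    can <- vapply(res$canonical, function(x) {
      if (is.null(x) || is.na(x)) NA_character_ else as.character(x)
    }, character(1))
    out[todo] <- can
    for (i in seq_along(todo)) {
      if (!is.na(can[i])) assign(smiles[todo[i]], can[i], envir = .classrt$canon)
    }
  }
  out
}

# ECFP on-bit sets (0-based indices), cached per (canonical smiles, radius, nbits).
chem_ecfp_bits <- function(smiles, radius = 2L, nbits = 2048L) {
  smiles <- as.character(smiles)
  keys <- paste0(smiles, "|", radius, "|", nbits)
  out <- vector("list", length(smiles))
  hit <- vapply(keys, function(k) !is.null(.classrt$fp[[k]]), logical(1))
  out[hit] <- lapply(keys[hit], function(k) .classrt$fp[[k]])
  todo <- which(!hit)
  if (length(todo)) {
    res <- chem_call("ecfp", list(
      smiles = as.list(smiles[todo]),
      radius = radius, nbits = nbits
    ))
    for (i in seq_along(todo)) {
      b <- res$on_bits[[i]]
      bits <- if (is.null(b)) NULL else as.integer(b)
      out[[todo[i]]] <- bits
      if (!is.null(bits)) assign(keys[todo[i]], bits, envir = .classrt$fp)
    }
  }
  out
}

chem_smarts_compile <- function(patterns) {
  res <- chem_call("compile_smarts", list(patterns = as.list(patterns)))
  list(
    ok = vapply(res$ok, isTRUE, logical(1)),
    error = vapply(res$msg, function(x) {
      if (is.null(x) || is.na(x)) NA_character_ else as.character(x)
    }, character(1))
  )
}

# Logical matrix: one row per molecule, one column per SMARTS pattern.
# Rows for unparseable molecules are NA.
chem_smarts_match <- function(smiles, patterns) {
  res <- chem_call("smarts_match", list(
    smiles = as.list(smiles), patterns = as.list(patterns)
  ))
  m <- matrix(NA, nrow = length(smiles), ncol = length(patterns))
  for (i in seq_along(res$match)) {
    row <- res$match[[i]]
    if (!is.null(row)) m[i, ] <- as.logical(unlist(row))
  }
  m
}

# Randomized SMILES renderings: list of character vectors, one per molecule.
# Per-molecule seeds keep results independent of batch composition.
chem_enumerate <- function(smiles, k, seed) {
  if (k <= 0 || length(smiles) == 0) {
    return(replicate(length(smiles), character(0), simplify = FALSE))
  }
  seeds <- unname(vapply(smiles, function(s) derive_seed(seed, paste0("enum:", s)), integer(1)))
  res <- chem_call("enumerate", list(
    smiles = as.list(smiles), k = as.integer(k), seeds = as.list(seeds)
  ))
  lapply(res$variants, function(v) as.character(unlist(v)))
}

# Full RDKit 2D descriptor block; rows cached by canonical SMILES.
# Returns a numeric matrix (NA where the toolkit produced non-finite values)
# with descriptor names as colnames; all-NA rows mark failed molecules.
chem_descriptors <- function(smiles) {
  smiles <- as.character(smiles)
  todo <- unique(smiles[!vapply(smiles, function(s) !is.null(.classrt$desc[[s]]), logical(1))])
  if (length(todo)) {
    res <- chem_call("descriptors", list(smiles = as.list(todo)))
    nm <- unlist(res$names)
    if (is.null(.classrt$desc_names)) .classrt$desc_names <- nm
    for (i in seq_along(todo)) {
      row <- res$values[[i]]
      v <- if (is.null(row)) rep(NA_real_, length(nm)) else
        vapply(row, function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1))
      assign(todo[i], v, envir = .classrt$desc)
    }
  }
  nm <- .classrt$desc_names
  X <- do.call(rbind, lapply(smiles, function(s) .classrt$desc[[s]]))
  colnames(X) <- nm
  rownames(X) <- NULL
  X
}
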