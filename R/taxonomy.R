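#' Compile a weighted SMARTS classification rule file
#'
#' The taxonomy engine is a local, deterministic stand-in for an
#' ontology-service classification: each rule is a SMARTS pattern with a
#' priority weight and a (superclass, subclass) label; the matched rule of
#' maximal weight classifies the molecule. The shipped default file covers 13
#' superclasses of the usual functional-group chemistry (acids, benzenoids,
#' N/S/P compounds, heterocycles, lipids, phenylpropanoids, ...).
#'
#' @param rule_file path to a UTF-8 TSV with header
#'   `rule_id  smarts  weight  superclass  subclass`.
#' @param fallback length-2 character: class assigned when nothing matches.
#' @return an `rt_ruleset`: list with `rules` (data.frame), `fallback`, and
#'   `hash` (digest of the file content, stamped into trained models).
#' @export
compile_rules <- function(rule_file, fallback = c("unclassified", "unclassified")) {
  if (!file.exists(rule_file)) stopf("rule file does not exist: %s", rule_file)
  rules <- utils::read.delim(rule_file, stringsAsFactors = FALSE, quote = "")
  need <- c("rule_id", "smarts", "weight", "superclass", "subclass")
  if (!all(need %in% names(rules))) {
    stopf("rule file must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(rules) == 0) stopf("rule file contains no rules")
  dup <- rules$rule_id[duplicated(rules$rule_id)]
  if (length(dup)) stopf("duplicate rule_id: %s", paste(unique(dup), collapse = ", "))
  rules$weight <- as.numeric(rules$weight)
  if (any(!is.finite(rules$weight) | rules$weight <= 0)) {
    stopf("all rule weights must be positive")
  }
  if (any(!nzchar(rules$superclass) | !nzchar(rules$subclass))) {
    stopf("superclass/subclass labels must be non-empty")
  }
  comp <- chem_smarts_compile(rules$smarts)
  if (any(!comp$ok)) {
    i <- which(!comp$ok)[1]
    stopf("rule '%s' has invalid SMARTS: %s", rules$rule_id[i], rules$smarts[i])
  }
  structure(
    list(
      rules = rules[order(rules$rule_id), , drop = FALSE],
      fallback = as.character(fallback),
      hash = digest::digest(readChar(rule_file, file.size(rule_file)), algo = "sha256")
    ),
    class = "rt_ruleset"
  )
}

#' @rdname compile_rules
#' @export
default_ruleset <- function() {
  compile_rules(system.file("extdata", "rules_default.tsv", package = "classrt"))
}

#' Classify molecules by weighted functional-group rules
#'
#' Total and deterministic: every valid molecule receives a class. Among all
#' matched rules the one of maximal weight wins; ties break by lexicographic
#' `rule_id`; molecules matching no rule receive the ruleset's fallback class
#' with winning weight 0.
#'
#' @param mol an [rt_dataset], or a character vector of SMILES.
#' @param rules an `rt_ruleset` from [compile_rules()].
#' @return data.frame with one row per molecule: `superclass`, `subclass`,
#'   `winning_weight`, `matched_rule_ids` (comma-separated).
#' @export
assign_class <- function(mol, rules = default_ruleset()) {
  stopifnot(inherits(rules, "rt_ruleset"))
  smiles <- if (inherits(mol, "rt_dataset")) mol$smiles_canonical else canonicalize(mol)
  rtab <- rules$rules # already ordered by rule_id => ties resolve lexicographically
  m <- chem_smarts_match(smiles, rtab$smarts)
  out <- data.frame(
    superclass = character(length(smiles)),
    subclass = character(length(smiles)),
    winning_weight = numeric(length(smiles)),
    matched_rule_ids = character(length(smiles)),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(smiles)) {
    hits <- which(m[i, ] %in% TRUE)
    if (length(hits) == 0) {
      out$superclass[i] <- rules$fallback[1]
      out$subclass[i] <- rules$fallback[2]
      out$winning_weight[i] <- 0
      out$matched_rule_ids[i] <- ""
    } else {
      win <- hits[which.max(rtab$weight[hits])] # first max = lexicographic tie-break
      out$superclass[i] <- rtab$superclass[win]
      out$subclass[i] <- rtab$subclass[win]
      out$winning_weight[i] <- rtab$weight[win]
      out$matched_rule_ids[i] <- paste(rtab$rule_id[hits], collapse = ",")
    }
  }
  out
}

#' Partition a dataset into per-subclass tables
#'
#' Every record lands in exactly one subclass table or, when its subclass has
#' fewer than `min_size` members, in the shared residual pool (which later
#' trains a single fallback submodel) — so the partition conserves records.
#'
#' @param table an [rt_dataset].
#' @param rules an `rt_ruleset`.
#' @param min_size minimum class size for a dedicated table (default 15).
#' @return list with `classes` (named list of [rt_dataset]s, keyed by
#'   subclass), `residual` (an [rt_dataset], possibly empty) and
#'   `assignment` (the [assign_class()] output, row-aligned with `table`).
#' @export
partition_by_class <- function(table, rules = default_ruleset(), min_size = 15L) {
  stopifnot(min_size >= 3)
  asg <- assign_class(table, rules)
  sizes <- table(asg$subclass)
  keep <- names(sizes)[sizes >= min_size]
  classes <- lapply(stats::setNames(keep, keep), function(cl) {
    as_rt_dataset(table[asg$subclass == cl, , drop = FALSE])
  })
  residual <- as_rt_dataset(table[!(asg$subclass %in% keep), , drop = FALSE])
  list(classes = classes, residual = residual, assignment = asg)
}
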