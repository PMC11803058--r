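test_that("SMILES enumeration round-trips and respects k", {
  expect_length(enumerate_smiles("CCO", k = 0), 0)

  v <- enumerate_smiles("CCO", k = 5, seed = 2)
  can <- canonicalize("CCO")
  expect_lte(length(v), 5)
  expect_gt(length(v), 0)
  expect_false(any(v == can))
  expect_false(anyDuplicated(v) > 0)
  expect_true(all(canonicalize(v) == can))

  # single-atom graph has essentially one rendering
  expect_lt(length(enumerate_smiles("C", k = 5, seed = 2)), 5)
})

test_that("enumeration is seed-deterministic and batch-independent", {
  v1 <- enumerate_smiles(c("CCCO", "CCN"), k = 3, seed = 9)
  v2 <- enumerate_smiles(c("CCN", "CCCO"), k = 3, seed = 9)
  expect_identical(v1[[1]], v2[[2]])
  expect_identical(v1[[2]], v2[[1]])
})

test_that("topo_al_expand recruits by max-similarity threshold and excludes leaks", {
  sp <- make_sparse_regime(synth_config(n_classes = 4L, per_class = 40L, seed = 13),
                           n_train = 8L, n_val = 5L, n_test = 5L)
  test_like <- rbind(as.data.frame(sp$val), as.data.frame(sp$test))
  # plant a leak: a pool record that is (another rendering of) a test molecule
  leak <- sp$test[1, , drop = FALSE]
  leak$id <- "leak"
  pool <- classrt:::as_rt_dataset(rbind(as.data.frame(sp$pool), as.data.frame(leak)))

  out <- topo_al_expand(sp$train, pool, test_like, tau = 0.5)
  added <- out[out$provenance == "topo_al_added", ]

  # the stated rule, recomputed here: max similarity to train >= tau, not in test_like
  fp_tr <- ecfp(sp$train$smiles_canonical)
  fp_po <- ecfp(pool$smiles_canonical)
  msim <- apply(similarity_matrix(fp_po, fp_tr), 1, max)
  should <- pool$smiles_canonical[
    msim >= 0.5 & !(pool$smiles_canonical %in% test_like$smiles_canonical)
  ]
  expect_setequal(added$smiles_canonical, unique(should))
  expect_false(leak$smiles_canonical %in% added$smiles_canonical)
  expect_true(any(msim[pool$id == "leak"] > 0.5)) # the leak was similar, exclusion was the guard
  # recruited records keep their own measured rt
  expect_true(all(added$rt > 0))

  # monotonicity: lower threshold recruits a superset
  out_lo <- topo_al_expand(sp$train, pool, test_like, tau = 0.3)
  expect_true(all(added$smiles_canonical %in% out_lo$smiles_canonical))

  bad_pool <- pool
  bad_pool$rt[1] <- NA
  expect_error(topo_al_expand(sp$train, bad_pool, test_like, tau = 0.5), "rt")
})

test_that("guarded augmentation traces the stop rule and returns the best set", {
  tab <- fix_lib()$data
  s <- split_dataset(tab, seed = 5)
  maes <- c(10, 9, 9.5, 8, 7)
  calls <- 0
  probe <- function(train, val) {
    calls <<- calls + 1
    maes[calls]
  }
  aset <- guarded_augment(s$train, s$val,
    config = augment_config(k = 4, tau = NA, guard_tolerance = 0.01, seed = 1),
    fit_probe = probe
  )
  # MAE 9.5 > 9 * 1.01: stop after the third evaluation, keep the second set
  expect_equal(calls, 3)
  expect_equal(nrow(aset$log), 3)
  expect_equal(aset$log$multiple, c(0, 1, 2))
  expect_equal(sum(aset$table$provenance == "se_augmented"),
               aset$log$n_rows[2] - aset$log$n_rows[1])

  # monotonically improving probe: all k multiples applied, no early stop
  calls <- 0
  maes <- c(10, 9, 8, 7, 6)
  aset2 <- guarded_augment(s$train, s$val,
    config = augment_config(k = 4, tau = NA, guard_tolerance = 0.01, seed = 1),
    fit_probe = probe
  )
  expect_equal(nrow(aset2$log), 5)
  expect_equal(aset2$counts[["n_se"]],
               sum(aset2$table$provenance == "se_augmented"))
})

test_that("guard disabled applies the full multiple and counts balance", {
  tab <- fix_lib()$data
  s <- split_dataset(tab, seed = 5)
  small <- classrt:::as_rt_dataset(as.data.frame(s$train)[1:12, ])
  aset <- guarded_augment(small, s$val,
    config = augment_config(k = 3, tau = NA, guard_enabled = FALSE, seed = 1)
  )
  expect_null(aset$log)
  expect_equal(sum(aset$counts), nrow(aset$table))
  expect_equal(aset$counts[["n_original"]], 12)
  # every parent contributes up to k variants (string-collision shortfall allowed)
  expect_lte(aset$counts[["n_se"]], 3 * 12)
  expect_gt(aset$counts[["n_se"]], 0)
  # every enumerated row round-trips onto its parent's canonical form
  se <- aset$table[aset$table$provenance == "se_augmented", ]
  expect_true(all(canonicalize(se$smiles_raw) == se$smiles_canonical))
  expect_true(all(se$smiles_canonical %in% small$smiles_canonical))
})

test_that("augmentation never leaks into validation or test", {
  sp <- make_sparse_regime(synth_config(n_classes = 4L, per_class = 40L, seed = 13),
                           n_train = 8L, n_val = 5L, n_test = 5L)
  test_like <- rbind(as.data.frame(sp$val), as.data.frame(sp$test))
  aset <- guarded_augment(sp$train, sp$val,
    pool = sp$pool, test_like = test_like,
    config = augment_config(k = 2, tau = 0.5, guard_enabled = FALSE, seed = 3)
  )
  expect_length(intersect(aset$table$smiles_canonical, test_like$smiles_canonical), 0)
})
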