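test_that("metrics match hand arithmetic and behave at the boundaries", {
  # absolute errors (10, 10, 30); SS_res = 100 + 100 + 900 = 1100, SS_tot = 20000
  m <- rt_metrics(c(100, 200, 300), c(110, 190, 330))
  expect_equal(m$mae, 50 / 3)
  expect_equal(m$medae, 10)
  expect_equal(m$mape, (0.1 + 0.05 + 0.1) / 3)
  expect_equal(m$r2, 1 - 1100 / 20000)

  perfect <- rt_metrics(c(10, 20, 30), c(10, 20, 30))
  expect_equal(unclass(perfect)[c("mae", "medae", "mape", "r2")],
               list(mae = 0, medae = 0, mape = 0, r2 = 1))

  shifted <- rt_metrics(c(100, 200, 300), c(105, 205, 305))
  expect_equal(shifted$mae, 5)
  expect_equal(shifted$medae, 5)

  expect_error(rt_metrics(1:3, 1:4), "lengths differ")
  expect_error(rt_metrics(c(5, 5, 5), c(1, 2, 3)), "zero-variance")
  expect_error(rt_metrics(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("a single-entry registry wins by default and the argmin is certified", {
  lib <- fix_lib()
  tab <- classrt:::as_rt_dataset(
    lib$data[lib$data$gen_subclass == lib$data$gen_subclass[1], , drop = FALSE]
  )
  tr <- classrt:::as_rt_dataset(tab[1:24, ])
  va <- classrt:::as_rt_dataset(tab[25:30, ])
  sm <- train_submodel(tr, va, class_id = "one",
                       registry = default_registry("knn"), budget = 2L, seed = 1)
  expect_equal(sm$algorithm, "knn")
  expect_true(all(sm$search_log$algorithm == "knn"))
  expect_lte(sm$val_mae, min(sm$search_log$val_mae))
})

test_that("routing is taxonomy-first with a total similarity fallback", {
  model <- fix_model()
  lib <- fix_lib()
  test_tab <- model$splits$test
  r <- route(test_tab, model)
  expect_equal(nrow(r), nrow(test_tab))
  expect_true(all(r$route_mode %in% c("taxonomy", "similarity_fallback")))
  # synthetic families are perfectly separable: everything routes by taxonomy
  expect_true(all(r$route_mode == "taxonomy"))
  expect_true(all(r$class_id == test_tab$gen_subclass))

  # a molecule from a family with no submodel must fall back by similarity,
  # and the fallback must match a brute-force top-m mean over all submodels
  q <- rt_dataset("q", "CCCCCCCl", rt = NA) # haloalkane: no such submodel
  rq <- route(q, model)
  expect_equal(rq$route_mode, "similarity_fallback")
  fq <- ecfp(q$smiles_canonical)
  scores <- vapply(model$submodels, function(s) {
    sims <- vapply(s$train_fingerprints, function(f) tanimoto(fq, f), numeric(1))
    mean(utils::head(sort(sims, decreasing = TRUE), model$routing$sim_fallback_top_m))
  }, numeric(1))
  expect_equal(rq$class_id, names(which.max(scores)))
})

test_that("prediction preserves row order, conserves rows and flags bad SMILES", {
  model <- fix_model()
  qs <- c("OC(=O)c1ccc(CC)cc1", "broken(((", "Nc1ccc(CCC)cc1")
  p <- predict(model, qs)
  expect_equal(nrow(p), 3)
  expect_equal(p$smiles, qs)
  expect_true(is.na(p$predicted_rt[2]))
  expect_match(p$error[2], "unparseable")
  expect_true(all(!is.na(p$predicted_rt[c(1, 3)])))
  expect_true(all(p$predicted_rt[c(1, 3)] > 0))
})

test_that("prediction is invariant to the SMILES rendering of the query", {
  model <- fix_model()
  p1 <- predict(model, "OC(=O)c1ccc(CCCC)cc1")$predicted_rt
  p2 <- predict(model, "c1cc(CCCC)ccc1C(O)=O")$predicted_rt
  expect_identical(p1, p2)
})

test_that("training is reproducible under a fixed seed", {
  lib <- fix_lib()
  args <- list(
    lib$data,
    aug = augment_config(k = 0L, tau = NA, guard_enabled = FALSE, seed = 2L),
    registry = default_registry("ridge_linear"),
    budget = 1L, min_size = 10L, seed = 2L
  )
  m1 <- do.call(train_ensemble, args)
  m2 <- do.call(train_ensemble, args)
  q <- lib$data$smiles_canonical[1:15]
  expect_identical(predict(m1, q)$predicted_rt, predict(m2, q)$predicted_rt)
  expect_identical(summary(m1), summary(m2))
})

test_that("the ablation harness pairs splits within seed and reports all arms", {
  lib <- fix_lib()
  res <- ablate(lib$data,
    arms = c("none", "se"), seeds = 1:2,
    k = 1L, registry = default_registry("ridge_linear"),
    budget = 1L, min_size = 10L
  )
  expect_s3_class(res, "rt_ablation")
  expect_equal(nrow(res), 4)
  expect_setequal(unique(res$arm), c("none", "se"))
  agg <- attr(res, "summary")
  expect_true(all(is.finite(agg$mean_mae)))
})
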