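test_that("read_dataset parses valid rows, drops and counts bad ones", {
  p <- write_mol_csv(data.frame(
    id = c("a", "b", "c"), smiles = c("CCO", "c1ccccc1", "CC(=O)O"),
    rt = c(300, 400, 500)
  ))
  tab <- read_dataset(p)
  expect_s3_class(tab, "rt_dataset")
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "n_rejected"), 0L)
  expect_true(all(nzchar(tab$smiles_canonical)))

  p2 <- write_mol_csv(data.frame(
    id = c("a", "b", "x"), smiles = c("CCO", "CCN", "not_a_smiles"),
    rt = c(300, 400, 500)
  ))
  tab2 <- read_dataset(p2)
  expect_equal(nrow(tab2), 2)
  expect_equal(attr(tab2, "n_rejected"), 1L)
})

test_that("read_dataset canonicalizes renderings to one form and converts units", {
  p <- write_mol_csv(data.frame(id = "a", smiles = "OCC", rt = 300))
  tab <- read_dataset(p)
  expect_identical(tab$smiles_canonical, canonicalize("CCO"))

  pm <- write_mol_csv(data.frame(id = "a", smiles = "CCO", rt = 5))
  expect_equal(read_dataset(pm, rt_unit = "min")$rt, 300)
})

test_that("read_dataset errors on missing columns and on zero parseable rows", {
  p <- write_mol_csv(data.frame(foo = "CCO", rt = 300))
  expect_error(read_dataset(p), "columns")
  p2 <- write_mol_csv(data.frame(id = "x", smiles = "garbage(", rt = 1))
  expect_error(read_dataset(p2), "no parseable rows")
})

test_that("smi format and dataset round-trip preserve records", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO\tmol1", "c1ccccc1\tmol2"), smi)
  tab <- read_dataset(smi, format = "smi")
  expect_equal(tab$id, c("mol1", "mol2"))

  p <- write_mol_csv(data.frame(id = c("a", "b"), smiles = c("CCO", "CCN"), rt = c(10, 20)))
  tab <- read_dataset(p)
  out <- tempfile(fileext = ".csv")
  write_dataset(tab, out)
  back <- read_dataset(out)
  expect_equal(back$id, tab$id)
  expect_equal(back$smiles_canonical, tab$smiles_canonical)
  expect_equal(back$rt, tab$rt)
})

test_that("canonicalize is idempotent and graph-invariant", {
  cases <- c("OCC", "CC(=O)Oc1ccccc1C(O)=O", "N#Cc1ccccc1")
  can <- canonicalize(cases)
  expect_identical(canonicalize(can), can)
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  # Kekule vs aromatic perception
  expect_identical(canonicalize("C1=CC=CC=C1"), canonicalize("c1ccccc1"))
  expect_error(canonicalize("xx(("), "invalid SMILES")
})

test_that("split_dataset applies floor-then-remainder-to-train sizing", {
  mk <- function(n) rt_dataset(
    id = paste0("m", 1:n), smiles = vapply(1:n, function(i) strrep("C", i), ""),
    rt = 100 + 1:n
  )
  s <- split_dataset(mk(100), seed = 3)
  expect_equal(vapply(s, nrow, integer(1)), c(train = 80L, val = 10L, test = 10L))
  s <- split_dataset(mk(10), seed = 3)
  expect_equal(vapply(s, nrow, integer(1)), c(train = 8L, val = 1L, test = 1L))
  s <- split_dataset(mk(12), seed = 3)
  expect_equal(vapply(s, nrow, integer(1)), c(train = 10L, val = 1L, test = 1L))
  expect_error(split_dataset(mk(2)), "too small")
})

test_that("split is seed-deterministic, seed-sensitive and leak-free", {
  tab <- fix_lib()$data
  s1 <- split_dataset(tab, seed = 7)
  s2 <- split_dataset(tab, seed = 7)
  expect_identical(s1$train$id, s2$train$id)
  expect_identical(s1$test$id, s2$test$id)
  s3 <- split_dataset(tab, seed = 8)
  expect_false(identical(s1$train$id, s3$train$id))
  # disjoint and exhaustive by canonical SMILES
  all_can <- sort(c(s1$train$smiles_canonical, s1$val$smiles_canonical, s1$test$smiles_canonical))
  expect_identical(all_can, sort(tab$smiles_canonical))
  expect_length(intersect(s1$train$smiles_canonical, s1$val$smiles_canonical), 0)
  expect_length(intersect(s1$train$smiles_canonical, s1$test$smiles_canonical), 0)
  # augmented records must not be split
  aug <- tab
  aug$provenance[1] <- "se_augmented"
  expect_error(split_dataset(aug), "original")
})

test_that("model persistence round-trips bit-identically and is version-guarded", {
  model <- fix_model()
  dir <- tempfile("model_")
  save_model(model, dir)
  m2 <- load_model(dir)
  q <- fix_lib()$data$smiles_canonical[1:20]
  expect_identical(predict(model, q)$predicted_rt, predict(m2, q)$predicted_rt)

  expect_error(load_model(tempfile("empty_")), "manifest")

  mf <- file.path(dir, "manifest.json")
  man <- jsonlite::fromJSON(mf)
  man$schema_version <- 99L
  jsonlite::write_json(man, mf, auto_unbox = TRUE)
  expect_error(load_model(dir), "incompatible")
})
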