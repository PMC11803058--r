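test_that("tanimoto matches hand-computed set arithmetic", {
  expect_equal(tanimoto(make_fp(c(1, 2, 3)), make_fp(c(2, 3, 4))), 0.5)
  f <- make_fp(c(10, 20, 30))
  expect_equal(tanimoto(f, f), 1.0)
  expect_equal(tanimoto(make_fp(1:5), make_fp(6:10)), 0.0)
  expect_equal(tanimoto(make_fp(integer(0)), make_fp(integer(0))), 0.0)
  expect_error(tanimoto(make_fp(1, nbits = 1024), make_fp(1, nbits = 2048)), "widths")
})

test_that("similarity_matrix agrees with pairwise tanimoto and both metrics bound in [0,1]", {
  set.seed(11)
  fps <- lapply(1:15, function(i) make_fp(sample(0:255, sample(5:40, 1))))
  S <- similarity_matrix(fps, fps)
  for (i in 1:15) for (j in 1:15) {
    expect_equal(S[i, j], tanimoto(fps[[i]], fps[[j]]), tolerance = 1e-12)
  }
  expect_true(all(S >= 0 & S <= 1))
  Sc <- similarity_matrix(fps, fps, metric = "cosine")
  expect_true(all(diag(Sc) == 1))
  expect_true(all(Sc >= 0 & Sc <= 1))
})

test_that("ecfp is rendering-invariant and discriminates structures", {
  f1 <- ecfp("CCO")
  f2 <- ecfp("OCC")
  expect_identical(f1$on_bits, f2$on_bits)
  expect_true(all(f1$on_bits >= 0 & f1$on_bits < f1$nbits))

  # one heavy atom admits at most environments of radius 0..2 around itself
  fm <- ecfp("C")
  expect_gt(length(fm$on_bits), 0)
  expect_lte(length(fm$on_bits), 3)

  fb <- ecfp("c1ccc2c(c1)cccn2")
  expect_false(identical(f1$on_bits, fb$on_bits))
  expect_error(ecfp("CCO", nbits = 1000), "power of two")
})

test_that("class similarity summary matches a brute-force cross-pair average", {
  tabs <- list(
    alcohols = rt_dataset(c("a1", "a2"), c("CCO", "CCCO"), rt = c(1, 2)),
    acids = rt_dataset(c("b1", "b2"), c("CC(=O)O", "CCC(=O)O"), rt = c(3, 4)),
    arenes = rt_dataset(c("c1", "c2"), c("c1ccccc1", "Cc1ccccc1"), rt = c(5, 6))
  )
  cs <- class_similarity_summary(tabs, seed = 1)
  expect_equal(diag(cs$matrix), c(alcohols = 1, acids = 1, arenes = 1))
  expect_identical(cs$matrix, t(cs$matrix))
  # brute force: mean over the 4 cross pairs, via tanimoto() directly
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    fa <- ecfp(tabs[[pair[1]]]$smiles_canonical)
    fb <- ecfp(tabs[[pair[2]]]$smiles_canonical)
    manual <- mean(c(
      tanimoto(fa[[1]], fb[[1]]), tanimoto(fa[[1]], fb[[2]]),
      tanimoto(fa[[2]], fb[[1]]), tanimoto(fa[[2]], fb[[2]])
    ))
    expect_equal(cs$matrix[pair[1], pair[2]], manual, tolerance = 1e-12)
  }
  expect_setequal(cs$order, 1:3)
  expect_equal(cs$frac_below_half, mean(cs$matrix[upper.tri(cs$matrix)] < 0.5))
  expect_error(class_similarity_summary(tabs[1]), "2 classes")
})

test_that("two classes holding the same molecule have cross-class similarity 1", {
  a <- rt_dataset("x1", "CC(=O)Oc1ccccc1C(O)=O", rt = 1)
  b <- rt_dataset("y1", "OC(=O)c1ccccc1OC(C)=O", rt = 2) # same molecule, other rendering
  cs <- class_similarity_summary(list(a = a, b = b), seed = 1)
  expect_equal(cs$matrix["a", "b"], 1.0)
})
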