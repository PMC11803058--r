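test_that("the shipped rule file compiles with at least 13 superclasses", {
  rs <- default_ruleset()
  expect_s3_class(rs, "rt_ruleset")
  expect_gte(length(unique(rs$rules$superclass)), 13)
  expect_true(nzchar(rs$hash))
})

test_that("rule compilation rejects malformed files", {
  base <- data.frame(
    rule_id = c("a01", "a01"), smarts = c("C(=O)[OX2H1]", "[OX2H]"),
    weight = c(5, 1), superclass = "s", subclass = c("x", "y")
  )
  expect_error(compile_rules(write_rule_tsv(base)), "duplicate rule_id")

  bad <- base
  bad$rule_id <- c("a01", "b02")
  bad$smarts[2] <- "[[[invalid"
  expect_error(compile_rules(write_rule_tsv(bad)), "b02")

  ok <- base
  ok$rule_id <- c("a01", "b02")
  expect_s3_class(compile_rules(write_rule_tsv(ok)), "rt_ruleset")

  neg <- ok
  neg$weight[1] <- -1
  expect_error(compile_rules(write_rule_tsv(neg)), "positive")
})

test_that("assign_class picks the matched rule of maximal weight", {
  rs <- compile_rules(write_rule_tsv(data.frame(
    rule_id = c("acid", "oxy"),
    smarts = c("C(=O)[OX2H1]", "[#8]"),
    weight = c(5, 1),
    superclass = c("acids", "oxygen"),
    subclass = c("carboxylic", "any-oxygen")
  )))
  a <- assign_class("CC(=O)O", rs)
  expect_equal(a$subclass, "carboxylic")
  expect_equal(a$winning_weight, 5)
  expect_equal(a$matched_rule_ids, "acid,oxy")
})

test_that("assign_class falls back on no match and tie-breaks lexicographically", {
  rs <- compile_rules(write_rule_tsv(data.frame(
    rule_id = c("b02", "a01"),
    smarts = c("[OX2H]", "[OX2H]"),
    weight = c(3, 3),
    superclass = c("B", "A"),
    subclass = c("b", "a")
  )))
  # both rules match an alcohol with equal weight: lexicographically first id wins
  a <- assign_class("CCO", rs)
  expect_equal(a$subclass, "a")
  # nothing matches an alkane
  f <- assign_class("CCCC", rs)
  expect_equal(f$superclass, "unclassified")
  expect_equal(f$winning_weight, 0)
})

test_that("assignment is total and run-to-run deterministic", {
  tab <- fix_lib()$data
  a1 <- assign_class(tab)
  a2 <- assign_class(tab)
  expect_identical(a1, a2)
  expect_true(all(nzchar(a1$subclass)))
})

test_that("partition_by_class conserves records and respects min_size", {
  rs <- compile_rules(write_rule_tsv(data.frame(
    rule_id = c("oh", "acid"),
    smarts = c("[OX2H][CX4]", "C(=O)[OX2H1]"),
    weight = c(2, 5),
    superclass = c("alcohols", "acids"),
    subclass = c("alcohols", "acids")
  )))
  # 12 alcohols, 11 acids, 2 unmatched alkanes
  smis <- c(
    paste0(strrep("C", 1:12), "O"),
    paste0("OC(=O)", strrep("C", 1:11)),
    "CCCC", "CCCCC"
  )
  tab <- rt_dataset(paste0("m", seq_along(smis)), smis, rt = 100 + seq_along(smis))
  part <- partition_by_class(tab, rs, min_size = 10L)
  expect_setequal(names(part$classes), c("alcohols", "acids"))
  expect_equal(nrow(part$residual), 2)
  expect_equal(
    sum(vapply(part$classes, nrow, integer(1))) + nrow(part$residual),
    nrow(tab)
  )
  # tighter threshold pushes a class into the residual
  part2 <- partition_by_class(tab, rs, min_size = 12L)
  expect_equal(names(part2$classes), "alcohols")
  expect_equal(nrow(part2$residual), 13)
})
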