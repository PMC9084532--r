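test_that("the bundled demo script parses to two if-blocks over four variants", {
  prog <- parse_script(demo_script_text())
  expect_s3_class(prog, "rule_program")
  expect_length(prog$statements, 2L)
  expect_true(all(vapply(prog$statements, `[[`, character(1), "type") == "if"))
  expect_setequal(prog$referenced_vars,
                  c("rs568149713", "rs557514207", "chr1_16949", "rs553090414"))
  expect_setequal(extract_variables(prog),
                  c("rs568149713", "rs557514207", "chr1:16949", "rs553090414"))
  # condition shapes: and in block 1, or in block 2
  expect_equal(prog$statements[[1]]$cond$type, "and")
  expect_equal(prog$statements[[2]]$cond$type, "or")
})

test_that("demo evaluation returns the documented risk/comment pairs", {
  prog <- parse_script(demo_script_text())
  high <- evaluate_script(prog, demo_store_high())
  expect_equal(high$risk, 0.8)
  expect_equal(high$comment, "highrisk")

  medium <- evaluate_script(prog, demo_store_medium())
  expect_equal(medium$risk, 0.5)
  expect_equal(medium$comment, "mediumrisk")

  none <- evaluate_script(prog, demo_store_none())
  expect_equal(none$risk, 0)
  expect_equal(none$comment, "none")

  # both blocks satisfied: no returns in the script, so the second
  # if-block overwrites the first
  both <- quick_store(rs568149713 = "A/G", rs557514207 = "G/G",
                      `chr1:16949` = "A/C", rs553090414 = "C/C")
  res <- evaluate_script(prog, both)
  expect_equal(res$risk, 0.5)
  expect_equal(res$comment, "mediumrisk")
})

test_that("and binds tighter than or, verified over all truth assignments", {
  src <- 'if rs1 == "A/G" or rs2 == "C/C" and rs3 == "G/G" then risk = 1 end'
  src_tight <- 'if rs1 == "A/G" or (rs2 == "C/C" and rs3 == "G/G") then risk = 1 end'
  src_loose <- 'if (rs1 == "A/G" or rs2 == "C/C") and rs3 == "G/G" then risk = 1 end'
  lits <- c("A/G", "C/C", "G/G")
  distinguishable <- FALSE
  for (bits in asplit(expand.grid(c(TRUE, FALSE), c(TRUE, FALSE),
                                  c(TRUE, FALSE)), 1)) {
    bits <- unlist(bits)
    g <- ifelse(bits, lits, "T/T")
    store <- quick_store(rs1 = g[1], rs2 = g[2], rs3 = g[3])
    got <- evaluate_script(parse_script(src), store)$risk
    tight <- evaluate_script(parse_script(src_tight), store)$risk
    loose <- evaluate_script(parse_script(src_loose), store)$risk
    expect_equal(got, tight)
    if (tight != loose) distinguishable <- TRUE
    # cross-check against R's own parser/evaluator on the same source
    ref <- ref_eval_script(src, store, c("rs1", "rs2", "rs3"))
    expect_equal(got, ref$risk)
  }
  expect_true(distinguishable)
})

test_that("positional identifiers are accepted in colon form and sanitized", {
  prog <- parse_script('if chr1:16949 == "A/C" then risk = 0.3 end')
  expect_equal(prog$referenced_vars, "chr1_16949")
  store <- quick_store(`chr1:16949` = "C/A")
  expect_equal(evaluate_script(prog, store)$risk, 0.3)
})

test_that("top-level genotype bindings are ignored with a warning", {
  src <- paste(
    'rs568149713 = "A/G"',
    'rs557514207 = "G/G"',
    'if rs568149713 == "A/G" and rs557514207 == "G/G" then risk = 0.8 end',
    sep = "\n")
  w <- testthat::capture_warnings(prog <- parse_script(src))
  expect_length(w, 2L)
  expect_match(w, "ignoring top-level", all = TRUE)
  # the binding values do not drive evaluation: the store does
  store <- quick_store(rs568149713 = "T/T", rs557514207 = "T/T")
  expect_equal(evaluate_script(prog, store)$risk, 0)
})

test_that("syntax violations are rejected with located messages", {
  expect_error(parse_script(""), "empty script")
  expect_error(parse_script("   \n \n"), "empty script")
  expect_error(parse_script('if rs1 == "A/G" then risk = 1'), "without matching")
  expect_error(parse_script('foo = 5'), "only `risk` and `comment`")
  expect_error(parse_script('if rs1 == "A/G" then foo = "x" end'),
               "only `risk` and `comment`")
  expect_error(parse_script('return'), "expected")
  expect_error(parse_script('return risk'), "expected")
  expect_error(parse_script('risk = "high"'), "expected number")
  expect_error(parse_script('comment = 5'), "expected string")
  expect_error(parse_script('if rs1 == "TGAT" then risk = 1 end'),
               "invalid genotype literal.*line 1")
  expect_error(parse_script('rs1 == "A/G"'), "not a statement")
  expect_error(parse_script('risk @ 1'), "unexpected character")
  expect_error(parse_script('return risk, comment\nrisk = 1'),
               "must be the last statement")
  expect_error(
    parse_script('if rs1 == "A/G" then return risk, comment risk = 1 end'),
    "must be the last statement")
})

test_that("early return halts execution and defaults survive empty programs", {
  src <- paste(
    'if rs1 == "A/A" then comment = "first" risk = 0.2 return risk, comment end',
    'if rs2 == "C/C" then comment = "second" risk = 0.9 end',
    sep = "\n")
  store <- quick_store(rs1 = "A/A", rs2 = "C/C")
  res <- evaluate_script(parse_script(src), store)
  expect_equal(res$comment, "first")
  expect_equal(res$risk, 0.2)

  # top-level return after assignments
  res2 <- evaluate_script(parse_script("risk = 0.1\nreturn risk, comment"),
                          quick_store(rs1 = "A/A"))
  expect_equal(res2$risk, 0.1)
  expect_equal(res2$comment, "none")
})

test_that("extract_variables deduplicates and handles empty references", {
  prog <- parse_script('if rs7 == "A/A" or rs7 == "C/C" then risk = 1 end')
  expect_equal(extract_variables(prog), "rs7")
  expect_equal(extract_variables(parse_script("risk = 0.5")), character(0))
})

test_that("absent and missing variants condition to FALSE with classed warnings", {
  prog <- parse_script('if rs1 == "A/A" or rs2 == "C/C" then risk = 1 end')
  store <- quick_store(rs2 = "--")
  w <- testthat::capture_warnings(res <- evaluate_script(prog, store))
  expect_equal(res$risk, 0)
  expect_length(w, 2L)
  classes <- character(0)
  withCallingHandlers(
    evaluate_script(prog, store),
    warning = function(w) {
      classes <<- c(classes, class(w)[1])
      invokeRestart("muffleWarning")
    })
  expect_true(all(classes == "genorules_absent_variant"))
  expect_length(classes, 2L)
})

test_that("the engine agrees with R-based reference evaluation on random scripts", {
  set.seed(101)
  pool <- default_key_pool()
  for (i in 1:200) {
    src <- random_script(pool)
    store <- random_genotype_store(pool)
    got <- suppressWarnings(evaluate_script(parse_script(src), store))
    ref <- ref_eval_script(src, store, pool)
    expect_equal(got$risk, ref$risk, info = src)
    expect_equal(got$comment, ref$comment, info = src)
  }
})

test_that("golden scripts agree with the reference interpreter too", {
  pool <- c("rs568149713", "rs557514207", "chr1:16949", "rs553090414")
  for (store in list(demo_store_high(), demo_store_medium(),
                     demo_store_none())) {
    got <- evaluate_script(parse_script(demo_script_text()), store)
    ref <- ref_eval_script(demo_script_text(), store, pool)
    expect_equal(got$risk, ref$risk)
    expect_equal(got$comment, ref$comment)
  }
  # the transpiled fructose rule set
  script <- ruleset_to_script(parse_rule_text(readLines(fructose_path())))
  fr_pool <- c("rs1800546", "rs76917243", "rs78340951")
  for (g in list(c("G/G", "G/G", "G/G"), c("C/G", "C/C", "G/G"),
                 c("C/C", "G/G", "G/G"))) {
    store <- quick_store(rs1800546 = g[1], rs76917243 = g[2],
                         rs78340951 = g[3])
    got <- evaluate_script(parse_script(script), store)
    ref <- ref_eval_script(script, store, fr_pool)
    expect_equal(got$risk, ref$risk)
    expect_equal(got$comment, ref$comment)
  }
})

test_that("every transpiled random rule set parses cleanly", {
  set.seed(33)
  for (i in 1:100) {
    rs <- random_ruleset()
    expect_s3_class(parse_script(ruleset_to_script(rs)), "rule_program")
  }
})

test_that("evaluation is a pure function of program and store", {
  set.seed(55)
  prog <- parse_script(random_script())
  store <- random_genotype_store()
  a <- suppressWarnings(evaluate_script(prog, store))
  b <- suppressWarnings(evaluate_script(prog, store))
  expect_identical(a, b)
})
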