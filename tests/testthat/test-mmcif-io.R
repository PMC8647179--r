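test_that("minimal constructs parse to the expected structure", {
  doc <- parseCif("data_x\n_a.b 1")
  expect_equal(cifBlockNames(doc), "x")
  cat <- getCategory(getBlock(doc, "x"), "a")
  expect_equal(itemNames(cat), "b")
  expect_equal(categoryTable(cat)$b, "1")

  doc <- parseCif("data_x\n_a.b ?\n_a.c .\n_a.d '?'")
  f <- cifFlags(getCategory(getBlock(doc, "x"), "a"))
  expect_equal(unname(f[1, ]), c(1L, 2L, 0L))  # unknown, inapplicable, text "?"

  doc <- parseCif("data_x\nloop_\n_c.p\n_c.q\n1 2\n3 4")
  cat <- getCategory(getBlock(doc, "x"), "c")
  expect_equal(itemNames(cat), c("p", "q"))
  expect_equal(categoryTable(cat), data.frame(p = c("1", "3"), q = c("2", "4")))
})

test_that("semicolon fences preserve multi-line values byte for byte", {
  val <- "line1\nline2  spaced\nline3'\"#"
  doc <- parseCif(paste0("data_y\n_m.v\n;", val, "\n;\n"))
  cat <- getCategory(getBlock(doc, "y"), "m")
  expect_identical(cat@values[1, 1], val)
  expect_true(isTRUE(cifEquals(parseCif(writeCif(doc)), doc)))
})

test_that("comments and case-insensitive keywords are handled", {
  doc <- parseCif("# leading comment\nDATA_x # trailing\n_a.b 1 # after value\nLOOP_\n_c.p\nv1\nv2\n")
  expect_equal(cifBlockNames(doc), "x")
  expect_equal(categoryRowCount(getCategory(getBlock(doc, "x"), "c")), 2L)
})

test_that("syntax errors are reported with line numbers", {
  expect_error(parseCif("data_x\n_a.b 'unterminated\n"), "line 2.*unterminated")
  expect_error(parseCif("data_x\n_m.v\n;open fence\nnever closed"),
               "line 3.*fence")
  expect_error(parseCif("data_x\nloop_\n_c.p\n_c.q\n1 2 3\n"),
               "line 5.*do not fill rows")
  expect_error(parseCif("_a.b 1\n"), "line 1.*outside any data block")
  expect_error(parseCif("data_x\nstray\n"), "line 2.*unexpected value")
  expect_error(parseCif("data_x\n_a.b\n_a.c 1\n"), "missing value")
})

test_that("writer quotes, fences and refuses the unfenceable", {
  doc <- cifDocument(list(cifBlock("b", list(
    cifCategory("t", list(v = "two words"))))))
  expect_match(writeCif(doc), "'two words'", fixed = TRUE)
  expect_identical(writeCif(cifDocument()), "")
  bad <- cifDocument(list(cifBlock("b", list(
    cifCategory("t", list(v = "line1\n;starts with semicolon"))))))
  expect_error(writeCif(bad), "dialect limit")
})

test_that("equality ignores style but respects rows, order and sentinels", {
  a <- parseCif("data_z\n_a.b 'same value'\n")
  b <- parseCif("data_z\n_a.b\n;same value\n;\n")
  expect_true(isTRUE(cifEquals(a, b)))

  a <- parseCif("data_z\n_a.b ?\n")
  b <- parseCif("data_z\n_a.b .\n")
  eq <- cifEquals(a, b)
  expect_false(isTRUE(eq))
  expect_match(attr(eq, "difference"), "block 'z' category 'a' item 'b' row 1")

  a <- parseCif("data_z\nloop_\n_c.p\n1\n2\n")
  b <- parseCif("data_z\nloop_\n_c.p\n2\n1\n")
  expect_false(isTRUE(cifEquals(a, b)))

  ## item and category order are insignificant; block order is not
  a <- parseCif("data_z\n_a.p 1\n_a.q 2\n_b.x 9\n")
  b <- parseCif("data_z\n_b.x 9\n_a.q 2\n_a.p 1\n")
  expect_true(isTRUE(cifEquals(a, b)))
  a <- parseCif("data_z1\n_a.p 1\ndata_z2\n_a.p 1\n")
  b <- parseCif("data_z2\n_a.p 1\ndata_z1\n_a.p 1\n")
  expect_false(isTRUE(cifEquals(a, b)))
})

test_that("random documents round-trip and the writer never emits rejects", {
  for (seed in 1:30) {
    doc <- generateRandomDocument(seed)
    text <- writeCif(doc)
    reparsed <- expect_no_error(parseCif(text))
    eq <- cifEquals(reparsed, doc)
    expect_true(isTRUE(eq), info = paste("seed", seed, attr(eq, "difference")))
    ## parse-write-parse fixpoint
    expect_true(isTRUE(cifEquals(parseCif(writeCif(reparsed)), reparsed)))
  }
})

test_that("tokenizer agrees with an independent character-level oracle", {
  for (seed in 1:50) {
    text <- writeCif(generateRandomDocument(seed + 500))
    mine <- ihmforge:::cifTokenize(text)
    orc <- oracleTokenize(text)
    expect_identical(unlist(mine$text), unlist(orc$text), info = paste("seed", seed))
    expect_identical(unlist(mine$quoted), unlist(orc$quoted))
  }
})
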