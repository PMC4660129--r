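test_that("ICD-10 and ATC codes parse into ordered hierarchy levels", {
  icd <- parse_code("G44.4", "ICD10")
  expect_identical(icd$normalized, "G444")
  expect_identical(icd$levels, c("G", "G4", "G44", "G444"))

  atc <- parse_code("C10AA01", "ATC")
  expect_identical(atc$levels[1], "C")
  expect_identical(atc$levels[4], "C10AA01")

  expect_error(parse_code("", "ICD10"), "empty")
  expect_error(parse_code("1234", "ICD10"), "not a valid")
  expect_error(parse_code("G44.4", "ATC"), "not a valid")
})

test_that("truncation returns level prefixes, nested across levels", {
  code <- parse_code("G444", "ICD10")
  expect_identical(truncate_code(code, 3), "G44")
  expect_identical(truncate_code(code, 1), "G")
  expect_identical(truncate_code(code, 4), "G444")
  expect_error(truncate_code(code, 5), "1..4")
  # short codes truncate to themselves, no padding
  expect_identical(truncate_code(parse_code("G44", "ICD10"), 4), "G44")
  for (raw in c("G444", "A01", "T8080")) {
    c4 <- parse_code(raw, "ICD10")
    for (l in 1:3)
      expect_true(startsWith(truncate_code(c4, l + 1),
                             truncate_code(c4, l)))
  }
})

test_that("similarity is 3-level prefix equality and an equivalence relation", {
  g444 <- parse_code("G444", "ICD10")
  g448 <- parse_code("G448", "ICD10")
  g514 <- parse_code("G514", "ICD10")
  expect_true(is_similar(g444, g448))
  expect_true(is_similar(g444, g444))
  expect_false(is_similar(g444, g514))
  expect_error(is_similar(g444, parse_code("C10AA01", "ATC")),
               "coding system")

  # reflexive, symmetric, transitive over a generated code set
  set.seed(5)
  codes <- lapply(sprintf("%s%d%d%d", sample(c("G", "F", "T"), 20, TRUE),
                          sample(0:9, 20, TRUE), sample(0:4, 20, TRUE),
                          sample(0:9, 20, TRUE)),
                  parse_code, system = "ICD10")
  for (a in codes) expect_true(is_similar(a, a))
  for (a in codes) for (b in codes) {
    expect_identical(is_similar(a, b), is_similar(b, a))
  }
  for (a in codes) for (b in codes) for (cc in codes) {
    if (is_similar(a, b) && is_similar(b, cc))
      expect_true(is_similar(a, cc))
  }
})

test_that("level expansion yields one tagged feature name per level", {
  code <- parse_code("G444", "ICD10")
  expect_identical(expand_levels(code),
                   c("code:ICD10:L1:G", "code:ICD10:L2:G4",
                     "code:ICD10:L3:G44", "code:ICD10:L4:G444"))
  expect_identical(expand_levels(code, 4), "code:ICD10:L4:G444")
  for (lv in list(1, c(1, 3), 1:4, c(2, 4)))
    expect_length(expand_levels(code, lv), length(lv))
  expect_error(expand_levels(code, integer()), "non-empty")
})

test_that("the packaged ADE code list is complete and parseable", {
  tab <- ade_target_codes()
  expect_identical(nrow(tab), 27L)
  expect_false(anyDuplicated(tab$code) > 0)
  for (code in tab$code)
    expect_s3_class(parse_code(code, "ICD10"), "clinical_code")
  expect_identical(tab$description[tab$code == "G444"],
                   "Drug-induced headache, not elsewhere classified")
})
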