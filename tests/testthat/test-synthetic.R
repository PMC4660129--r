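test_that("vocabulary size is the product of the branching factors", {
  spec <- synthetic_spec(diag_branching = c(5L, 5L, 5L, 5L),
                         drug_branching = c(2L, 3L, 2L, 2L))
  vocab <- generate_vocabulary(spec)
  expect_length(vocab$diagnosis, 625)
  expect_length(vocab$drug, 24)
  # closure: every generated code parses under the hierarchy module
  for (code in sample(vocab$diagnosis, 20))
    expect_s3_class(parse_code(code, "ICD10"), "clinical_code")
  for (code in sample(vocab$drug, 10))
    expect_s3_class(parse_code(code, "ATC"), "clinical_code")
  # target and designated sibling are similar by construction
  expect_true(is_similar(parse_code(vocab$target_code, "ICD10"),
                         parse_code(vocab$sibling_code, "ICD10")))
  expect_false(vocab$target_code == vocab$sibling_code)
})

test_that("generation is reproducible and prevalence is binomial", {
  spec <- synthetic_spec(n_patients = 200L, prevalence = 0.3,
                         background_rate = 5)
  a <- generate_cohort(spec, seed = 5)
  b <- generate_cohort(spec, seed = 5)
  expect_identical(as.data.frame(a$log), as.data.frame(b$log))
  d <- generate_cohort(spec, seed = 6)
  expect_false(identical(as.data.frame(a$log), as.data.frame(d$log)))

  # realized positives within the central 99% binomial interval around 60
  n_pos <- sum(a$truth$label)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.3)
  expect_gte(n_pos, bounds[1])
  expect_lte(n_pos, bounds[2])
})

test_that("planted signals reference existing features or fail loudly", {
  spec <- synthetic_spec(signal = list(list(feature = "NOPE",
                                            channel = "count",
                                            effect = 2)))
  expect_error(generate_cohort(spec, 1), "absent feature")
  expect_error(synthetic_spec(signal = list(list(feature = "X",
                                                 channel = "weird",
                                                 effect = 1))))
  expect_error(synthetic_spec(prevalence = 0.01), "0.025")
})

test_that("a zero-signal dataset carries no informative features", {
  spec <- synthetic_spec(n_patients = 250L, prevalence = 0.3,
                         background_rate = 10)
  ds <- generate_cohort(spec, seed = 17)
  cohort <- build_cohort(ds$log, ds$vocabulary$target_code)
  x <- build_features(prior_events(ds$log, cohort), cohort)
  rk <- rank_features(x)
  # all gains stay far below the class entropy - pure sampling noise
  expect_lt(max(rk$gain_bits), 0.25 * attr(rk, "class_entropy"))
  expect_identical(nrow(ds$truth$planted), 0L)
})

test_that("duplicate rows are injected and preserved end to end", {
  spec <- synthetic_spec(n_patients = 80L, duplicate_prob = 0.1)
  ds <- generate_cohort(spec, seed = 23)
  df <- as.data.frame(ds$log)
  expect_gt(nrow(df) - nrow(unique(df)), 0)
})

test_that("dataset collections are independent and track their specs", {
  specs <- list(synthetic_spec(n_patients = 60L, prevalence = 0.3),
                synthetic_spec(n_patients = 80L, prevalence = 0.5))
  coll <- dataset_collection(specs, base_seed = 31)
  expect_length(coll, 2)
  expect_false(identical(as.data.frame(coll[[1]]$log),
                         as.data.frame(coll[[2]]$log)))
  for (i in 1:2) {
    n <- specs[[i]]$n_patients
    p <- specs[[i]]$prevalence
    n_pos <- sum(coll[[i]]$truth$label)
    expect_gte(n_pos, qbinom(0.005, n, p))
    expect_lte(n_pos, qbinom(0.995, n, p))
  }
  expect_error(dataset_collection(specs[1]), "2")
})

test_that("planted features map to their representation columns", {
  ds <- generate_cohort(planted_signal_spec(n_patients = 100L), seed = 3)
  expect_setequal(planted_feature_names(ds),
                  c("code:ATC:L4:A00A00", "meas:mean:meas01"))
})
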