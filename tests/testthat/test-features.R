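test_that("measurement summaries match direct arithmetic", {
  s <- summarize_measurement(c(0, 2), c(10, 14))
  expect_equal(s[["mean"]], 12)
  expect_equal(s[["sd"]], sqrt(8), tolerance = 1e-12)  # 2.8284
  expect_equal(s[["slope"]], 2)
  expect_equal(s[["existence"]], 1)
  expect_equal(s[["count"]], 2)

  single <- summarize_measurement(1, 7)
  expect_equal(unname(single), c(7, 0, 0, 1, 1))

  empty <- summarize_measurement(numeric(), numeric())
  expect_equal(empty[["existence"]], 0)
  expect_equal(empty[["count"]], 0)
  expect_equal(empty[["mean"]], 0)  # default zero imputation

  # zero time span and the pure-difference variant
  expect_equal(summarize_measurement(c(3, 3), c(1, 9))[["slope"]], 0)
  expect_equal(summarize_measurement(c(0, 4), c(1, 9),
                                     slope_mode = "difference")[["slope"]],
               8)
})

test_that("summaries are order-invariant; slope uses temporal endpoints", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    t <- runif(n, 0, 30); v <- rnorm(n, 50, 5)
    perm <- sample(n)
    expect_equal(summarize_measurement(t, v),
                 summarize_measurement(t[perm], v[perm]),
                 tolerance = 1e-12)
    s <- summarize_measurement(t, v)
    o <- order(t)
    expect_equal(s[["slope"]],
                 (v[o][n] - v[o][1]) / (t[o][n] - t[o][1]),
                 tolerance = 1e-12)
  }
})

make_small_dataset <- function(seed = 3L) {
  spec <- synthetic_spec(n_patients = 60L, prevalence = 0.3,
                         background_rate = 10, n_measurements = 4L)
  ds <- generate_cohort(spec, seed = seed)
  cohort <- build_cohort(ds$log, ds$vocabulary$target_code)
  list(pre = prior_events(ds$log, cohort), cohort = cohort)
}

test_that("feature matrices satisfy the representation invariants", {
  d <- make_small_dataset()
  x <- build_features(d$pre, d$cohort)
  fi <- attr(x, "feature_info")
  expect_false(anyDuplicated(colnames(x)) > 0)
  expect_identical(nrow(x), nrow(d$cohort))

  cnt <- x[, fi$name[fi$representation == "count" &
                       fi$data_type == "measurement"], drop = FALSE]
  ex <- x[, fi$name[fi$representation == "existence"], drop = FALSE]
  sdv <- x[, fi$name[fi$representation == "sd"], drop = FALSE]
  expect_true(all(cnt == round(cnt) & cnt >= 0))
  expect_true(all(ex %in% c(0, 1)))
  expect_true(all(cnt >= ex))
  expect_true(all((ex == 1) == (cnt >= 1)))
  expect_true(all(sdv[cnt < 2] == 0))

  # hierarchy aggregation: the level-L count of a prefix equals the sum
  # of the level-(L+1) counts of its children
  code_cols <- fi$name[fi$data_type == "code"]
  parents <- code_cols[grepl(":L[123]:", code_cols)]
  for (col in sample(parents, min(10, length(parents)))) {
    lv <- as.integer(sub("^.*:L(\\d):.*$", "\\1", col))
    prefix <- sub("^.*:L\\d:", "", col)
    system <- sub("^code:([^:]+):.*$", "\\1", col)
    children <- code_cols[grepl(sprintf(":L%d:", lv + 1), code_cols) &
                            startsWith(sub("^.*:L\\d:", "", code_cols),
                                       prefix) &
                            grepl(paste0("^code:", system), code_cols)]
    expect_equal(x[, col], rowSums(x[, children, drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("feature universe size follows the counting rule", {
  d <- make_small_dataset()
  x <- build_features(d$pre, d$cohort)
  fi <- attr(x, "feature_info")
  meas_names <- unique(d$pre$measurement_name[d$pre$kind == "measurement"])
  expect_identical(sum(fi$data_type == "measurement"),
                   5L * length(meas_names))
  # per level: one column per distinct prefix present in the log
  codes <- d$pre[d$pre$kind %in% c("diagnosis", "drug"), ]
  for (lv in 1:4) {
    expected <- length(unique(vapply(seq_len(nrow(codes)), function(i) {
      sys <- if (codes$kind[i] == "diagnosis") "ICD10" else "ATC"
      paste0(sys, ":", truncate_code(parse_code(codes$code[i], sys), lv))
    }, character(1))))
    expect_identical(sum(fi$data_type == "code" & fi$level == lv),
                     expected)
  }
})

test_that("code multiplicity lands in the count representation at every level", {
  log <- event_log(patient_id = c("P1", "P1", "P1", "P2"),
                   timestamp = c(1, 2, 10, 0.5),
                   kind = c("drug", "drug", "diagnosis", "diagnosis"),
                   code = c("C10AA01", "C10AA01", "G444", "G440"))
  cohort <- build_cohort(log, "G444")
  pre <- prior_events(log, cohort)
  x <- build_features(pre, cohort,
                      representation_config(measurement_reps = character()))
  expect_equal(x["P1", "code:ATC:L1:C"], 2, ignore_attr = TRUE)
  expect_equal(x["P1", "code:ATC:L4:C10AA01"], 2, ignore_attr = TRUE)
  xb <- build_features(pre, cohort,
                       representation_config(measurement_reps = character(),
                                             code_value = "existence"))
  expect_equal(xb["P1", "code:ATC:L4:C10AA01"], 1, ignore_attr = TRUE)
})

test_that("fusion concatenates aligned matrices and rejects misaligned ones", {
  d <- make_small_dataset()
  x <- build_features(d$pre, d$cohort)
  M <- data_type_matrix(x, "measurement")
  C <- data_type_matrix(x, "code")
  fused <- fuse(M, C)
  expect_identical(ncol(fused), ncol(M) + ncol(C))
  expect_identical(attr(fused, "labels"), attr(M, "labels"))
  expect_identical(attr(fused, "labels"), attr(C, "labels"))
  expect_identical(fuse(M, select_features(C, character()))[, ], M[, ])

  other <- make_small_dataset(seed = 4L)
  y <- build_features(other$pre, other$cohort)
  expect_error(fuse(M, data_type_matrix(y, "code")), "aligned")
})

test_that("feature matrices round-trip through the sparse triplet format", {
  d <- make_small_dataset()
  x <- build_features(d$pre, d$cohort)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(x, path)
  back <- read_feature_matrix(path)
  expect_equal(unclass(back)[, ], unclass(x)[, ], tolerance = 1e-12)
  expect_identical(attr(back, "labels"), attr(x, "labels"))
  expect_identical(attr(back, "feature_info")$name,
                   attr(x, "feature_info")$name)
})
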