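test_that("manifest reading groups slides by patient and sorts cancer labels", {
  df <- data.frame(
    patient_id = c("p1", "p1", "p2"),
    slide_id = c("s1", "s2", "s3"),
    cancer_type = c("BRCA", "BRCA", "BLCA"),
    age = c(60, 60, 70), sex = c("female", "female", "male"),
    stage = c("II", "II", NA),
    time = c(24, 24, 10), event = c(1, 1, 0))
  cohort <- read_manifest(write_manifest_file(df))
  expect_length(cohort$patients, 2L)
  expect_length(cohort$patients[[1L]]$bags, 2L)
  expect_equal(cohort$cancer_levels, c("BLCA", "BRCA"))
  # sorted-label convention: BLCA first
  expect_equal(cohort$patients[[2L]]$cancer$index, 1L)
  expect_equal(cohort$patients[[1L]]$cancer$index, 2L)
  expect_equal(cohort$patients[[1L]]$cancer$onehot, c(0, 1))
})

test_that("manifest validation raises classed errors", {
  base <- data.frame(patient_id = "p1", slide_id = "s1", cancer_type = "BLCA",
                     time = 10, event = 1)
  noc <- base[, setdiff(names(base), "cancer_type")]
  expect_error(read_manifest(write_manifest_file(noc)),
               class = "pcm_schema_error", regexp = "cancer_type")
  dup <- rbind(base, base)
  expect_error(read_manifest(write_manifest_file(dup)),
               class = "pcm_integrity_error")
  bad <- base; bad$time <- 0
  expect_error(read_manifest(write_manifest_file(bad)),
               class = "pcm_validation_error", regexp = "row")
})

test_that("clinical encoding follows the fixed 8-slot layout", {
  enc <- encode_clinical(60, "female", "II")
  expect_equal(enc$values, c(0.60, 1, 0, 0, 1, 0, 0, 0))
  expect_equal(sum(enc$missing_mask), 0L)

  # stage-missing must be representable (no-staging cancers such as LGG)
  enc2 <- encode_clinical(70, "male", NA)
  expect_equal(enc2$values[4:7], rep(0, 4))
  expect_equal(enc2$values[8], 1)

  enc3 <- encode_clinical(NA, NA, NA)
  expect_equal(enc3$values, c(0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(enc3$missing_mask[1:3], c(1L, 1L, 1L))

  expect_error(encode_clinical(60, "female", "V"), class = "pcm_validation_error")
  expect_error(encode_clinical(60, "unknown", "II"), class = "pcm_validation_error")
})

test_that("clinical encoding is total and always length 8", {
  ages <- list(NA, 20, 95.5, "55")
  sexes <- list(NA, "male", "Female", "M")
  stages <- list(NA, "I", "iv", "Stage III", "2")
  for (a in ages) for (s in sexes) for (st in stages) {
    enc <- encode_clinical(a, s, st)
    expect_length(enc$values, 8L)
    expect_length(enc$missing_mask, 8L)
    expect_true(all(is.finite(enc$values)))
    expect_identical(enc$values, encode_clinical(a, s, st)$values)
  }
})

test_that("bag container round trip is bit-identical", {
  set.seed(42)
  bag <- feature_bag(matrix(rnorm(5 * 16), 5, 16),
                     cbind(0:4 * 224L, 0L), "slideA",
                     patch_size_px = 224L, magnification = "10x",
                     encoder_name = "stub")
  path <- tempfile(fileext = ".bag")
  write_bag(bag, path)
  back <- read_bag(path)
  expect_identical(back$features, bag$features)
  expect_identical(back$coords, bag$coords)
  expect_identical(back$slide_id, bag$slide_id)
  expect_identical(back$patch_size_px, bag$patch_size_px)
  expect_identical(back$magnification, bag$magnification)
  expect_identical(back$encoder_name, bag$encoder_name)
})

test_that("bag container read errors are classed and informative", {
  expect_error(read_bag(tempfile()), class = "pcm_format_error")
  junk <- tempfile()
  writeBin(charToRaw("NOTABAG!"), junk)
  expect_error(read_bag(junk), class = "pcm_format_error")

  # container whose header lacks the coords dataset
  nocoords <- tempfile()
  con <- file(nocoords, "wb")
  writeBin(charToRaw("PCMBAG1\n"), con)
  hdr <- charToRaw('{"schema_version":1,"slide_id":"x","n":1,"d":2,"datasets":["features"]}')
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(hdr, con)
  writeBin(c(0.5, 0.5), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_bag(nocoords), class = "pcm_format_error", regexp = "coords")

  # truncated payload
  good <- tempfile()
  write_bag(feature_bag(matrix(1:8, 4, 2), cbind(0:3, 0L), "s"), good)
  raw_all <- readBin(good, "raw", file.size(good))
  trunc <- tempfile()
  writeBin(raw_all[1:(length(raw_all) - 8L)], trunc)
  expect_error(read_bag(trunc), class = "pcm_format_error", regexp = "truncated")
})

test_that("cohort-level feature dimension is enforced on load", {
  d16 <- feature_bag(matrix(rnorm(3 * 16), 3, 16), cbind(0:2, 0L), "a")
  d32 <- feature_bag(matrix(rnorm(3 * 32), 3, 32), cbind(0:2, 0L), "b")
  p16 <- tempfile(fileext = ".bag"); write_bag(d16, p16)
  expect_error(read_bag(p16, expected_dim = 32L), class = "pcm_dimension_error")

  dir <- tempfile(); dir.create(dir)
  write_bag(d16, file.path(dir, "a.bag"))
  write_bag(d32, file.path(dir, "b.bag"))
  df <- data.frame(patient_id = c("p1", "p2"), slide_id = c("a", "b"),
                   cancer_type = "BLCA", time = c(5, 6), event = c(1, 0))
  skel <- cohort_from_manifest(df)
  expect_error(load_cohort_bags(skel, dir), class = "pcm_dimension_error")
})

test_that("patient bag pooling concatenates in order with bijective provenance", {
  b1 <- feature_bag(matrix(1:12, 3, 4), cbind(c(0L, 224L, 448L), 0L), "s1")
  b2 <- feature_bag(matrix(13:20, 2, 4), cbind(c(0L, 224L), 224L), "s2")
  rec <- patient_record("p1", list(b1, b2), encode_clinical(),
                        cancer_type_code("BLCA", "BLCA"), survival_label(5, 1))
  pooled <- pool_patient_bag(rec)
  expect_equal(nrow(pooled$features), 5L)
  expect_identical(pooled$features[1:3, ], b1$features)
  expect_identical(pooled$features[4:5, ], b2$features)
  expect_equal(pooled$provenance$slide_id, c(rep("s1", 3), rep("s2", 2)))
  # bijection between merged rows and (slide, row) pairs
  key <- paste(pooled$provenance$slide_id, pooled$provenance$slide_row)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(nrow(pooled$provenance), nrow(pooled$features))

  single <- pool_patient_bag(
    patient_record("p2", list(b1), encode_clinical(),
                   cancer_type_code("BLCA", "BLCA"), survival_label(5, 1)))
  expect_identical(single$features, b1$features)

  expect_error(patient_record("p3", list(), encode_clinical(),
                              cancer_type_code("BLCA", "BLCA"),
                              survival_label(5, 1)),
               class = "pcm_validation_error")
})

test_that("manifest -> cohort -> manifest round trip preserves labels", {
  sim <- tiny_sim(K = 2L, n_per_type = 6L, seed = 9L)
  m1 <- sim$manifest
  cohort2 <- cohort_from_manifest(m1)
  m2 <- as_manifest(cohort2)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(sort(m2$slide_id), sort(m1$slide_id))
  ord <- match(m1$patient_id, m2$patient_id)
  expect_equal(m2$time[ord], m1$time)
  expect_equal(m2$event[ord], m1$event)
  expect_equal(m2$cancer_type[ord], m1$cancer_type)
})

test_that("survival labels and cancer codes enforce their invariants", {
  expect_error(survival_label(0, 1), class = "pcm_validation_error")
  expect_error(survival_label(5, 2), class = "pcm_validation_error")
  expect_error(survival_label(5, 1, "XX"))
  code <- cancer_type_code("BRCA", c("LUAD", "BRCA", "BLCA"))
  expect_equal(code$levels, c("BLCA", "BRCA", "LUAD"))
  expect_equal(code$onehot[code$index], 1)
  expect_equal(sum(code$onehot), 1)
  expect_error(cancer_type_code("XXXX", c("BLCA")), class = "pcm_validation_error")
})
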