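test_that("border and adaptor are located and extended to the read ends", {
  design <- small_design(7)
  withr::local_seed(21)
  seg <- random_dna(60)
  read <- paste0(design$border, seg, design$adaptor)
  rec <- qual_seq_record("fst", read)
  opt <- optional_seq_set(border = design$border, adaptor = design$adaptor,
                          vector = design$vector)
  mk <- annotate_optional_sequences(rec, opt)
  roles <- vapply(mk$intervals, `[[`, "", "role")
  expect_setequal(roles, c("border", "adaptor"))
  b <- mk$intervals[[which(roles == "border")]]$interval
  a <- mk$intervals[[which(roles == "adaptor")]]$interval
  expect_equal(b, c(0, 25))
  expect_equal(a, c(85, 105))
})

test_that("a read with no construct similarity gets an empty annotation", {
  design <- small_design(7)
  withr::local_seed(22)
  rec <- qual_seq_record("fst", random_dna(80))
  opt <- optional_seq_set(border = design$border, adaptor = design$adaptor,
                          vector = design$vector)
  expect_length(annotate_optional_sequences(rec, opt)$intervals, 0L)
})

test_that("a pure vector read is masked across at least 90% of its length", {
  design <- small_design(7)
  rec <- qual_seq_record("v", substring(design$vector, 501, 650))
  opt <- optional_seq_set(vector = design$vector)
  mk <- annotate_optional_sequences(rec, opt)
  roles <- vapply(mk$intervals, `[[`, "", "role")
  expect_true("vector" %in% roles)
  iv <- mk$intervals[[which(roles == "vector")[1]]]
  expect_gte(iv$interval[2] - iv$interval[1], 0.9 * 150)
  expect_lte(iv$hit$evalue, 1e-10)
})

test_that("classification applies the LOW/VECTOR/NA/A priority", {
  design <- small_design(7)
  withr::local_seed(23)
  opt <- optional_seq_set(border = design$border, adaptor = design$adaptor,
                          vector = design$vector)
  classify_read <- function(seq, quals = NULL, msl = 30) {
    rec <- qual_seq_record("r", seq, quals)
    tr <- trim_by_quality(rec)
    mk <- annotate_optional_sequences(tr$record, opt)
    classify(rec, tr, mk, msl = msl)
  }
  # 50-bp clean genomic run -> A
  a <- classify_read(paste0(design$border, random_dna(50), design$adaptor))
  expect_equal(a$category, "A")
  expect_equal(a$insert_length, 50)
  expect_equal(a$border_end, 25)
  expect_equal(a$adaptor_start, 76)
  # 12-bp run -> NA
  na <- classify_read(paste0(design$border, random_dna(12), design$adaptor))
  expect_equal(na$category, "NA")
  expect_equal(na$insert_length, 12)
  # all-bad qualities -> LOW (post-trim length 0)
  low <- classify_read(random_dna(80), quals = rep(2L, 80))
  expect_equal(low$category, "LOW")
  # vector covering the whole insert -> VECTOR
  vec <- classify_read(paste0(design$border,
                              substring(design$vector, 101, 220),
                              design$adaptor))
  expect_equal(vec$category, "VECTOR")
})

test_that("raising the MSL never promotes a read and A implies insert >= MSL", {
  design <- small_design(7)
  withr::local_seed(24)
  opt <- optional_seq_set(border = design$border, adaptor = design$adaptor)
  for (i in 1:20) {
    seg <- random_dna(sample(10:60, 1))
    rec <- qual_seq_record("r", paste0(design$border, seg, design$adaptor))
    tr <- trim_by_quality(rec)
    mk <- annotate_optional_sequences(tr$record, opt)
    c30 <- classify(rec, tr, mk, msl = 30)
    c45 <- classify(rec, tr, mk, msl = 45)
    if (c30$category == "NA") expect_true(c45$category %in% c("NA", "LOW"))
    if (c30$category == "A") expect_gte(c30$insert_length, 30)
    expect_false(c30$category == "NA" && c45$category == "A")
  }
})

test_that("validate_batch partitions a designed batch into the planted categories", {
  design <- small_design(7)
  withr::local_seed(25)
  opt <- optional_seq_set(border = design$border, adaptor = design$adaptor,
                          vector = design$vector)
  reads <- c(
    lapply(1:6, function(i)
      qual_seq_record(paste0("clean", i),
                      paste0(design$border, random_dna(60), design$adaptor))),
    lapply(1:2, function(i)
      qual_seq_record(paste0("short", i),
                      paste0(design$border, random_dna(15), design$adaptor))),
    list(qual_seq_record("vec", paste0(design$border,
                                       substring(design$vector, 1000, 1120),
                                       design$adaptor))),
    list(qual_seq_record("low", random_dna(70), rep(3L, 70))))
  res <- validate_batch(reads, opt)
  counts <- setNames(res$summary$count, res$summary$category)
  expect_equal(counts[["A"]], 6)
  expect_equal(counts[["NA"]], 2)
  expect_equal(counts[["VECTOR"]], 1)
  expect_equal(counts[["LOW"]], 1)
  expect_equal(counts[["Total"]], 10)
  expect_equal(sum(res$summary$count[res$summary$category != "Total"]),
               length(reads))
  expect_equal(nrow(res$per_fst), length(reads))
})

test_that("without optional sequences no VECTOR call is possible", {
  withr::local_seed(26)
  reads <- lapply(1:5, function(i)
    qual_seq_record(paste0("r", i), random_dna(40 + i)))
  res <- validate_batch(reads, optional_seq_set())
  expect_true(all(res$per_fst$category == "A"))
  expect_equal(vapply(res$masked, `[[`, 0, "insert_length"), 41:45)
})
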