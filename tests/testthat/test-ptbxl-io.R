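# WFDB reading, metadata parsing, SCP label mapping and fold splits.

test_that("WFDB round trip preserves signals to the amplitude resolution", {
  dir <- withr::local_tempdir()
  set.seed(1)
  for (fs in c(100, 500)) {
    sig <- matrix(rnorm(10 * fs * 12, sd = 0.5), ncol = 12)
    write_wfdb_record(sig, paste0("rec", fs), dir, fs = fs)
    r <- read_wfdb_record(file.path(dir, paste0("rec", fs)))
    expect_equal(dim(r$signal), c(10 * fs, 12))
    expect_equal(r$fs, fs)
    # 16-bit quantization at gain 1000 ADC units/mV
    expect_lte(max(abs(r$signal - sig)), 0.5 / 1000)
  }
})

test_that("read_record enforces 12 leads, 10 s length and sampling rate", {
  dir <- withr::local_tempdir()
  write_wfdb_record(matrix(0, 1000, 12), "ok", dir, fs = 100)
  rec <- read_record(file.path(dir, "ok"), fs = 100)
  expect_s3_class(rec, "ecg_record")
  expect_identical(dim(rec$signal), c(1000L, 12L))

  write_wfdb_record(matrix(0, 1000, 3), "three", dir, fs = 100)
  expect_error(read_record(file.path(dir, "three"), fs = 100), "12 leads")

  expect_error(read_record(file.path(dir, "ok"), fs = 500), "mismatch")
  expect_error(read_record(file.path(dir, "absent"), fs = 100), "not found")

  # truncate the signal file behind the header's back
  write_wfdb_record(matrix(0, 1000, 12), "trunc", dir, fs = 100)
  dat <- file.path(dir, "trunc.dat")
  raw <- readBin(dat, "raw", file.size(dat))
  writeBin(raw[seq_len(length(raw) - 100L)], dat)
  expect_error(read_record(file.path(dir, "trunc"), fs = 100), "truncated")
})

test_that("metadata loading parses scp_codes and drops malformed rows", {
  dir <- withr::local_tempdir()
  corp <- tiny_binary_corpus(n = 20, seed = 5)
  write_wfdb_fixture(corp, dir)

  meta <- load_metadata(file.path(dir, "ptbxl_database.csv"),
                        file.path(dir, "scp_statements.csv"))
  expect_equal(nrow(meta), 20)
  expect_equal(attr(meta, "n_dropped"), 0)
  expect_type(meta$scp_codes, "list")
  expect_true(all(vapply(meta$scp_codes, is.numeric, logical(1))))

  # corrupt one row's scp_codes
  db <- read.csv(file.path(dir, "ptbxl_database.csv"), stringsAsFactors = FALSE)
  db$scp_codes[3] <- "not a dict"
  write.csv(db, file.path(dir, "ptbxl_database.csv"), row.names = FALSE)
  expect_message(
    meta2 <- load_metadata(file.path(dir, "ptbxl_database.csv"),
                           file.path(dir, "scp_statements.csv")),
    "1 record\\(s\\) dropped")
  expect_equal(nrow(meta2), 19)
  expect_equal(attr(meta2, "n_dropped"), 1)

  # schema error when the statement table lacks the diagnostic class
  scp <- read.csv(file.path(dir, "scp_statements.csv"), stringsAsFactors = FALSE)
  scp$diagnostic_class <- NULL
  write.csv(scp, file.path(dir, "scp_statements.csv"), row.names = FALSE)
  expect_error(load_metadata(file.path(dir, "ptbxl_database.csv"),
                             file.path(dir, "scp_statements.csv")),
               "diagnostic_class")
})

test_that("SCP codes map onto the taxonomy with single-label resolution", {
  expect_identical(map_scp_to_label(c(IMI = 100)),
                   list(status = "ok", superclass = "MI", subclass = "IMI"))
  expect_identical(map_scp_to_label(c(NORM = 100)),
                   list(status = "ok", superclass = "NORM", subclass = "NORM"))
  expect_identical(map_scp_to_label(setNames(numeric(0), character(0)))$status,
                   "unlabeled")
  expect_identical(map_scp_to_label(c(IMI = 100, CLBBB = 100))$status,
                   "ambiguous")
  # below-threshold codes are not retained
  expect_identical(map_scp_to_label(c(IMI = 100, CLBBB = 50))$superclass, "MI")
  expect_identical(map_scp_to_label(c(IMI = 60), min_likelihood = 50)$superclass,
                   "MI")
  # non-diagnostic statements (absent from the taxonomy) are ignored
  expect_identical(map_scp_to_label(c(IMI = 100, SR = 100))$superclass, "MI")
  # two codes sharing a superclass but not a subclass: superclass label only
  res <- map_scp_to_label(c(AMI = 100, IMI = 100))
  expect_identical(res$status, "ok")
  expect_identical(res$superclass, "MI")
  expect_true(is.na(res$subclass))
  # LAFB and LPFB pool into one subclass
  expect_identical(map_scp_to_label(c(LAFB = 100))$subclass, "LAFB/LPFB")
})

test_that("taxonomy closure: every subclass sits under its one superclass", {
  tax <- ptbxl_taxonomy()
  expect_setequal(unique(tax$superclass), ECG_SUPERCLASSES)
  expect_equal(length(unique(tax$subclass)), 23)
  # a subclass never appears under two superclasses
  expect_true(all(tapply(tax$superclass, tax$subclass,
                         function(s) length(unique(s))) == 1))
})

test_that("folds map to partitions as 1-8 train, 9 validation, 10 test", {
  expect_identical(as.character(assign_split(3)), "train")
  expect_identical(as.character(assign_split(9)), "validation")
  expect_identical(as.character(assign_split(10)), "test")
  expect_identical(as.character(assign_split(1:10)),
                   c(rep("train", 8), "validation", "test"))
  expect_error(assign_split(11), "1..10")
  expect_error(assign_split(0), "1..10")
})

test_that("corpus loading excludes ambiguous/unlabeled records and round-trips metadata", {
  dir <- withr::local_tempdir()
  corp <- tiny_binary_corpus(n = 15, seed = 9)
  write_wfdb_fixture(corp, dir)
  # add one ambiguous and one unlabeled row pointing at an existing waveform
  db <- read.csv(file.path(dir, "ptbxl_database.csv"), stringsAsFactors = FALSE)
  amb <- db[1, ]; amb$ecg_id <- "90001"; amb$scp_codes <- "{'IMI': 100.0, 'CLBBB': 100.0}"
  unl <- db[1, ]; unl$ecg_id <- "90002"; unl$scp_codes <- "{'IMI': 40.0}"
  write.csv(rbind(db, amb, unl), file.path(dir, "ptbxl_database.csv"),
            row.names = FALSE)

  expect_message(loaded <- load_corpus(dir, fs = 100),
                 "1 ambiguous and 1 unlabeled")
  expect_equal(length(loaded$records), 15)
  expect_identical(loaded$labels$superclass, corp$labels$superclass)
  expect_identical(loaded$labels$fold, corp$labels$fold)
  expect_identical(loaded$labels$sex, corp$labels$sex)
  # scp_codes maps survive the round trip
  expect_identical(lapply(loaded$records, `[[`, "scp_codes"),
                   lapply(corp$records, `[[`, "scp_codes"))
  # signals agree to the WFDB quantization bound
  dmax <- max(vapply(seq_len(15), function(i) {
    max(abs(loaded$records[[i]]$signal - corp$records[[i]]$signal))
  }, numeric(1)))
  expect_lte(dmax, 0.5 / 1000)
})
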