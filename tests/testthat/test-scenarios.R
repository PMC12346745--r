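# Scenario construction and materialization.

test_that("binary superclass scenarios include NORM plus one disease", {
  sc <- binary_superclass("MI")
  expect_identical(sc$class_names, c("NORM", "MI"))
  expect_identical(scenario_index(sc, "MI", "IMI"), 1L)
  expect_identical(scenario_index(sc, "NORM", "NORM"), 0L)
  expect_true(is.na(scenario_index(sc, "STTC", "ISCA")))  # excluded
  expect_error(binary_superclass("XYZ"), "must be one of")
  expect_error(binary_superclass("NORM"), "must be one of")
})

test_that("binary subclass scenarios operate at subclass granularity", {
  sc <- binary_subclass("CRBBB")
  expect_identical(sc$class_names, c("NORM", "CRBBB"))
  expect_true(is.na(scenario_index(sc, "CD", "CLBBB")))  # different subclass
  expect_identical(scenario_index(binary_subclass("AMI"), "MI", "AMI"), 1L)
  expect_error(binary_subclass("WPW"), "must be one of")
})

test_that("normal-vs-abnormal pools every non-NORM single-disease record", {
  sc <- binary_normal_abnormal()
  expect_identical(scenario_index(sc, "NORM", "NORM"), 0L)
  expect_identical(scenario_index(sc, "HYP", "LVH"), 1L)
  expect_identical(scenario_index(sc, "MI", NA), 1L)
})

test_that("the 5-class scenario lists the superclasses in canonical order", {
  sc <- multiclass(5)
  expect_identical(sc$class_names, c("NORM", "MI", "CD", "STTC", "HYP"))
  expect_identical(scenario_index(sc, "STTC", "ISCA"), 3L)
})

test_that("top-k subclass selection matches a brute-force sort of the counts", {
  subs <- setdiff(unique(ptbxl_taxonomy()$subclass), "NORM")
  counts <- setNames(rep(0, length(subs)), subs)
  nine <- c("STTC", "AMI", "IMI", "LAFB/LPFB", "LVH", "IRBBB", "CLBBB",
            "ISCA", "CRBBB")
  counts[nine] <- seq(90, 10, by = -10)
  counts["NORM"] <- 500
  sc <- multiclass(10, counts)
  # brute force: sort non-NORM counts decreasing, take nine
  brute <- names(sort(counts[setdiff(names(counts), "NORM")],
                      decreasing = TRUE))[1:9]
  expect_setequal(setdiff(sc$class_names, "NORM"), brute)
  expect_identical(sc$class_names[1], "NORM")
  expect_identical(sc$k, 10L)
  expect_error(multiclass(7), "must be 5, 10 or 15")
  expect_error(multiclass(10), "class_counts")
})

test_that("count ties at the cutoff break by taxonomy order", {
  counts <- c(AMI = 5, IMI = 5, LMI = 5, PMI = 5, LVH = 5, RVH = 5,
              ISCA = 5, ISCI = 5, CLBBB = 5, CRBBB = 5, WPW = 5)
  expect_message(sc <- multiclass(10, counts), "tie")
  # first nine candidate subclasses in taxonomy (table) order
  tax_order <- unique(ptbxl_taxonomy()$subclass)
  expected <- intersect(tax_order, names(counts))[1:9]
  expect_setequal(setdiff(sc$class_names, "NORM"), expected)
})

test_that("materialized datasets have contiguous 0-based indices and honor partitions", {
  corp <- generate_corpus(disjoint_leads_config(n_records = 120, seed = 21))
  sc <- multiclass(5)
  sets <- materialize_splits(sc, corp)
  all_ids <- unlist(lapply(sets, `[[`, "record_id"))
  expect_identical(anyDuplicated(all_ids), 0L)           # pairwise disjoint
  expect_setequal(all_ids, corp$labels$record_id)        # exhaustive
  for (s in sets) {
    if (length(s$y)) {
      expect_true(all(s$y %in% 0:(sc$k - 1L)))
    }
  }
  # idempotence: mapping a class name back through the scenario returns
  # the same index
  y2 <- scenario_index(sc, sc$class_names[sets$train$y + 1L], NA)
  expect_identical(y2, sets$train$y)

  # conservation: the 5-class record set equals the union of the four
  # binary-superclass record sets' disease arms plus the NORM records
  train_ids_5 <- sets$train$record_id
  union_ids <- unique(unlist(lapply(c("MI", "CD", "STTC", "HYP"), function(d) {
    materialize(binary_superclass(d), corp, "train")$record_id
  })))
  expect_setequal(train_ids_5, union_ids)
})

test_that("scenario YAML manifests round-trip", {
  dir <- withr::local_tempdir()
  sc <- binary_subclass("LAFB/LPFB")
  path <- file.path(dir, "scenario.yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_identical(sc2$class_names, sc$class_names)
  expect_identical(sc2$granularity, sc$granularity)
  expect_identical(sc2$k, sc$k)
})
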