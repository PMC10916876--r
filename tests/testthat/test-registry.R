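test_that("planted associations are recovered and level-5 sets nest inside
           step-A subsets", {
  sc <- small_scenario(seed = 5)
  panel <- generate_crispr_panel(sc)
  z <- standardize_features(panel$profiles)
  reg <- build_registry(z, panel$readouts, panel$meta, panel$annotations,
                        seed = 5)
  found <- unique(data.frame(
    readout = vapply(reg$terms, `[[`, character(1), "level3_phenotype"),
    group = vapply(reg$terms, `[[`, character(1), "level4_process")))
  truth <- panel$truth$planted_pairs
  tp <- nrow(merge(found, truth))
  expect_gte(tp / nrow(truth), 2 / 3)            # most planted pairs found
  expect_gte(tp / max(nrow(found), 1), 2 / 3)    # few spurious pairs

  # nesting: every term's features lie inside its readout's step-A subset
  for (t in reg$terms) {
    expect_true(all(t$level5_features %in%
                      reg$step_a_subsets[[t$level3_phenotype]]))
    expect_true(t$regression_gate$passed && t$regression_gate$value > 0.25)
    expect_true(t$classifier_gate$passed && t$classifier_gate$value > 0.50)
  }

  # summary is one row per term, sorted by id
  s <- summary(reg)
  expect_identical(nrow(s), length(reg$terms))
  expect_identical(s$term_id, sort(s$term_id))
})

test_that("registry build is deterministic under a fixed seed", {
  sc <- small_scenario(seed = 2)
  panel <- generate_crispr_panel(sc)
  z <- standardize_features(panel$profiles)
  r1 <- build_registry(z, panel$readouts, panel$meta, panel$annotations,
                       seed = 9)
  r2 <- build_registry(z, panel$readouts, panel$meta, panel$annotations,
                       seed = 9)
  expect_identical(summary(r1), summary(r2))
  expect_identical(lapply(r1$terms, `[[`, "level5_features"),
                   lapply(r2$terms, `[[`, "level5_features"))
})

test_that("registry serialization round-trips and validates", {
  reg <- toy_registry()
  f <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_identical(length(back$terms), length(reg$terms))
  ids <- vapply(reg$terms, `[[`, character(1), "term_id")
  back_ids <- vapply(back$terms, `[[`, character(1), "term_id")
  expect_setequal(back_ids, ids)
  for (t in back$terms) {
    orig <- reg$terms[[match(t$term_id, ids)]]
    expect_identical(t$level5_features, orig$level5_features)
    expect_identical(t$level3_phenotype, orig$level3_phenotype)
  }
  # byte-stability: serializing the same registry twice gives identical files
  f2 <- withr::local_tempfile(fileext = ".json")
  write_registry(back, f2)
  write_registry(read_registry(f2), f)
  expect_identical(readLines(f), readLines(f2))

  # empty registry round-trips
  empty <- biomorph:::new_registry(list(), feature_universe = "f1")
  f3 <- withr::local_tempfile(fileext = ".json")
  write_registry(empty, f3)
  expect_identical(length(read_registry(f3)$terms), 0L)

  # schema-version mismatch and duplicate ids are read errors
  doc <- jsonlite::fromJSON(f3, simplifyVector = FALSE)
  doc$schema_version <- "0.9"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), f3)
  expect_error(read_registry(f3), "schema version")

  write_registry(reg, f)
  doc2 <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  doc2$terms <- c(doc2$terms, doc2$terms[1])
  writeLines(jsonlite::toJSON(doc2, auto_unbox = TRUE, null = "null"), f)
  expect_error(read_registry(f), "duplicate term_id")
})

test_that("registry construction validates inputs", {
  sc <- small_scenario(seed = 3)
  panel <- generate_crispr_panel(sc)
  z <- standardize_features(panel$profiles)
  ann <- panel$annotations[-1, ]
  expect_error(build_registry(z, panel$readouts, panel$meta, ann, seed = 1),
               "no level-1/level-2 annotation")
  meta_nc <- panel$meta
  meta_nc$is_negative_control <- FALSE
  expect_error(build_registry(z, panel$readouts, meta_nc, panel$annotations,
                              seed = 1),
               "negative-control")
  expect_error(biomorph_term("a", "b", "c", "d", character(0)), "non-empty")
})
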