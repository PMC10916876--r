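test_that("plate-control subtraction centres each plate on its controls", {
  # two plates with different control means, hand-computed expectations
  vals <- rbind(c(10, 0), c(12, 2), c(15, 5),   # plate A, controls rows 1-2
                c(100, 50), c(104, 54))         # plate B, control row 4
  rownames(vals) <- paste0("w", 1:5)
  colnames(vals) <- c("f1", "f2")
  tab <- morph_table(vals)
  out <- subtract_plate_control(tab, c("A", "A", "A", "B", "B"),
                                c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.numeric(out["w3", ]), c(15 - 11, 5 - 1))   # plate A mean (11,1)
  expect_equal(as.numeric(out["w5", ]), c(4, 4))             # plate B ctrl (100,50)
  expect_equal(as.numeric(out["w1", ]), c(-1, -1))           # controls centred

  # all-control plate: per-feature mean exactly 0
  all_ctrl <- subtract_plate_control(tab[1:3, ], rep("A", 3), rep(TRUE, 3))
  expect_equal(unname(colMeans(all_ctrl)), c(0, 0))

  # idempotence on centred plates
  again <- subtract_plate_control(out, c("A", "A", "A", "B", "B"),
                                  c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(unclass(again), unclass(out), tolerance = 1e-10)

  expect_error(subtract_plate_control(tab, c("A", "A", "B", "B", "B"),
                                      c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               "'B' has no control")
})

test_that("dose-window consensus follows the one-sd rule", {
  mk <- function(id, doses) {
    data.frame(compound_id = id, dose = doses,
               f1 = seq_along(doses), f2 = 10 * seq_along(doses))
  }
  # singleton always retained
  one <- consensus_by_compound(mk("c1", 5))
  expect_equal(as.numeric(one["c1", ]), c(1, 10))

  # {1,1,1,100}: sd 49.5, |100 - 25.75| = 74.25 > sd, so the outlier drops
  d <- mk("c2", c(1, 1, 1, 100))
  expect_equal(stats::sd(d$dose), 49.5)
  out <- consensus_by_compound(d)
  expect_equal(unclass(out)["c2", "f1"], stats::median(1:3))

  # {1,2,3,4,50}: 50 falls outside one sd of the mean, median over the rest
  d2 <- mk("c3", c(1, 2, 3, 4, 50))
  keep <- abs(d2$dose - mean(d2$dose)) <= stats::sd(d2$dose)  # brute force
  expect_identical(which(!keep), 5L)
  out2 <- consensus_by_compound(d2)
  expect_equal(unclass(out2)["c3", "f1"], stats::median(1:4))

  # two dose points are always both within one sd of their mean
  out3 <- consensus_by_compound(mk("c4", c(1, 1000)))
  expect_equal(unclass(out3)["c4", "f1"], 1.5)

  # permutation invariance in dose-point order
  perm <- d2[c(4, 1, 5, 3, 2), ]
  expect_equal(unclass(consensus_by_compound(perm)), unclass(out2),
               ignore_attr = TRUE)

  empty <- data.frame(compound_id = character(0), dose = numeric(0),
                      f1 = numeric(0))
  expect_error(consensus_by_compound(empty), "empty")
  expect_error(consensus_by_compound(mk("c6", -1)), "> 0")
})

test_that("standardisation uses the population convention and is idempotent", {
  tab <- morph_table(matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
                            dimnames = list(letters[1:3], c("v", "const"))))
  expect_warning(z <- standardize_features(tab), "zero-variance")
  expect_equal(as.numeric(z[, "v"]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_identical(as.numeric(z[, "const"]), c(0, 0, 0))

  big <- toy_profiles(50, 8, seed = 9)
  z2 <- standardize_features(big)
  expect_true(all(abs(colMeans(z2)) < 1e-12))
  expect_equal(unname(colMeans(unclass(z2)^2)), rep(1, 8), tolerance = 1e-12)
  z3 <- standardize_features(z2)
  expect_equal(unclass(z3), unclass(z2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # reference-statistics mode reproduces the training scaling
  ref <- standardize_features(big)
  z4 <- standardize_features(big, center = attr(ref, "center"),
                             scale = attr(ref, "scale"))
  expect_equal(unclass(z4), unclass(ref), ignore_attr = TRUE)
})
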