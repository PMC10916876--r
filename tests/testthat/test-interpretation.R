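# importance selection, attribution contracts and enrichment arithmetic

test_that("two-sd importance rule matches hand computations", {
  # (0,0,0,0,0,0,0,0,0,10): mean 1, population sd 3, cut 7 -> only the 10
  v <- setNames(c(rep(0, 9), 10), paste0("f", 1:10))
  sel <- select_important(v)
  expect_identical(sel$feature_names, "f10")
  expect_equal(sel$threshold_value, 7)

  # (0,0,0,0,1): cut = 1.0 (population) or ~1.094 (sample); strict -> empty
  v2 <- setNames(c(0, 0, 0, 0, 1), paste0("f", 1:5))
  expect_length(select_important(v2)$feature_names, 0)
  expect_length(select_important(v2, convention = "sample")$feature_names, 0)
  # non-strict population convention picks up the boundary value
  expect_identical(select_important(v2, strict = FALSE)$feature_names, "f5")

  # uniform vector -> sd 0 -> empty
  expect_length(select_important(setNames(rep(3, 6), paste0("f", 1:6)))
                $feature_names, 0)
})

test_that("term overlap is a plain percentage and is monotone", {
  term <- biomorph_term("a", "m", "ph", "pr", c("f1", "f2", "f3", "f4"))
  expect_equal(term_overlap(c("f1", "f3", "f9"), term), 50)
  expect_equal(term_overlap(character(0), term), 0)
  expect_equal(term_overlap(c("f8", "f9"), term), 0)
  expect_equal(term_overlap(paste0("f", 1:9), term), 100)
  # adding features never decreases overlap
  set.seed(31)
  base <- sample(paste0("f", 1:9), 3)
  expect_gte(term_overlap(c(base, "f1"), term), term_overlap(base, term))
})

test_that("level enrichment means, the >= 10% ladder and top-k ranking
           match hand-computed values", {
  reg <- toy_registry()   # pct_dead x {ROS, Apoptosis}, g2_arrest x ROS
  ov <- c("viability_intensity_pct_dead_ROS" = 20,
          "viability_intensity_pct_dead_Apoptosis" = 40,
          "cell_cycle_count_g2_arrest_ROS" = 5)
  rep_ <- enrich_levels(reg, ov)
  expect_equal(rep_$level4_enrichment[["ROS"]], 12.5)        # mean(20, 5)
  expect_equal(rep_$level4_enrichment[["Apoptosis"]], 40)
  expect_equal(rep_$level3_enrichment[["pct_dead"]], 30)     # mean(20, 40)
  expect_equal(rep_$level3_enrichment[["g2_arrest"]], 5)

  h <- rep_$hierarchical
  h3 <- h[h$level == 3, ]
  expect_equal(h3$value[h3$label == "pct_dead"], 100)  # 2 of 2 terms >= 10
  expect_equal(h3$value[h3$label == "g2_arrest"], 0)

  # hand case from a three-entry ladder: (5, 12, 50) -> 2 of 3 >= 10%
  reg1 <- biomorph:::new_registry(
    list(biomorph_term("a", "m", "ph", "p1", "f1"),
         biomorph_term("a", "m", "ph", "p2", "f2"),
         biomorph_term("a", "m", "ph", "p3", "f3")),
    feature_universe = paste0("f", 1:3))
  ov1 <- c(a_m_ph_p1 = 5, a_m_ph_p2 = 12, a_m_ph_p3 = 50)
  h1 <- enrich_levels(reg1, ov1)$hierarchical
  expect_equal(h1$value[h1$level == 3], 200 / 3, tolerance = 1e-9)

  # top-k: descending score, alphabetical ties, truncation
  fake <- list(level3_enrichment = c(A = 30, B = 10, C = 30))
  expect_identical(top_k(fake, "level3", 2), c("A", "C"))
  expect_identical(top_k(fake, "level3", 10), c("A", "C", "B"))
  scaled <- list(level3_enrichment = c(A = 3, B = 1, C = 3))
  expect_identical(top_k(scaled, "level3", 3), top_k(fake, "level3", 3))

  # singleton registry: level maps equal the term's overlap
  single <- biomorph:::new_registry(
    list(biomorph_term("a", "m", "ph", "p1", "f1")), "f1")
  rep1 <- enrich_levels(single, c(a_m_ph_p1 = 37.5))
  expect_equal(unname(rep1$level3_enrichment), 37.5)
  expect_equal(unname(rep1$level4_enrichment), 37.5)

  expect_error(enrich_levels(reg, ov[1:2]), "missing for terms")
})

test_that("attributions satisfy local accuracy and the null-player
           property", {
  set.seed(71)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X <- cbind(X, constant = 0)    # never split on -> zero attribution
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.5) > 0)
  fit <- train_heldout(X, y, seed = 4,
                       config = cv_config(n_candidates = 2L,
                                          rung_trees = c(25L, 50L),
                                          final_trees = 100L))
  set.seed(72)
  new_rows <- matrix(rnorm(50 * 7), 50, 7,
                     dimnames = list(NULL, colnames(X)))
  A <- attribute_compound(fit, new_rows)
  resid <- rowSums(A) + attr(A, "baseline") - attr(A, "scores")
  expect_lt(max(abs(resid)), 1e-6)
  expect_true(all(A[, "constant"] == 0))

  expect_error(attribute_compound(list(model = NULL), new_rows), "fitted")
})

test_that("planted-signal compounds attribute mostly to planted features", {
  wins <- vapply(1:3, function(s) {
    sc <- small_scenario(seed = s)
    screen <- generate_compound_screen(sc)
    X <- unclass(standardize_features(screen$profiles))
    fit <- train_heldout(X, screen$labels, seed = s,
                         config = cv_config(n_candidates = 2L,
                                            rung_trees = c(25L, 50L),
                                            final_trees = 100L))
    tp <- true_positive_rows(fit)
    if (!length(tp)) return(FALSE)
    A <- attribute_compound(fit, fit$X_test[tp, , drop = FALSE])
    top <- names(sort(colMeans(A), decreasing = TRUE))[seq_len(sc$subset_size)]
    mean(top %in% screen$truth$active_subset) >= 0.5
  }, logical(1L))
  expect_gte(sum(wins), 2L)
})
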