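# chi-squared term scoring against closed-form and Monte-Carlo oracles

# closed-form survival function for even dof: exp(-x/2) * sum (x/2)^i / i!
chisq_sf_even <- function(x, dof) {
  k <- dof / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

test_that("term p-values match the even-dof closed-form series", {
  for (dof in c(2L, 4L, 10L)) {
    term <- biomorph_term("a", "m", "ph", "pr", sprintf("f%02d", 1:dof))
    set.seed(dof)
    for (i in 1:20) {
      z <- rnorm(dof)
      names(z) <- sprintf("f%02d", 1:dof)
      sc <- score_term(z, term)
      expect_equal(sc$statistic, sum(z^2), tolerance = 1e-15)
      expect_identical(sc$dof, dof)
      expect_equal(sc$p_value, chisq_sf_even(sum(z^2), dof),
                   tolerance = 1e-12)
    }
  }
  # frozen hand value: z = (1,1,1,1) -> stat 4, p = e^-2 * (1 + 2)
  term4 <- biomorph_term("a", "m", "ph", "pr", paste0("f", 1:4))
  z <- setNames(rep(1, 4), paste0("f", 1:4))
  expect_equal(score_term(z, term4)$p_value, exp(-2) * 3, tolerance = 1e-12)
  expect_equal(score_term(z, term4)$p_value, 0.4060058, tolerance = 1e-6)
})

test_that("scores obey the null, symmetry and monotonicity properties", {
  term <- biomorph_term("a", "m", "ph", "pr", paste0("f", 1:5))
  z0 <- setNames(rep(0, 5), paste0("f", 1:5))
  s0 <- score_term(z0, term)
  expect_identical(s0$statistic, 0)
  expect_identical(s0$p_value, 1)

  set.seed(1)
  z <- setNames(rnorm(5), paste0("f", 1:5))
  expect_equal(score_term(-z, term)$p_value, score_term(z, term)$p_value)

  # p strictly decreasing in the statistic at fixed dof
  stats_seq <- seq(0.5, 20, by = 0.5)
  ps <- pchisq(stats_seq, df = 5, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  zm <- z
  names(zm)[1] <- "other"
  expect_error(score_term(zm, term), "lacks features")
})

test_that("tail probabilities agree with a Monte-Carlo oracle", {
  set.seed(77)
  n_mc <- 1e5
  for (dof in c(1L, 2L, 5L, 10L)) {
    draws <- matrix(rnorm(n_mc * dof), n_mc, dof)
    stat_mc <- rowSums(draws^2)
    for (q in c(0.5, 1, 2) * dof) {
      p_hat <- mean(stat_mc >= q)
      p <- pchisq(q, df = dof, lower.tail = FALSE)
      mc_sd <- sqrt(p * (1 - p) / n_mc)
      expect_lt(abs(p_hat - p), 3 * mc_sd + 1e-12)
    }
  }
})

test_that("transform composes per-term scoring, standardizes columns and
           drops degenerate terms", {
  reg <- biomorph:::new_registry(
    list(biomorph_term("a", "m", "ph1", "pr", c("f1", "f2")),
         biomorph_term("a", "m", "ph2", "pr", c("f3", "f4"))),
    feature_universe = paste0("f", 1:4))
  set.seed(12)
  X <- morph_table(matrix(rnorm(40), 10, 4,
                          dimnames = list(paste0("p", 1:10),
                                          paste0("f", 1:4))))
  mat <- biomorph_transform(X, reg)
  expect_identical(dim(mat), c(10L, 2L))
  expect_true(all(abs(colMeans(mat)) < 1e-12))
  expect_equal(unname(colMeans(unclass(mat)^2)), c(1, 1), tolerance = 1e-12)

  # raw p-values equal explicit score_term calls on the standardized rows
  z <- unclass(standardize_features(X))
  pm <- attr(mat, "p_values")
  for (i in 1:10) {
    expect_equal(pm[i, 1],
                 score_term(z[i, ], reg$terms[[1]])$p_value,
                 tolerance = 1e-12)
  }

  # row-permutation equivariance
  perm <- c(4, 1, 10, 3, 2, 9, 5, 8, 7, 6)
  mat_perm <- biomorph_transform(X[perm, ], reg)
  expect_equal(unclass(mat_perm), unclass(mat)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  # a term on constant features gives constant p-values -> dropped
  Xc <- unclass(X)
  Xc[, "f3"] <- 5
  Xc[, "f4"] <- -2
  expect_warning(mat2 <- biomorph_transform(morph_table(Xc), reg),
                 "zero-variance")
  expect_identical(attr(mat2, "retained_terms"), "a_m_ph1_pr")

  # terms with absent features are dropped with a warning; none left -> error
  X3 <- X[, c("f1", "f2")]
  expect_warning(mat3 <- biomorph_transform(X3, reg), "dropped")
  expect_identical(ncol(mat3), 1L)
  expect_error(suppressWarnings(biomorph_transform(X[, "f1", drop = FALSE],
                                                   reg)))
})

test_that("planted-active profiles score smaller p on their planted term", {
  diffs <- vapply(1:10, function(s) {
    sc <- sim_scenario(seed = s)   # default screen conditions
    screen <- generate_compound_screen(sc)
    term <- biomorph_term("a", "m", "ph", "pr", sc$planted_map[[1]])
    reg <- biomorph:::new_registry(list(term), sc$feature_names)
    p <- attr(biomorph_transform(screen$profiles, reg), "p_values")[, 1]
    mean(p[screen$labels == 1L]) - mean(p[screen$labels == 0L])
  }, numeric(1L))
  expect_true(all(diffs < 0))   # one-sided: actives have smaller mean p
})

test_that("predict on a registry equals the transform", {
  reg <- toy_registry()
  set.seed(5)
  X <- morph_table(matrix(rnorm(60), 5, 12,
                          dimnames = list(paste0("p", 1:5),
                                          paste0("f", 1:12))))
  expect_equal(unclass(predict(reg, X)), unclass(biomorph_transform(X, reg)),
               ignore_attr = TRUE)
})
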