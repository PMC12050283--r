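# GMPR normalization, EMD scoring, pooled permutation testing, and
# exclusive/differential classification.

test_that("GMPR size factors reproduce symmetry and scaling identities", {
  m <- cbind(S1 = c(10L, 5L, 0L, 8L), S2 = c(10L, 5L, 0L, 8L))
  expect_equal(unname(gmpr_size_factors(m)$s), c(1, 1))
  m2 <- cbind(S1 = c(10L, 5L, 2L, 8L), S2 = c(20L, 10L, 4L, 16L))
  s <- gmpr_size_factors(m2)$s
  expect_equal(unname(s[2] / s[1]), 2)
})

test_that("GMPR matches a hand-computed pairwise-median oracle", {
  # 4 features x 3 samples with planted zeros; oracle evaluates the formula
  # directly and independently
  m <- cbind(A = c(10L, 0L, 4L, 6L),
             B = c(20L, 8L, 0L, 12L),
             C = c(5L, 4L, 2L, 0L))
  oracle <- local({
    p <- ncol(m)
    r <- diag(p)  # self-ratio 1 on the diagonal
    for (i in 1:p) for (j in 1:p) {
      if (i == j) next
      sh <- m[, i] > 0 & m[, j] > 0
      r[i, j] <- if (any(sh)) median(m[sh, i] / m[sh, j]) else NA_real_
    }
    s <- sapply(1:p, function(i) exp(mean(log(r[i, ][!is.na(r[i, ])]))))
    s / exp(mean(log(s)))
  })
  expect_equal(unname(gmpr_size_factors(m)$s), oracle, tolerance = 1e-9)
})

test_that("multiplying one sample scales its factor exactly", {
  set.seed(101)
  m <- matrix(rpois(80L, 8), 20L, 4L,
              dimnames = list(NULL, paste0("S", 1:4)))
  m[sample(80L, 20L)] <- 0L
  s0 <- gmpr_size_factors(m)$s
  m2 <- m
  m2[, 1] <- m2[, 1] * 4L
  s1 <- gmpr_size_factors(m2)$s
  # pre-rescaling covariance: the factor ratio to any other sample
  # quadruples exactly
  expect_equal(unname(s1[1] / s1[2]), unname(4 * s0[1] / s0[2]),
               tolerance = 1e-12)
})

test_that("a sample sharing no features is reported by name", {
  m <- cbind(S1 = c(5L, 3L, 0L), S2 = c(2L, 1L, 0L), S3 = c(0L, 0L, 7L))
  expect_error(gmpr_size_factors(m), "S3")
})

test_that("normalization removes a planted 4-fold depth difference", {
  set.seed(102)
  base <- rpois(500L, 20) * (runif(500L) >= 0.3)
  m <- cbind(S1 = as.integer(base), S2 = as.integer(base * 4L),
             S3 = as.integer(rpois(500L, 20) * (runif(500L) >= 0.3)),
             S4 = as.integer(rpois(500L, 20) * (runif(500L) >= 0.3)))
  sf <- gmpr_size_factors(m)$s
  norm <- sweep(m, 2L, sf, "/")
  expect_equal(mean(norm[, 2]) / mean(norm[, 1]), 1, tolerance = 0.05)
})

test_that("emd_score equals its closed-form values and metric properties", {
  expect_equal(emd_score(c(3, 7, 1), c(3, 7, 1)), 0)
  expect_equal(emd_score(c(0, 0), c(4, 4)), 4.0)
  expect_equal(emd_score(c(0, 1), c(1, 2)), 1.0)
  set.seed(103)
  for (i in 1:25) {
    a <- sample(0:20, 4L, replace = TRUE)
    b <- sample(0:20, 4L, replace = TRUE)
    e <- emd_score(a, b)
    expect_gte(e, 0)
    expect_equal(e, emd_score(b, a))                      # symmetry
    expect_equal(emd_score(3 * a, 3 * b), 3 * e)          # scale covariance
    expect_equal(e, mean(abs(sort(a) - sort(b))))         # equal-n identity
    if (identical(sort(a), sort(b))) expect_equal(e, 0) else expect_gt(e, 0)
  }
  expect_error(emd_score(numeric(0), 1), "non-empty")
})

test_that("constant features are never significant", {
  m <- rbind(feat_1 = c(5L, 5L, 5L, 5L), feat_2 = c(9L, 1L, 8L, 2L))
  colnames(m) <- c("A_1", "A_2", "B_1", "B_2")
  groups <- setNames(c("A", "A", "B", "B"), colnames(m))
  sf <- structure(list(s = setNames(rep(1, 4), colnames(m))),
                  class = "gmpr_factors")
  res <- emd_permutation_test(m, groups, size_factors = sf)
  expect_equal(res$emd[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(res$q[1], 1)
  cls <- classify_features(m, groups, res, sf)
  expect_equal(cls$class_label[1], "not_significant")
})

test_that("the pooled permutation null controls the q<0.05 fraction", {
  sim <- simulate_count_matrix(count_sim_design(
    n_features = 2000L, base_lambda = 10, zero_inflation_pi = 0.3,
    seed = 104L))
  res <- emd_permutation_test(sim$counts, sim$groups)
  expect_lte(mean(res$q < 0.05), 0.06)
})

test_that("a strong planted feature reaches significance in a null matrix", {
  sim <- simulate_count_matrix(count_sim_design(
    n_features = 2000L, base_lambda = 10, zero_inflation_pi = 0.3,
    seed = 105L))
  m <- sim$counts
  m[1, sim$groups[colnames(m)] == "A"] <- 0L
  m[1, sim$groups[colnames(m)] == "B"] <- c(50L, 60L)
  res <- ecc_diff(m, sim$groups)
  # a lone outlier attains the smallest possible pooled p and the top rank;
  # BH over 2000 features cannot take a single feature below q = 0.05 when
  # only two label splits feed the null, so the q gate needs batches of
  # true effects (see the recovery test below)
  expect_equal(res$p[1], min(res$p))
  expect_lt(res$p[1], 1e-3)
  expect_equal(order(res$p)[1], 1L)
})

test_that("classification separates exclusive from differential calls", {
  groups <- setNames(c("A", "A", "B", "B"), c("A_1", "A_2", "B_1", "B_2"))
  m <- rbind(f1 = c(5L, 7L, 0L, 0L), f2 = c(5L, 7L, 0L, 2L),
             f3 = c(5L, 7L, 0L, 0L))
  colnames(m) <- names(groups)
  sf <- structure(list(s = setNames(rep(1, 4), names(groups))),
                  class = "gmpr_factors")
  emd <- data.frame(unified_id = rownames(m), emd = c(6, 5, 6),
                    p = c(0.01, 0.01, 0.2), q = c(0.01, 0.01, 0.2))
  got <- classify_features(m, groups, emd, sf)
  expect_equal(got$class_label,
               c("exclusive_A", "differential_A_up", "not_significant"))
})

test_that("planted exclusive features are recovered with correct labels", {
  sim <- simulate_count_matrix(count_sim_design(
    n_features = 2000L, base_lambda = 10, zero_inflation_pi = 0.3,
    exclusive_A = 1:30, exclusive_B = 31:60, differential = 61:100,
    seed = 106L))
  res <- ecc_diff(sim$counts, sim$groups)
  recovered_a <- mean(res$class_label[1:30] == "exclusive_A")
  recovered_b <- mean(res$class_label[31:60] == "exclusive_B")
  expect_gte(recovered_a, 0.9)
  expect_gte(recovered_b, 0.9)
  # false exclusive calls among true nulls stay within the FDR bound
  null_idx <- 101:2000
  expect_lte(mean(grepl("exclusive", res$class_label[null_idx])), 0.05)
})

test_that("swapping group labels swaps directions but not q-values", {
  sim <- simulate_count_matrix(count_sim_design(
    n_features = 300L, base_lambda = 10, zero_inflation_pi = 0.3,
    exclusive_A = 1:5, exclusive_B = 6:10, seed = 107L))
  g1 <- sim$groups
  g2 <- setNames(ifelse(g1 == "A", "B", "A"), names(g1))
  r1 <- ecc_diff(sim$counts, g1)
  r2 <- ecc_diff(sim$counts, g2)
  expect_equal(r1$q, r2$q)
  swap <- c(exclusive_A = "exclusive_B", exclusive_B = "exclusive_A",
            differential_A_up = "differential_B_up",
            differential_B_up = "differential_A_up",
            not_significant = "not_significant")
  expect_identical(unname(swap[r1$class_label]), r2$class_label)
})
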