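cell_table <- function(values, subjects = 2, features = 3) {
  grid <- expand.grid(subject = paste0("s", seq_len(subjects)),
                      feature = paste0("f", seq_len(features)),
                      stringsAsFactors = FALSE)
  grid$value <- values
  grid
}

test_that("correlate recovers monotone and reversed orders", {
  cce <- cell_table(1:6)
  acc <- cell_table((1:6)^2 / 40)            # strictly increasing transform
  r <- correlate(cce, acc, mode = "average")
  expect_equal(r$rho, 1.0)
  acc_rev <- cell_table(rev(1:6) / 10)
  expect_equal(correlate(cce, acc_rev, "average")$rho, -1.0)
  expect_lt(r$p_value, 0.05)
})

test_that("correlate handles ties like hand-computed ranks", {
  cce <- cell_table(c(1, 2, 2, 3, 4, 4))
  acc <- cell_table(c(2, 1, 3, 5, 4, 6) / 10)
  r <- correlate(cce, acc, "average")
  # oracle: Pearson on mid-ranks computed by hand
  rx <- c(1, 2.5, 2.5, 4, 5.5, 5.5)
  ry <- c(2, 1, 3, 5, 4, 6)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(r$rho, oracle, tolerance = 1e-12)
  # cross-check against the standard implementation
  expect_equal(r$rho, suppressWarnings(
    cor.test(cce$value, acc$value, method = "spearman"))$estimate[[1]])
})

test_that("correlate modes aggregate and guard their keys", {
  ind <- expand.grid(subject = "s1", feature = c("f1", "f2"),
                     movement = c("m1", "m2", "m3"),
                     stringsAsFactors = FALSE)
  ind$value <- 1:6
  acc <- ind; acc$value <- ind$value + 0.5
  r <- correlate(ind, acc, "individual")
  expect_equal(r$n, 6)
  expect_equal(r$rho, 1.0)
  bad <- acc; bad$subject <- "s2"
  expect_error(correlate(ind, bad, "individual"), "key mismatch")
  const <- acc; const$value <- 1
  expect_error(correlate(ind, const, "individual"), "all-constant")
})

test_that("best-set search ranks every candidate and finds planted pairs", {
  fm <- planted_bank(n_feat = 6, K = 3, n = 50, planted = c(2L, 5L),
                     seed = 21)
  for (ccea in c("nns", "si")) {
    rep <- best_sets(fm, ccea, 2, k = 30)
    expect_equal(nrow(rep$ranking), choose(6, 2))
    expect_setequal(rep$best, c("dim2", "dim5"))
    # ranking is a permutation of all candidates
    combos <- utils::combn(fm$features, 2, simplify = FALSE)
    keys <- vapply(rep$ranking$features, function(f)
      paste(sort(f), collapse = "+"), "")
    expect_setequal(keys, vapply(combos, function(f)
      paste(sort(f), collapse = "+"), ""))
    expect_true(all(diff(rep$ranking$cce) <= 1e-12))
  }
  # F == set_size: single candidate
  small <- fm_select_features(fm, c("dim2", "dim5"))
  one <- best_sets(small, "si", 2)
  expect_equal(nrow(one$ranking), 1)
  expect_error(best_sets(small, "si", 3), "exceeds")
})

test_that("paired Wilcoxon comparison is exact and directional", {
  a <- c(0.71, 0.64, 0.80, 0.75, 0.69, 0.73, 0.77, 0.66, 0.70, 0.74,
         0.68, 0.72)
  b <- a + 0.05
  r <- compare_sets(a, b)
  expect_true(r$significant)
  expect_identical(r$direction, "b > a")
  # exact enumeration oracle: all 12 differences positive and tied in
  # magnitude -> P(W+ = max) = 2^-12, two-sided
  expect_equal(r$p_value, 2 / 2^12, tolerance = 1e-12)

  # tie-free case agrees with the standard implementation
  set.seed(30)
  d <- rnorm(12, 0.02, 0.01)
  b2 <- a + d
  expect_equal(compare_sets(a, b2)$p_value,
               wilcox.test(a, b2, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # symmetric permuted differences: false-positive rate near alpha
  set.seed(31)
  hits <- mean(vapply(1:200, function(i) {
    d <- sample(c(-1, 1), 12, TRUE) * runif(12, 0.01, 0.05)
    compare_sets(a, a + d)$significant
  }, NA))
  expect_lt(abs(hits - 0.05), 0.05)

  expect_error(compare_sets(a, a), "all differences zero")
  expect_error(compare_sets(a[1:4], (a + 1)[1:4]), "at least 5")
  expect_error(compare_sets(a, b[1:6]), "equal length")
})

test_that("conflict counts sum to K and expose a central class", {
  two <- random_models(2, 2)
  r2 <- conflict_report(two)
  expect_equal(sort(r2$times_conflicting), c(1L, 1L))
  # one class centered among all others collects the maximum count
  mods <- c(list(gm(c(0, 0), diag(2) * 0.5, "center")),
            lapply(1:5, function(i) {
              ang <- 2 * pi * i / 5
              gm(4 * c(cos(ang), sin(ang)), diag(2) * 0.5,
                 paste0("outer", i))
            }))
  r <- conflict_report(mods, "modified_mahalanobis")
  expect_equal(sum(r$times_conflicting), 6)
  expect_identical(r$movement[which.max(r$times_conflicting)], "center")
  # brute-force distance oracle agrees on who conflicts with whom
  o <- oracle_si(mods, "modified_mahalanobis")
  si <- separability_index(mods, "modified_mahalanobis")
  expect_equal(unname(si$individual), o$individual, tolerance = 1e-10)
  expect_error(conflict_report(mods[1]), "at least two")
})

test_that("channel correlation determinant matches closed forms", {
  set.seed(33)
  n <- 400
  base <- rnorm(n)
  rho <- 0.6
  ch2 <- rho * base + sqrt(1 - rho^2) * rnorm(n)
  fm <- feature_matrix(cbind(base, ch2), rep("a", n),
                       features = "tmabs", n_channels = 2L)
  got <- channel_correlation_determinant(fm, "tmabs")
  emp_rho <- cor(base, ch2)
  expect_equal(got, 1 - emp_rho^2, tolerance = 1e-10)   # det = 1 - rho^2

  # duplicated channels: fully redundant
  dup <- feature_matrix(cbind(base, base), rep("a", n),
                        features = "tmabs", n_channels = 2L)
  expect_equal(channel_correlation_determinant(dup, "tmabs"), 0,
               tolerance = 1e-12)

  # independent channels at large n: near 1
  ind <- feature_matrix(matrix(rnorm(4 * 2000), 2000), rep("a", 2000),
                        features = "x", n_channels = 4L)
  expect_gt(channel_correlation_determinant(ind, "x"), 0.95)

  const <- feature_matrix(cbind(base, rep(1, n)), rep("a", n),
                          features = "tmabs", n_channels = 2L)
  expect_error(channel_correlation_determinant(const, "tmabs"),
               "constant channel")
})
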