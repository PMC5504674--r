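test_that("class models are sample moments with regularization", {
  fm <- feature_matrix(matrix(c(-1, 1), 2, 1), c("a", "a"))
  m <- fit_class_models(fm)[[1]]
  expect_equal(m$mu, 0, ignore_attr = TRUE)
  expect_equal(as.numeric(m$S), 2)            # n - 1 denominator
  expect_equal(m$n, 2)

  # duplicate columns: singular covariance must come back positive definite
  set.seed(1)
  x <- rnorm(30)
  fm2 <- feature_matrix(cbind(x, x), rep("a", 30))
  expect_message(m2 <- fit_class_models(fm2)[[1]], "regularized")
  expect_gt(min(eigen(m2$S, symmetric = TRUE)$values), 0)

  expect_error(fit_class_models(
    feature_matrix(matrix(1, 1, 1), "a")), "fewer than 2")

  # large-n draw recovers the generating moments
  cfg <- cloud_config(rbind(c(1, -2)), matrix(c(2, 0.3, 0.3, 1), 2),
                      n = 4000, seed = 3)
  m3 <- fit_class_models(synth_clouds(cfg))[[1]]
  expect_true(all(abs(m3$mu - c(1, -2)) < 3 * sqrt(c(2, 1) / 4000)))
  expect_true(all(abs(m3$S - matrix(c(2, 0.3, 0.3, 1), 2)) < 0.15))
})

test_that("distance definitions match forced values and vanish at identity", {
  a <- gm(c(0, 0), diag(2))
  b <- gm(c(2, 0), diag(2))
  expect_equal(class_distance(a, b, "mahalanobis"), 1.0)
  expect_equal(class_distance(a, b, "modified_mahalanobis"), 1.0)

  for (def in distance_definitions()) {
    expect_equal(class_distance(a, a, def), 0, tolerance = 1e-12, info = def)
  }

  # d = 1, equal means, S1 = 1, S2 = 4
  k1 <- gm(0, matrix(1)); k2 <- gm(0, matrix(4))
  expect_equal(class_distance(k1, k2, "kullback_leibler"),
               0.5 * (4 - 1 + log(1 / 4)))
  expect_error(class_distance(a, gm(0, matrix(1))), "dimension mismatch")
})

test_that("KL matches a Monte-Carlo log-density-ratio oracle", {
  # closed form vs E_2[log p2/p1] for P1 = N(0,1), P2 = N(0,4)
  set.seed(101)
  x <- rnorm(2e5, 0, 2)
  lr <- dnorm(x, 0, 2, log = TRUE) - dnorm(x, 0, 1, log = TRUE)
  mc <- mean(lr)
  se <- sd(lr) / sqrt(length(lr))
  closed <- class_distance(gm(0, matrix(1)), gm(0, matrix(4)),
                           "kullback_leibler")
  expect_lt(abs(closed - mc), 3 * se)
})

test_that("distances agree with the brute-force formula oracle", {
  set.seed(5)
  for (i in 1:20) {
    d <- sample(1:4, 1)
    a <- gm(rnorm(d), random_pd(d))
    b <- gm(rnorm(d), random_pd(d))
    for (def in distance_definitions()) {
      expect_equal(class_distance(a, b, def), oracle_distance(a, b, def),
                   tolerance = 1e-10, info = def)
    }
  }
})

test_that("Hellinger and Bhattacharyya share the coefficient", {
  set.seed(6)
  for (i in 1:50) {
    d <- sample(1:3, 1)
    a <- gm(rnorm(d, sd = 2), random_pd(d))
    b <- gm(rnorm(d, sd = 2), random_pd(d))
    db <- class_distance(a, b, "bhattacharyya")^2
    dh <- class_distance(a, b, "hellinger")
    expect_equal(dh, 1 - exp(-2 * db), tolerance = 1e-10)
    expect_gte(dh, 0); expect_lte(dh, 1)
    expect_gte(class_distance(a, b, "kullback_leibler"), 0)
    # equal covariances collapse modified onto plain Mahalanobis
    b2 <- gm(b$mu, a$S)
    expect_equal(class_distance(a, b2, "modified_mahalanobis"),
                 class_distance(a, b2, "mahalanobis"), tolerance = 1e-12)
  }
})

test_that("separability index takes the most conflicting neighbor", {
  # 1-D, unit variances, means 0, 1, 5
  mods <- list(gm(0, matrix(1), "a"), gm(1, matrix(1), "b"),
               gm(5, matrix(1), "c"))
  si <- separability_index(mods, "modified_mahalanobis")
  expect_equal(unname(si$individual), c(0.5, 0.5, 2.0))
  expect_equal(si$average, 1.0)
  expect_identical(unname(si$conflict), c("b", "a", "b"))
  expect_equal(si$parameters$K, 3)

  # K = 2: both sides of a possibly asymmetric distance
  two <- list(gm(0, matrix(1), "a"), gm(2, matrix(4), "b"))
  si2 <- separability_index(two, "mahalanobis")
  expect_equal(unname(si2$individual),
               c(class_distance(two[[1]], two[[2]], "mahalanobis"),
                 class_distance(two[[2]], two[[1]], "mahalanobis")))
  expect_equal(si2$average, mean(si2$individual))
  expect_error(separability_index(mods[1]), "at least two")

  set.seed(8)
  for (i in 1:10) {
    mods <- random_models(sample(3:4, 1), sample(2:3, 1))
    for (def in distance_definitions()) {
      o <- oracle_si(mods, def)
      got <- separability_index(mods, def)
      expect_equal(unname(got$individual), o$individual, tolerance = 1e-10)
      expect_equal(got$average, o$average, tolerance = 1e-10)
    }
  }
})

test_that("NNS follows the harmonic dominance definition", {
  # separated: every nearest neighbor shares the class
  f1 <- feature_matrix(matrix(c(0, 1, 10, 11)), c("A", "A", "B", "B"))
  expect_equal(nearest_neighbor_separability(f1, k = 1)$average, 1.0)
  # interleaved: every nearest neighbor is the opposite class
  f2 <- feature_matrix(matrix(c(0, 2, 1, 3)), c("A", "A", "B", "B"))
  expect_equal(nearest_neighbor_separability(f2, k = 1)$average, 0.0)
  # k = 2 forced weights: first neighbor matches, second does not
  f3 <- feature_matrix(matrix(c(0, 1, 2.5)), c("A", "A", "B"))
  r3 <- nearest_neighbor_separability(f3, k = 2)
  expect_equal(unname(r3$individual["A"]), 2 / 3)   # d_t = (1/1)/(1 + 1/2)
  expect_equal(unname(r3$individual["B"]), 0)
  expect_equal(r3$average, mean(c(2 / 3, 2 / 3, 0)))

  expect_warning(r <- nearest_neighbor_separability(f3, k = 10), "clamped")
  expect_equal(r$parameters$k, 2)
})

test_that("NNS and purity match brute-force oracles on random instances", {
  set.seed(9)
  for (i in 1:10) {
    K <- sample(2:4, 1); d <- sample(1:3, 1); n <- sample(10:40, 1)
    cfg <- cloud_config(matrix(rnorm(K * d, sd = 2), K, d), diag(d),
                        n = n, seed = i)
    fm <- synth_clouds(cfg)
    k <- sample(1:10, 1)
    got <- nearest_neighbor_separability(fm, k = k)
    o <- oracle_nns(fm$values, fm$class, k)
    expect_equal(got$average, o$average, tolerance = 1e-10)
    expect_equal(unname(got$individual[names(o$individual)]),
                 unname(o$individual), tolerance = 1e-10)

    p <- purity(fm)
    expect_equal(p$average, oracle_purity(fm$values, fm$class),
                 tolerance = 1e-10)
    expect_true(all(p$individual >= 0 & p$individual <= 1))
    expect_gte(p$average, 0); expect_lte(p$average, 1)
  }
})

test_that("purity is 1 for single or cleanly separated classes", {
  one <- feature_matrix(matrix(rnorm(40), 20), rep("a", 20))
  expect_equal(purity(one)$average, 1.0)
  # two classes beyond the r = 2 boundary in every dimension
  x <- rbind(matrix(runif(40, 0, 0.4), 20), matrix(runif(40, 0.6, 1), 20))
  two <- feature_matrix(x, rep(c("a", "b"), each = 20))
  expect_equal(purity(two, resolutions = 2)$average, 1.0)
  # hand-enumerated mixed 2-D configuration at r = 2:
  # cell (0,0): 2A+1B -> 2/3; cell (1,1): 1A+2B -> 2/3; weights 3,3
  pts <- rbind(c(0, 0), c(0.1, 0.1), c(0.2, 0.2),
               c(0.8, 0.8), c(0.9, 0.9), c(1, 1))
  mix <- feature_matrix(pts, c("A", "A", "B", "A", "B", "B"))
  expect_equal(purity(mix, resolutions = 2)$average, 2 / 3)
  expect_error(purity(mix, resolutions = 10000), "too fine")
})

test_that("repeatability index measures drift from the first repetition", {
  # identical repetitions: zero
  set.seed(10)
  x <- matrix(rnorm(60), 30)
  fm0 <- feature_matrix(rbind(x, x, x), rep("a", 90),
                        rep(1:3, each = 30))
  expect_equal(repeatability_index(fm0)$average, 0)

  # 1-D: rep1 ~ N(0,1), reps 2-3 ~ N(1,1) -> individual ~ 0.5
  cfg <- cloud_config(rbind(0), matrix(1), n = 3000, drift = 0.5, seed = 4)
  fm1 <- synth_clouds(cfg)   # drift 0.5/rep: rep2 at 0.5, rep3 at 1.0
  ri1 <- repeatability_index(fm1)
  # population value 0.375; band ~3 standard errors at n = 1000/repetition
  expect_lt(abs(unname(ri1$individual) - mean(c(0.5 * 0.5, 0.5 * 1.0))),
            0.08)

  # monotone in the drift parameter (rank check over seeds)
  med_ri <- vapply(c(0, 0.5, 1, 2), function(dr) {
    median(vapply(1:5, function(s) {
      cfg <- cloud_config(rbind(c(0, 0)), diag(2), n = 90, drift = dr,
                          seed = s)
      repeatability_index(synth_clouds(cfg))$average
    }, 0))
  }, 0)
  expect_identical(order(med_ri), 1:4)

  expect_error(repeatability_index(
    feature_matrix(matrix(rnorm(10), 5), rep("a", 5), rep(1L, 5))),
    "fewer than 2 repetitions")
})

test_that("SI is affine invariant; NNS under translation and scaling", {
  cfg <- cloud_config(matrix(rnorm(12, sd = 2), 3, 4), random_pd(4),
                      n = 40, seed = 12)
  fm <- synth_clouds(cfg)
  set.seed(13)
  A <- matrix(rnorm(16), 4); while (abs(det(A)) < 0.1)
    A <- matrix(rnorm(16), 4)
  shift <- rnorm(4)
  mapped <- feature_matrix(sweep(fm$values %*% t(A), 2, shift, `+`),
                           fm$class, fm$repetition)
  for (def in distance_definitions()) {
    si0 <- separability_index(fit_class_models(fm), def)$average
    si1 <- separability_index(fit_class_models(mapped), def)$average
    expect_equal(si1, si0, tolerance = 1e-6, info = def)
  }
  nns0 <- nearest_neighbor_separability(fm, k = 7)
  iso <- feature_matrix(3.7 * sweep(fm$values, 2, shift, `+`),
                        fm$class, fm$repetition)
  nns1 <- nearest_neighbor_separability(iso, k = 7)
  expect_equal(nns1$average, nns0$average)
  expect_equal(nns1$individual, nns0$individual)
})

test_that("balanced identical distributions sit near chance dominance", {
  K <- 4
  vals <- vapply(1:6, function(s) {
    cfg <- cloud_config(matrix(0, K, 2), diag(2), n = 50, seed = s)
    nearest_neighbor_separability(synth_clouds(cfg), k = 20)$average
  }, 0)
  expect_lt(abs(mean(vals) - 1 / K), 0.05)
})

test_that("complexity_estimate dispatches to each algorithm", {
  fm <- synth_clouds(cloud_config(rbind(c(0, 0), c(3, 0)), diag(2),
                                  n = 30, seed = 1))
  expect_identical(complexity_estimate(fm, "si")$algorithm, "si")
  expect_identical(complexity_estimate(fm, "nns", k = 5)$algorithm, "nns")
  expect_identical(complexity_estimate(fm, "purity")$algorithm, "purity")
  expect_identical(complexity_estimate(fm, "ri")$algorithm, "ri")
})
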