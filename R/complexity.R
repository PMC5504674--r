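#' Fit per-class Gaussian models
#'
#' Each class (movement) is summarised by its sample mean vector and sample
#' covariance matrix (n - 1 denominator).  Singular or severely
#' ill-conditioned covariances (condition number > 1e12) are regularized by
#' adding `ridge * trace(S) / d` to the diagonal, with a message.
#'
#' @param fm a [feature_matrix()].
#' @param ridge relative ridge added on regularization (default 1e-8).
#' @return list of `gaussian_class_model` objects (fields `class`, `mu`,
#'   `S`, `n`), one per class in order of first appearance.
#' @export
fit_class_models <- function(fm, ridge = 1e-8) {
  stopifnot(inherits(fm, "feature_matrix"))
  classes <- unique(fm$class)
  lapply(classes, function(cl) {
    x <- fm$values[fm$class == cl, , drop = FALSE]
    if (nrow(x) < 2L) stop("class ", cl, " has fewer than 2 rows")
    mu <- colMeans(x)
    S <- stats::cov(x)
    S <- regularize_cov(S, ridge, cl)
    structure(list(class = cl, mu = mu, S = S, n = nrow(x)),
              class = "gaussian_class_model")
  })
}

regularize_cov <- function(S, ridge, label = "") {
  d <- ncol(S)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > 1e12) {
    bump <- ridge * sum(diag(S)) / d
    if (bump <= 0) bump <- ridge
    repeat {
      S2 <- S + diag(bump, d)
      ev2 <- eigen((S2 + t(S2)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values
      if (min(ev2) > 0 && max(ev2) / min(ev2) <= 1e12) break
      bump <- bump * 10
    }
    message("regularized covariance of class ", label,
            " (ridge ", format(bump), ")")
    S <- S2
  }
  (S + t(S)) / 2
}

#' The five Gaussian distance definitions
#' @return character vector of the supported distance definition names.
#' @export
distance_definitions <- function() {
  c("mahalanobis", "bhattacharyya", "kullback_leibler", "hellinger",
    "modified_mahalanobis")
}

# log-determinant via Cholesky (S assumed PD)
logdet <- function(S) {
  2 * sum(log(diag(chol(S))))
}

#' Distance between two Gaussian class models
#'
#' Computes the chosen distance definition between the considered class `a`
#' (index 1) and the compared class `b` (index 2); `mahalanobis` and
#' `kullback_leibler` are asymmetric in that order.  With
#' `dmu = mu1 - mu2` and pooled `S = (S1 + S2) / 2`:
#'
#' * `mahalanobis`: half the Mahalanobis distance,
#'   `0.5 * sqrt(dmu' S1^-1 dmu)` — only the considered class's covariance.
#' * `modified_mahalanobis`: `0.5 * sqrt(dmu' S^-1 dmu)` — the pooled
#'   covariance of both distributions.
#' * `bhattacharyya`: `sqrt(-0.5 * log(BC))` where `BC` is the Gaussian
#'   Bhattacharyya coefficient, i.e.
#'   `sqrt(0.5 * (dmu' S^-1 dmu / 8 + 0.5 * log(det S / sqrt(det S1 det S2))))`.
#' * `kullback_leibler`:
#'   `0.5 * (tr(S1^-1 S2) + dmu' S1^-1 dmu - d + log(det S1 / det S2))`,
#'   the divergence of the compared distribution from the considered one
#'   (`E_2[log p2/p1]`).
#' * `hellinger`: the squared Hellinger distance `1 - BC`, in `[0, 1]`.
#'
#' @param a,b `gaussian_class_model` objects of equal dimension; `a` is the
#'   considered class.
#' @param def one of [distance_definitions()].
#' @return nonnegative finite scalar.
#' @export
class_distance <- function(a, b, def = distance_definitions()) {
  def <- match.arg(def)
  if (length(a$mu) != length(b$mu)) stop("dimension mismatch")
  dmu <- a$mu - b$mu
  d <- length(dmu)
  switch(def,
    mahalanobis = 0.5 * sqrt(max(0, sum(dmu * solve(a$S, dmu)))),
    modified_mahalanobis = {
      S <- (a$S + b$S) / 2
      0.5 * sqrt(max(0, sum(dmu * solve(S, dmu))))
    },
    bhattacharyya = {
      S <- (a$S + b$S) / 2
      db <- sum(dmu * solve(S, dmu)) / 8 +
        0.5 * (logdet(S) - 0.5 * (logdet(a$S) + logdet(b$S)))
      sqrt(max(0, 0.5 * db))
    },
    hellinger = {
      S <- (a$S + b$S) / 2
      bc <- exp(0.25 * logdet(a$S) + 0.25 * logdet(b$S) -
                  0.5 * logdet(S) - sum(dmu * solve(S, dmu)) / 8)
      min(1, max(0, 1 - bc))
    },
    kullback_leibler = {
      S1inv_S2 <- solve(a$S, b$S)
      max(0, 0.5 * (sum(diag(S1inv_S2)) + sum(dmu * solve(a$S, dmu)) - d +
                      logdet(a$S) - logdet(b$S)))
    }
  )
}

new_cce_result <- function(algorithm, parameters, individual,
                           average = mean(individual), conflict = NULL) {
  structure(list(algorithm = algorithm, parameters = parameters,
                 individual = individual, average = average,
                 conflict = conflict),
            class = "cce_result")
}

#' @export
print.cce_result <- function(x, ...) {
  cat("cce_result [", x$algorithm, "]\n", sep = "")
  for (nm in names(x$individual)) {
    cat(sprintf("  %-16s %.6g", nm, x$individual[[nm]]))
    if (!is.null(x$conflict)) cat("  (vs ", x$conflict[[nm]], ")", sep = "")
    cat("\n")
  }
  cat(sprintf("  %-16s %.6g\n", "average", x$average))
  invisible(x)
}

#' Separability index (SI)
#'
#' For every class, the distance to its most conflicting neighbor — the
#' class minimizing the chosen distance definition from the considered
#' class — is the individual result; the average result is the mean over
#' classes (the class count `K` is recorded in the parameters, so the
#' bare-sum form is recoverable as `average * K`).
#'
#' @param models list of `gaussian_class_model` from [fit_class_models()],
#'   K >= 2.
#' @param def one of [distance_definitions()].
#' @return a `cce_result` with per-class minima, the arg-min recorded as
#'   `conflict` (most conflicting neighbor), and the mean as average.
#' @export
separability_index <- function(models, def = distance_definitions()) {
  def <- match.arg(def)
  K <- length(models)
  if (K < 2L) stop("need at least two classes")
  labels <- vapply(models, `[[`, "", "class")
  individual <- stats::setNames(numeric(K), labels)
  conflict <- stats::setNames(character(K), labels)
  for (i in seq_len(K)) {
    dists <- vapply(setdiff(seq_len(K), i), function(j) {
      class_distance(models[[i]], models[[j]], def)
    }, 0)
    others <- setdiff(seq_len(K), i)
    j_min <- others[which.min(dists)]
    individual[i] <- min(dists)
    conflict[i] <- labels[j_min]
  }
  new_cce_result("si", list(distance = def, K = K), individual,
                 conflict = conflict)
}

#' Nearest neighbor separability (NNS)
#'
#' For every target point, its `k` nearest neighbors (Euclidean, excluding
#' the point itself; ties broken by point index) are ranked by proximity.
#' With `b_i = 1` when neighbor `i` shares the target's class and 0
#' otherwise, the target's dominance is the harmonically weighted mean
#' `d_t = (sum 1/i)^-1 * sum(b_i / i)`.  The individual result of a class
#' is the mean dominance over its points; the average result is the mean
#' over all points.  Values lie in `[0, 1]`.
#'
#' @param fm a [feature_matrix()].
#' @param k neighbors considered (default 120, a value sized to typical
#'   per-class window counts of guided recordings; clamped to N - 1 with a
#'   warning).
#' @param normalization `"none"` (default) or `"zscore"` (per-column
#'   standardization before the distance computation; raw EMG features
#'   have very different scales).
#' @return a `cce_result`.
#' @export
nearest_neighbor_separability <- function(fm, k = 120L,
                                          normalization = c("none", "zscore")) {
  stopifnot(inherits(fm, "feature_matrix"))
  normalization <- match.arg(normalization)
  X <- fm$values
  N <- nrow(X)
  if (k < 1L) stop("k must be >= 1")
  if (k >= N) {
    warning("k = ", k, " >= N = ", N, "; clamped to N - 1")
    k <- N - 1L
  }
  if (normalization == "zscore") {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
  }
  D <- as.matrix(stats::dist(X))
  wts <- 1 / seq_len(k)
  wsum <- sum(wts)
  d_t <- numeric(N)
  for (t in seq_len(N)) {
    ord <- order(D[t, ], seq_len(N))      # stable: index breaks ties
    nb <- ord[ord != t][seq_len(k)]
    b <- fm$class[nb] == fm$class[t]
    d_t[t] <- sum(wts[b]) / wsum
  }
  classes <- unique(fm$class)
  individual <- vapply(classes, function(cl) mean(d_t[fm$class == cl]), 0)
  names(individual) <- classes
  new_cce_result("nns", list(k = k, normalization = normalization, N = N),
                 individual, average = mean(d_t))
}

#' Multiresolution purity
#'
#' The feature hyperspace is bounded per dimension by the data's
#' `[min, max]` and divided into `r` equal bins per dimension (top edge
#' inclusive), forming `r^d` hyper-cuboid cells.  A cell's purity is the
#' largest class fraction among its points; a resolution's purity is the
#' occupancy-weighted mean over non-empty cells, and the overall value is
#' the mean over resolutions.  A class's individual result weights, over
#' the cells that contain it, the fraction of the cell belonging to that
#' class by cell occupancy.
#'
#' @param fm a [feature_matrix()].
#' @param resolutions positive integers (default `1:5`).
#' @return a `cce_result` with values in `[0, 1]`.
#' @export
purity <- function(fm, resolutions = 1:5) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$values
  N <- nrow(X); d <- ncol(X)
  if (N == 0L) stop("empty feature matrix")
  if (any(resolutions < 1L)) stop("resolutions must be positive integers")
  if (max(resolutions)^d > 1e7) {
    stop("resolution too fine for dimensionality (", max(resolutions), "^",
         d, " cells)")
  }
  classes <- unique(fm$class)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- pmax(hi - lo, .Machine$double.eps)
  res_purity <- numeric(length(resolutions))
  indiv_num <- stats::setNames(numeric(length(classes)), classes)
  indiv_den <- stats::setNames(numeric(length(classes)), classes)
  for (ri in seq_along(resolutions)) {
    r <- resolutions[ri]
    bins <- matrix(0L, N, d)
    for (j in seq_len(d)) {
      b <- floor((X[, j] - lo[j]) / span[j] * r)
      b[b >= r] <- r - 1L                  # top edge inclusive
      bins[, j] <- b
    }
    cell <- apply(bins, 1, paste, collapse = ",")
    tab <- table(cell, fm$class)
    occ <- rowSums(tab)
    maxcnt <- apply(tab, 1, max)
    res_purity[ri] <- sum(maxcnt) / N     # occupancy-weighted mean purity
    for (cl in classes) {
      has <- tab[, cl] > 0
      indiv_num[cl] <- indiv_num[cl] + sum(occ[has] * tab[has, cl] / occ[has])
      indiv_den[cl] <- indiv_den[cl] + sum(occ[has])
    }
  }
  individual <- indiv_num / indiv_den
  new_cce_result("purity", list(resolutions = resolutions), individual,
                 average = mean(res_purity))
}

#' Repeatability index (RI)
#'
#' Measures how much a movement's feature cluster drifts between recording
#' repetitions: per movement, a Gaussian model is fit to the first
#' repetition and to each later one, and the individual result is the mean
#' over later repetitions `j` of half the Mahalanobis distance
#' `0.5 * sqrt((mu_j - mu_1)' S_1^-1 (mu_j - mu_1))`.  The average result
#' is the mean over movements.  Lower is more repeatable.
#'
#' @param fm a [feature_matrix()] with at least 2 repetition labels per
#'   class and at least 2 rows per (class, repetition).
#' @param ridge covariance regularization passed to [fit_class_models()].
#' @return a `cce_result`.
#' @export
repeatability_index <- function(fm, ridge = 1e-8) {
  stopifnot(inherits(fm, "feature_matrix"))
  classes <- unique(fm$class)
  individual <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    sel <- fm$class == cl
    reps <- sort(unique(fm$repetition[sel]))
    if (length(reps) < 2L) {
      stop("class ", cl, " has fewer than 2 repetitions")
    }
    models <- lapply(reps, function(r) {
      x <- fm$values[sel & fm$repetition == r, , drop = FALSE]
      if (nrow(x) < 2L) {
        stop("class ", cl, " repetition ", r, " has fewer than 2 rows")
      }
      list(mu = colMeans(x), S = regularize_cov(stats::cov(x), ridge, cl))
    })
    first <- models[[1]]
    dists <- vapply(models[-1], function(m) {
      dmu <- m$mu - first$mu
      0.5 * sqrt(max(0, sum(dmu * solve(first$S, dmu))))
    }, 0)
    individual[cl] <- mean(dists)
  }
  new_cce_result("ri", list(), individual)
}

#' Compute a complexity estimate by name
#'
#' Convenience dispatcher over the four estimators.
#'
#' @param fm a [feature_matrix()].
#' @param algo `"si"`, `"nns"`, `"purity"` or `"ri"`.
#' @param distance distance definition for SI.
#' @param k,normalization NNS parameters.
#' @param resolutions purity resolutions.
#' @param ridge covariance regularization.
#' @return a `cce_result`.
#' @export
complexity_estimate <- function(fm, algo = c("si", "nns", "purity", "ri"),
                                distance = "modified_mahalanobis",
                                k = 120L, normalization = "none",
                                resolutions = 1:5, ridge = 1e-8) {
  algo <- match.arg(algo)
  switch(algo,
    si = separability_index(fit_class_models(fm, ridge), distance),
    nns = nearest_neighbor_separability(fm, k, normalization),
    purity = purity(fm, resolutions),
    ri = repeatability_index(fm, ridge))
}
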