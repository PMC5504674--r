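# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive each quantity from first principles with
# plain loops, sharing no code with the package implementations.

gm <- function(mu, S, class = "x", n = 10L) {
  structure(list(class = class, mu = as.numeric(mu), S = as.matrix(S),
                 n = n),
            class = "gaussian_class_model")
}

random_pd <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.5
}

random_models <- function(K, d, spread = 3) {
  lapply(seq_len(K), function(k) {
    gm(rnorm(d, sd = spread), random_pd(d), class = paste0("c", k))
  })
}

# --- distances, re-derived with dense inverses and determinants ---------
oracle_distance <- function(a, b, def) {
  dmu <- a$mu - b$mu
  Sp <- (a$S + b$S) / 2
  quad <- function(M, v) as.numeric(t(v) %*% solve(M) %*% v)
  if (def == "mahalanobis") {
    0.5 * sqrt(quad(a$S, dmu))
  } else if (def == "modified_mahalanobis") {
    0.5 * sqrt(quad(Sp, dmu))
  } else if (def == "bhattacharyya") {
    bd <- quad(Sp, dmu) / 8 +
      0.5 * log(det(Sp) / sqrt(det(a$S) * det(b$S)))
    sqrt(0.5 * bd)
  } else if (def == "hellinger") {
    bc <- (det(a$S)^0.25 * det(b$S)^0.25 / sqrt(det(Sp))) *
      exp(-quad(Sp, dmu) / 8)
    1 - bc
  } else if (def == "kullback_leibler") {
    0.5 * (sum(diag(solve(a$S) %*% b$S)) + quad(a$S, dmu) -
             length(dmu) + log(det(a$S) / det(b$S)))
  } else {
    stop("unknown def")
  }
}

# --- SI: all-pairs minimum with the oracle distance ---------------------
oracle_si <- function(models, def) {
  K <- length(models)
  indiv <- numeric(K)
  for (i in seq_len(K)) {
    best <- Inf
    for (j in seq_len(K)) {
      if (j == i) next
      best <- min(best, oracle_distance(models[[i]], models[[j]], def))
    }
    indiv[i] <- best
  }
  list(individual = indiv, average = mean(indiv))
}

# --- NNS: O(N^2) loops, harmonic weights, index tie-break ---------------
oracle_nns <- function(X, labels, k) {
  N <- nrow(X)
  d_t <- numeric(N)
  wts <- 1 / seq_len(k)
  for (t in seq_len(N)) {
    dists <- sqrt(rowSums((X - matrix(X[t, ], N, ncol(X), byrow = TRUE))^2))
    ord <- order(dists, seq_len(N))
    ord <- ord[ord != t]
    nb <- ord[seq_len(k)]
    b <- as.numeric(labels[nb] == labels[t])
    d_t[t] <- sum(b * wts) / sum(wts)
  }
  classes <- unique(labels)
  list(individual = vapply(classes, function(cl) mean(d_t[labels == cl]), 0),
       average = mean(d_t))
}

# --- purity: explicit cell enumeration ----------------------------------
oracle_purity <- function(X, labels, resolutions = 1:5) {
  N <- nrow(X); d <- ncol(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- pmax(hi - lo, .Machine$double.eps)
  per_res <- numeric(length(resolutions))
  for (ri in seq_along(resolutions)) {
    r <- resolutions[ri]
    cell_id <- character(N)
    for (i in seq_len(N)) {
      coords <- integer(d)
      for (j in seq_len(d)) {
        b <- floor((X[i, j] - lo[j]) / span[j] * r)
        if (b >= r) b <- r - 1
        coords[j] <- b
      }
      cell_id[i] <- paste(coords, collapse = "/")
    }
    total <- 0
    for (cl in unique(cell_id)) {
      members <- labels[cell_id == cl]
      n_cell <- length(members)
      pur <- max(table(members)) / n_cell
      total <- total + n_cell * pur        # occupancy weight
    }
    per_res[ri] <- total / N
  }
  mean(per_res)
}

# --- small labeled cloud helpers ---------------------------------------
two_cloud_fm <- function(n = 50, sep = 5, d = 2, seed = 1) {
  set.seed(seed)
  x1 <- matrix(rnorm(n * d), n)
  x2 <- matrix(rnorm(n * d), n)
  x2[, 1] <- x2[, 1] + sep
  feature_matrix(rbind(x1, x2), rep(c("A", "B"), each = n))
}

# planted-informative-feature benchmark: n_feat 1-channel features of
# which exactly two (planted) carry class information, the rest iid noise
planted_bank <- function(n_feat = 8, K = 3, n = 60,
                         planted = c(1L, min(2L, n_feat)),
                         sep = 3, seed = 1) {
  means <- matrix(0, K, n_feat)
  means[, planted[1]] <- (seq_len(K) - 1) * sep
  means[, planted[2]] <- rev(seq_len(K) - 1) * sep
  cfg <- cloud_config(means, diag(n_feat), n = n, seed = seed)
  synth_clouds(cfg)
}
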