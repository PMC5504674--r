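#' Rank correlation between complexity estimates and accuracy
#'
#' Pairs complexity estimates with realized classification accuracies over
#' matching table cells and reports Spearman's rho with tie-corrected
#' ranks and a two-sided t-approximation p-value.  In `individual` mode
#' each cell is one (subject, feature, movement); in `average` mode cells
#' are (subject, feature) and multiple observations per cell are averaged
#' first.
#'
#' @param cce_by_cell data.frame with key columns (`subject`, `feature`,
#'   and `movement` for individual mode) and a `value` column of
#'   complexity estimates.
#' @param acc_by_cell same keys with a `value` column of accuracies.
#' @param mode `"individual"` or `"average"`.
#' @return a `correlation_report`: list with `mode`, `n`, `rho`, `p_value`
#'   and the merged `pairs` data.frame.
#' @export
correlate <- function(cce_by_cell, acc_by_cell,
                      mode = c("individual", "average")) {
  mode <- match.arg(mode)
  keys <- if (mode == "individual") {
    c("subject", "feature", "movement")
  } else {
    c("subject", "feature")
  }
  for (df in list(cce_by_cell, acc_by_cell)) {
    miss <- setdiff(c(keys, "value"), names(df))
    if (length(miss)) {
      stop("missing column(s): ", paste(miss, collapse = ", "))
    }
  }
  agg <- function(df) {
    stats::aggregate(df["value"], df[keys], mean)
  }
  a <- agg(cce_by_cell)
  b <- agg(acc_by_cell)
  merged <- merge(a, b, by = keys, suffixes = c(".cce", ".acc"))
  if (nrow(merged) != nrow(a) || nrow(merged) != nrow(b)) {
    stop("key mismatch between CCE and accuracy tables")
  }
  if (nrow(merged) < 3L) stop("need at least 3 paired observations")
  x <- merged$value.cce; y <- merged$value.acc
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("all-constant input: rank correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))         # tie-corrected ranks
  n <- nrow(merged)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(mode = mode, n = n, rho = rho, p_value = p,
                 pairs = merged),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, p = %.3g, %s results)\n",
              x$rho, x$n, x$p_value, x$mode))
  invisible(x)
}

#' Exhaustive best-feature-set search
#'
#' Enumerates every combination of `set_size` features from the feature
#' bank of `fm_full`, builds the combined feature matrix (all channels of
#' each selected feature), computes the average-result complexity
#' estimate, and ranks candidates descending (higher SI/NNS predicts
#' higher accuracy).
#'
#' @param fm_full a [feature_matrix()] containing the full feature bank.
#' @param ccea `"nns"` or `"si"`.
#' @param set_size number of features per candidate set (2, 3 or 4 in
#'   typical use).
#' @param distance SI distance definition (default modified Mahalanobis).
#' @param k NNS neighbor count.
#' @param normalization NNS normalization.
#' @return a `feature_set_report`: list with `ccea`, `set_size`, `best`
#'   (character vector of the winning features) and `ranking` (data.frame
#'   of all candidates with their CCE, sorted descending).
#' @export
best_sets <- function(fm_full, ccea = c("nns", "si"), set_size = 2L,
                      distance = "modified_mahalanobis", k = 120L,
                      normalization = "none") {
  ccea <- match.arg(ccea)
  stopifnot(inherits(fm_full, "feature_matrix"))
  n_feat <- length(fm_full$features)
  if (set_size > n_feat) {
    stop("set_size exceeds the feature bank (", n_feat, ")")
  }
  combos <- utils::combn(fm_full$features, set_size, simplify = FALSE)
  cce <- vapply(combos, function(fs) {
    sub <- fm_select_features(fm_full, fs)
    if (ccea == "nns") {
      nearest_neighbor_separability(sub, k = min(k, nrow(sub$values) - 1L),
                                    normalization = normalization)$average
    } else {
      separability_index(fit_class_models(sub), distance)$average
    }
  }, 0)
  ord <- order(cce, decreasing = TRUE)
  ranking <- data.frame(rank = seq_along(combos),
                        cce = cce[ord], stringsAsFactors = FALSE)
  ranking$features <- combos[ord]
  structure(list(ccea = ccea, set_size = as.integer(set_size),
                 parameters = if (ccea == "si") list(distance = distance)
                 else list(k = k, normalization = normalization),
                 best = combos[[ord[1]]], ranking = ranking),
            class = "feature_set_report")
}

#' @export
print.feature_set_report <- function(x, ...) {
  cat("best ", x$set_size, "-feature set by ", x$ccea, ": ",
      paste(x$best, collapse = " + "),
      sprintf("  (cce = %.5g)\n", x$ranking$cce[1]), sep = "")
  invisible(x)
}

#' Paired comparison of two feature sets' accuracies
#'
#' Two-sided Wilcoxon signed-rank test on paired per-subject accuracy
#' differences.  Zero differences are dropped (Wilcoxon convention).  For
#' up to 25 effective pairs the exact null distribution of the signed-rank
#' sum is computed by convolution over the (possibly tied, midranked)
#' absolute-difference ranks; beyond that a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param accuracies_a,accuracies_b paired numeric vectors (one value per
#'   subject), length >= 5.
#' @param alpha significance level (default 0.05).
#' @return list with `p_value`, `significant`, `direction` (`"a > b"`,
#'   `"b > a"` or `"none"` by median difference) and `n_effective`.
#' @export
compare_sets <- function(accuracies_a, accuracies_b, alpha = 0.05) {
  if (length(accuracies_a) != length(accuracies_b)) {
    stop("paired vectors must have equal length")
  }
  if (length(accuracies_a) < 5L) stop("need at least 5 pairs")
  diffs <- accuracies_b - accuracies_a
  nz <- diffs[diffs != 0]
  if (!length(nz)) stop("all differences zero")
  med <- stats::median(diffs)
  list(p_value = signed_rank_p(nz),
       significant = signed_rank_p(nz) <= alpha,
       direction = if (med > 0) "b > a" else if (med < 0) "a > b" else "none",
       n_effective = length(nz))
}

# two-sided signed-rank p for nonzero differences; exact (tie-tolerant,
# via convolution over doubled midranks) for n <= 25
signed_rank_p <- function(nz) {
  n <- length(nz)
  r <- rank(abs(nz))
  w <- sum(r[nz > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))          # doubled midranks are integers
    tot <- sum(r2)
    f <- numeric(tot + 1L)
    f[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(tot + 1L - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(probs[(w2 + 1L):(tot + 1L)])
    p_le <- sum(probs[seq_len(w2 + 1L)])
    min(1, 2 * min(p_ge, p_le))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sig2)
    2 * stats::pnorm(-abs(z))
  }
}

#' Most-conflicting-neighbor counts
#'
#' Counts, for every movement, how many times it is the most conflicting
#' neighbor (the SI arg-min) of another movement.  Useful to spot a single
#' badly recorded movement degrading the separability of many others.
#'
#' @param models list of `gaussian_class_model` (K >= 2).
#' @param distance SI distance definition.
#' @return data.frame with columns `movement` and `times_conflicting`;
#'   counts sum to K.
#' @export
conflict_report <- function(models, distance = "modified_mahalanobis") {
  if (length(models) < 2L) stop("need at least two classes")
  si <- separability_index(models, distance)
  labels <- vapply(models, `[[`, "", "class")
  counts <- table(factor(si$conflict, levels = labels))
  data.frame(movement = labels,
             times_conflicting = as.integer(counts[labels]),
             stringsAsFactors = FALSE)
}

#' Channel redundancy of a single feature
#'
#' Extracts one feature's window sequence from every channel, computes the
#' Pearson correlation matrix across channels, and returns its
#' determinant: 1 means uncorrelated (informative) channels, 0 fully
#' redundant ones.
#'
#' @param fm a [feature_matrix()] containing the feature (>= 2 channels,
#'   >= 3 windows).
#' @param feature a single feature id present in `fm`.
#' @return scalar in \[0, 1\].
#' @export
channel_correlation_determinant <- function(fm, feature) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$n_channels < 2L) stop("need at least 2 channels")
  if (nrow(fm$values) < 3L) stop("need at least 3 windows")
  sub <- fm_select_features(fm, feature)
  M <- sub$values
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant channel sequence (channel ",
         paste(which(sds == 0), collapse = ", "),
         "): correlation undefined")
  }
  det(stats::cor(M))
}
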