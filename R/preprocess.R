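#' Trim the transient edges of a contraction segment
#'
#' Discards the initial and final `trim_fraction` of a contraction (delayed
#' response at onset, anticipatory relaxation at offset), keeping the
#' central portion: with `L` samples, rows `[round(trim_fraction * L),
#' L - round(trim_fraction * L))` (0-based, half-open; round half away from
#' zero).  The default 15% trim retains the central 70%.
#'
#' @param segment samples x channels numeric matrix.
#' @param trim_fraction fraction in \[0, 0.5) removed from each end
#'   (default 0.15).
#' @return the trimmed matrix.
#' @export
trim_contraction <- function(segment, trim_fraction = 0.15) {
  segment <- as.matrix(segment)
  if (nrow(segment) == 0L) stop("empty segment")
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("empty trim result: trim_fraction must be in [0, 0.5)")
  }
  L <- nrow(segment)
  k <- round_half_away(trim_fraction * L)
  segment[(k + 1L):(L - k), , drop = FALSE]
}

#' Cut a session into labeled sliding windows
#'
#' For each movement, the trimmed contraction repetitions are concatenated
#' and windows of `W = round(window_ms * fs / 1000)` samples are cut every
#' `I = round(increment_ms * fs / 1000)` samples, yielding
#' `floor((L - W) / I) + 1` windows per movement.  A window's repetition
#' label is the repetition containing its first sample; windows may span
#' the seam between consecutive repetitions of the same movement.
#'
#' @param session a [recording_session()].
#' @param window_ms window length in milliseconds (default 200).
#' @param increment_ms window increment in milliseconds (default 50).
#' @param trim_fraction passed to [trim_contraction()] (default 0.15).
#' @return a `window_set`: list with `windows` (list of samples x channels
#'   matrices), `class`, `repetition`, `window_ms`, `increment_ms`,
#'   `sampling_rate_hz`, `channel_names`.
#' @export
window_signal <- function(session, window_ms = 200, increment_ms = 50,
                          trim_fraction = 0.15) {
  validate_session(session)
  if (increment_ms <= 0 || window_ms < increment_ms) {
    stop("need window_ms >= increment_ms > 0")
  }
  fs <- session$sampling_rate_hz
  W <- as.integer(round_half_away(window_ms * fs / 1000))
  I <- as.integer(round_half_away(increment_ms * fs / 1000))
  layout <- session_layout(session)
  windows <- list(); cls <- character(0); reps <- integer(0)
  for (mv in session$movements) {
    segs <- layout[layout$movement == mv, , drop = FALSE]
    trimmed <- lapply(seq_len(nrow(segs)), function(i) {
      trim_contraction(
        session$signal[(segs$start[i] + 1L):segs$end[i], , drop = FALSE],
        trim_fraction)
    })
    lens <- vapply(trimmed, nrow, 0L)
    concat <- do.call(rbind, trimmed)
    L <- nrow(concat)
    if (W > L) stop("signal too short: window (", W,
                    " samples) exceeds concatenated contraction data (",
                    L, ") for movement ", mv)
    starts <- seq.int(0L, L - W, by = I)
    rep_of_sample <- rep(segs$repetition, times = lens)
    for (s0 in starts) {
      windows[[length(windows) + 1L]] <-
        concat[(s0 + 1L):(s0 + W), , drop = FALSE]
      cls <- c(cls, mv)
      reps <- c(reps, rep_of_sample[s0 + 1L])
    }
  }
  structure(list(windows = windows, class = cls, repetition = reps,
                 window_ms = window_ms, increment_ms = increment_ms,
                 sampling_rate_hz = fs,
                 channel_names = session$channel_names),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set:", length(x$windows), "windows of",
      if (length(x$windows)) nrow(x$windows[[1]]) else 0, "samples x",
      if (length(x$windows)) ncol(x$windows[[1]]) else 0, "channels\n")
  invisible(x)
}

#' Split specification for train/validation/test partitioning
#'
#' @param fractions length-3 numeric (train, validation, test), each in
#'   \[0, 1\], summing to 1 (default `c(0.4, 0.2, 0.4)`).
#' @param n_randomizations number of independent re-randomizations for
#'   Monte-Carlo cross-validation (default 10).
#' @param seed integer RNG seed.
#' @return a `split_spec` list.
#' @export
split_spec <- function(fractions = c(0.4, 0.2, 0.4),
                       n_randomizations = 10L, seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) || any(fractions > 1)) {
    stop("fractions must be three values in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(fractions = fractions,
                 n_randomizations = as.integer(n_randomizations),
                 seed = as.integer(seed)),
            class = "split_spec")
}

# largest-remainder apportionment of n rows into the three fractions
apportion <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified random split of a feature matrix
#'
#' Rows are permuted uniformly at random (seeded) and partitioned per class
#' so each class's train/validation/test proportions match the requested
#' fractions (largest-remainder rounding).  The three sets are disjoint and
#' their union is the input.
#'
#' @param fm a [feature_matrix()].
#' @param spec a [split_spec()].
#' @param randomization which of the `n_randomizations` re-randomizations
#'   to produce (1-based); each uses an independent derived seed.
#' @return named list `train`, `validation`, `test` of `feature_matrix`
#'   objects (empty sets have zero rows).
#' @export
split_features <- function(fm, spec = split_spec(), randomization = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) == 0L) stop("empty feature matrix")
  counts <- table(fm$class)
  if (any(counts < 3L) && all(spec$fractions > 0)) {
    stop("class too small to split: ",
         paste(names(counts)[counts < 3L], collapse = ", "))
  }
  if (spec$fractions[2] == 0 || spec$fractions[3] == 0) {
    warning("degenerate split: empty validation and/or test set")
  }
  set.seed(spec$seed + 7919L * (as.integer(randomization) - 1L))
  assign <- integer(nrow(fm$values))
  for (cl in names(counts)) {
    idx <- sample(which(fm$class == cl))
    n3 <- apportion(length(idx), spec$fractions)
    assign[idx[seq_len(n3[1])]] <- 1L
    assign[idx[n3[1] + seq_len(n3[2])]] <- 2L
    assign[idx[n3[1] + n3[2] + seq_len(n3[3])]] <- 3L
  }
  list(train = fm_rows(fm, assign == 1L),
       validation = fm_rows(fm, assign == 2L),
       test = fm_rows(fm, assign == 3L))
}
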