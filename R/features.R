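#' Feature identifiers
#'
#' The closed set of supported EMG features.  Time domain: mean absolute
#' value (`tmabs`), standard deviation (`tstd`), variance (`tvar`),
#' waveform length (`twl`), RMS (`trms`), zero crossings (`tzc`), slope
#' sign changes (`tslpch`), power (`tpwr`), difference absolute mean
#' (`tdam`), maximum fractal length (`tmfl`), Higuchi fractal dimension
#' (`tfdh`), Katz fractal dimension (`tfd`), cardinality (`tcard`), rough
#' entropy (`tren`).  Frequency domain (single-sided rectangular-window
#' DFT): spectral waveform length (`fwl`), mean frequency (`fmn`), median
#' frequency (`fmd`).
#'
#' @return character vector of the 17 feature ids.
#' @export
feature_ids <- function() {
  c("tmabs", "tstd", "tvar", "twl", "trms", "tzc", "tslpch", "tpwr",
    "tdam", "tmfl", "tfdh", "tfd", "tcard", "tren", "fwl", "fmn", "fmd")
}

# single-sided power/magnitude spectrum of a raw (rectangular) window
single_sided_spectrum <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2) + 1L
  mag <- Mod(X[seq_len(half)])
  freq <- (seq_len(half) - 1L) * fs / n
  list(freq = freq, mag = mag, power = mag^2)
}

higuchi_fd <- function(x, kmax = 8L) {
  n <- length(x)
  kmax <- min(kmax, n - 1L)
  if (kmax < 2L) return(1)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq.int(m, n, by = k)
      nm <- length(idx) - 1L
      if (nm < 1L) { Lm[m] <- NA_real_; next }
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  ok <- is.finite(Lk) & Lk > 0
  if (sum(ok) < 2L) return(1)
  stats::coef(stats::lm(log(Lk[ok]) ~ log(1 / seq_len(kmax)[ok])))[[2]]
}

katz_fd <- function(x) {
  n <- length(x)
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  if (L == 0 || d == 0) return(1)
  m <- n - 1
  log10(m) / (log10(m) + log10(d / L))
}

cardinality <- function(x, alpha = 0.01) {
  rng <- max(x) - min(x)
  if (rng == 0) return(0)
  tau <- alpha * rng
  sum(diff(sort(x)) > tau)
}

rough_entropy <- function(x, alpha = 0.01) {
  n <- length(x)
  p <- cardinality(x, alpha) / (n - 1)
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

count_zero_crossings <- function(x, eps = 0) {
  a <- x[-length(x)]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= eps)
}

count_slope_changes <- function(x, eps = 0) {
  if (length(x) < 3L) return(0)
  d1 <- diff(x)
  a <- d1[-length(d1)]; b <- d1[-1]
  sum(a * b < 0 & abs(a) >= eps & abs(b) >= eps)
}

#' Compute one EMG feature on one window of one channel
#'
#' @param x numeric vector, the window samples of a single channel (length
#'   >= 2).
#' @param id a feature id from [feature_ids()].
#' @param fs sampling rate in Hz (required by the frequency-domain
#'   features `fwl`, `fmn`, `fmd`).
#' @param eps deadband threshold for `tzc`/`tslpch` (default 0: strict
#'   sign-change counts, appropriate for low-noise high-resolution ADC
#'   data; raise for noisy recordings).
#' @param alpha threshold fraction of the window range used by
#'   `tcard`/`tren` (default 0.01).
#' @param kmax maximum segment stride for the Higuchi fractal dimension
#'   (default 8).
#' @return a finite scalar.  Constant (zero-variance) windows degrade to
#'   the documented conventions (counts and entropies 0, fractal
#'   dimensions 1, spectral statistics 0) rather than NaN.
#' @export
extract_feature <- function(x, id, fs = NULL, eps = 0, alpha = 0.01,
                            kmax = 8L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("window too short (need >= 2 samples)")
  if (id %in% c("fwl", "fmn", "fmd") && (is.null(fs) || fs <= 0)) {
    stop("frequency-domain feature ", id, " needs a positive sampling rate")
  }
  constant <- (max(x) == min(x))
  switch(id,
    tmabs = mean(abs(x)),
    tstd = stats::sd(x),
    tvar = stats::var(x),
    twl = sum(abs(diff(x))),
    trms = sqrt(mean(x^2)),
    tzc = if (constant) 0 else count_zero_crossings(x, eps),
    tslpch = if (constant) 0 else count_slope_changes(x, eps),
    tpwr = mean(x^2),
    tdam = mean(abs(diff(x))),
    tmfl = {
      ss <- sum(diff(x)^2)
      if (ss == 0) 0 else log10(sqrt(ss))
    },
    tfdh = if (constant) 1 else higuchi_fd(x, kmax),
    tfd = if (constant) 1 else katz_fd(x),
    tcard = if (constant) 0 else cardinality(x, alpha),
    tren = if (constant) 0 else rough_entropy(x, alpha),
    fwl = {
      sp <- single_sided_spectrum(x, fs)
      sum(abs(diff(sp$mag)))
    },
    fmn = {
      sp <- single_sided_spectrum(x, fs)
      tot <- sum(sp$power)
      if (tot == 0 || constant) 0 else sum(sp$freq * sp$power) / tot
    },
    fmd = {
      sp <- single_sided_spectrum(x, fs)
      tot <- sum(sp$power)
      if (tot == 0 || constant) 0 else
        sp$freq[which(cumsum(sp$power) >= tot / 2)[1]]
    },
    stop("unknown feature id: ", id)
  )
}

#' Extract a feature matrix from a window set
#'
#' Row `i` is the concatenation, feature-block by feature-block and channel
#' by channel within each block, of [extract_feature()] applied to window
#' `i`.  Class and repetition labels are copied from the window set.
#'
#' @param ws a `window_set` from [window_signal()].
#' @param features character vector of feature ids (default: all 17).
#' @param fs sampling rate; defaults to the window set's.
#' @param ... passed to [extract_feature()] (`eps`, `alpha`, `kmax`).
#' @return a [feature_matrix()].
#' @export
extract_matrix <- function(ws, features = feature_ids(), fs = NULL, ...) {
  stopifnot(inherits(ws, "window_set"))
  if (!length(ws$windows)) stop("empty window set")
  if (is.null(fs)) fs <- ws$sampling_rate_hz
  bad <- setdiff(features, feature_ids())
  if (length(bad)) stop("unknown feature id: ", paste(bad, collapse = ", "))
  n_ch <- ncol(ws$windows[[1]])
  vals <- matrix(NA_real_, nrow = length(ws$windows),
                 ncol = length(features) * n_ch)
  for (i in seq_along(ws$windows)) {
    w <- ws$windows[[i]]
    row <- tryCatch(
      unlist(lapply(features, function(f) {
        vapply(seq_len(n_ch), function(ch) {
          extract_feature(w[, ch], f, fs = fs, ...)
        }, 0)
      })),
      error = function(e) stop("window ", i, ": ", conditionMessage(e))
    )
    vals[i, ] <- row
  }
  colnames(vals) <- as.vector(vapply(features, function(f) {
    paste0(f, ":", if (is.null(ws$channel_names))
      seq_len(n_ch) else ws$channel_names)
  }, character(n_ch)))
  feature_matrix(vals, ws$class, ws$repetition, features, n_ch)
}
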