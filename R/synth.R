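#' Configuration for a synthetic recording session
#'
#' The synthetic EMG surrogate is zero-phase band-pass-filtered white
#' Gaussian noise, amplitude-modulated per (movement, repetition) segment:
#' during a contraction of movement `m`, channel `c` carries unit-variance
#' band-limited noise scaled by `activation[m, c] + noise_floor`; rest
#' segments carry `noise_floor` alone.  This reproduces the amplitude and
#' spectral cues that EMG feature banks measure without modelling motor
#' units.
#'
#' @param n_movements,n_channels,n_repetitions session geometry (defaults
#'   mirror a typical individual-movement acquisition: 11 movements, 4
#'   channels, 3 repetitions).
#' @param sampling_rate_hz sampling frequency (default 2000 Hz).
#' @param contraction_s,rest_s instructed contraction and rest durations
#'   (default 3 s each).
#' @param activation movements x channels matrix of amplitude gains in
#'   \[0, 1\]; default gives each movement a distinct smooth activation
#'   pattern across channels.
#' @param band_hz length-2 passband in Hz (default 20-500, the usual
#'   surface-EMG band).
#' @param noise_floor baseline amplitude of the always-present sensor noise
#'   (default 0.02).
#' @param seed integer RNG seed.
#' @return a `synth_session_config` list.
#' @export
synth_session_config <- function(n_movements = 11L, n_channels = 4L,
                                 n_repetitions = 3L,
                                 sampling_rate_hz = 2000,
                                 contraction_s = 3, rest_s = 3,
                                 activation = NULL,
                                 band_hz = c(20, 500),
                                 noise_floor = 0.02, seed = 1L) {
  if (is.null(activation)) {
    # distinct smooth per-movement channel profiles
    activation <- outer(seq_len(n_movements), seq_len(n_channels),
                        function(m, c) {
                          0.5 + 0.5 * cos(2 * pi * (m - 1) / n_movements +
                                            pi * (c - 1) / n_channels)
                        })
  }
  activation <- as.matrix(activation)
  if (any(!is.finite(activation)) || any(activation < 0)) {
    stop("activation gains must be finite and >= 0")
  }
  if (nrow(activation) != n_movements || ncol(activation) != n_channels) {
    stop("activation must be n_movements x n_channels")
  }
  if (contraction_s <= 0 || rest_s < 0 || sampling_rate_hz <= 0) {
    stop("durations and sampling rate must be positive")
  }
  structure(list(
    n_movements = as.integer(n_movements),
    n_channels = as.integer(n_channels),
    n_repetitions = as.integer(n_repetitions),
    sampling_rate_hz = sampling_rate_hz,
    contraction_s = contraction_s, rest_s = rest_s,
    activation = activation, band_hz = band_hz,
    noise_floor = noise_floor, seed = as.integer(seed)
  ), class = "synth_session_config")
}

#' Generate a synthetic recording session
#'
#' @param config a [synth_session_config()].
#' @return a [recording_session()]; deterministic given `config$seed`.
#' @export
synth_session <- function(config) {
  stopifnot(inherits(config, "synth_session_config"))
  fs <- config$sampling_rate_hz
  band <- config$band_hz
  nyq <- fs / 2
  if (band[1] >= band[2] || band[2] >= nyq) {
    stop("degenerate band: need low < high < Nyquist (", nyq, " Hz)")
  }
  nc <- round_half_away(fs * config$contraction_s)
  nr <- round_half_away(fs * config$rest_s)
  seg <- nc + nr
  total <- seg * config$n_movements * config$n_repetitions
  set.seed(config$seed)
  bf <- signal::butter(4, band / nyq, type = "pass")
  # per-segment amplitude envelope
  env_col <- function(ch) {
    env <- numeric(total)
    for (m in seq_len(config$n_movements)) {
      for (r in seq_len(config$n_repetitions)) {
        off <- ((m - 1L) * config$n_repetitions + (r - 1L)) * seg
        env[off + seq_len(nc)] <- config$activation[m, ch] +
          config$noise_floor
        if (nr > 0L) env[off + nc + seq_len(nr)] <- config$noise_floor
      }
    }
    env
  }
  sig <- matrix(0, nrow = total, ncol = config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    white <- stats::rnorm(total)
    bl <- as.numeric(signal::filtfilt(bf, white))
    bl <- bl / stats::sd(bl)                   # unit-variance carrier
    sig[, ch] <- bl * env_col(ch)
  }
  recording_session(
    signal = sig, sampling_rate_hz = fs,
    movements = paste0("mov", seq_len(config$n_movements)),
    n_repetitions = config$n_repetitions,
    contraction_s = config$contraction_s, rest_s = config$rest_s
  )
}

#' Configuration for synthetic Gaussian feature clouds
#'
#' Direct generator of labeled multivariate-normal class clouds, for
#' controlled tests of the Gaussian distance definitions and the
#' sample-based complexity estimators.
#'
#' @param means K x d matrix of class means.
#' @param covariances list of K symmetric positive-definite d x d matrices
#'   (a single matrix is recycled to all classes).
#' @param n samples per class.
#' @param n_repetitions repetition labels are assigned by splitting each
#'   class's draw order into this many equal blocks (default 3).
#' @param drift optional per-repetition mean drift: repetition j's samples
#'   get `(j - 1) * drift` added along the first dimension (default 0);
#'   exercises the repeatability index.
#' @param seed integer RNG seed.
#' @return a `cloud_config` list.
#' @export
cloud_config <- function(means, covariances, n = 100L, n_repetitions = 3L,
                         drift = 0, seed = 1L) {
  means <- as.matrix(means)
  K <- nrow(means); d <- ncol(means)
  if (is.matrix(covariances)) covariances <- rep(list(covariances), K)
  if (length(covariances) != K) stop("need one covariance per class")
  for (S in covariances) {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S)))) stop("covariance not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance not positive definite")
  }
  if (n <= d) warning("samples per class <= dimensionality; ",
                      "covariance estimates will be singular")
  structure(list(means = means, covariances = lapply(covariances, as.matrix),
                 n = as.integer(n), n_repetitions = as.integer(n_repetitions),
                 drift = drift, seed = as.integer(seed)),
            class = "cloud_config")
}

#' Draw synthetic Gaussian class clouds
#'
#' @param config a [cloud_config()].
#' @return a [feature_matrix()] with `n` rows per class, classes labeled
#'   `class1..classK`, repetition labels block-wise in draw order.
#' @export
synth_clouds <- function(config) {
  stopifnot(inherits(config, "cloud_config"))
  K <- nrow(config$means); d <- ncol(config$means)
  set.seed(config$seed)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    x <- MASS::mvrnorm(config$n, mu = config$means[k, ],
                       Sigma = config$covariances[[k]])
    x <- matrix(x, ncol = d)
    rep_lab <- rep(seq_len(config$n_repetitions),
                   each = ceiling(config$n / config$n_repetitions),
                   length.out = config$n)
    if (config$drift != 0) {
      x[, 1] <- x[, 1] + (rep_lab - 1L) * config$drift
    }
    rows[[k]] <- list(x = x, rep = rep_lab)
  }
  values <- do.call(rbind, lapply(rows, `[[`, "x"))
  feature_matrix(values,
                 class = rep(paste0("class", seq_len(K)), each = config$n),
                 repetition = unlist(lapply(rows, `[[`, "rep")),
                 features = paste0("dim", seq_len(d)), n_channels = 1L)
}

#' Sweep class separation over synthetic clouds
#'
#' Produces one cloud per separation value by scaling all class means about
#' their centroid: `mu_k(s) = centroid + s * (mu_k - centroid)`.  Separation
#' 0 collapses every class onto the same distribution (chance level);
#' increasing `s` moves the classes apart along fixed directions.
#'
#' @param base a [cloud_config()] defining means at separation 1.
#' @param separations numeric vector of nonnegative scale factors.
#' @return a list of [feature_matrix()] objects, one per separation, with
#'   the separation attached as attribute `"separation"`.
#' @export
separation_sweep <- function(base, separations) {
  stopifnot(inherits(base, "cloud_config"))
  if (!length(separations)) stop("empty separations list")
  centroid <- colMeans(base$means)
  lapply(seq_along(separations), function(i) {
    s <- separations[i]
    mk <- sweep(sweep(base$means, 2, centroid) * s, 2, centroid, `+`)
    cfg <- cloud_config(mk, base$covariances, n = base$n,
                        n_repetitions = base$n_repetitions,
                        drift = base$drift, seed = base$seed + i - 1L)
    fm <- synth_clouds(cfg)
    attr(fm, "separation") <- s
    fm
  })
}
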