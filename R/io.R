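#' Read a recording session from disk
#'
#' Two dialects are supported.  The native dialect is a directory holding
#' `session.json` (acquisition metadata) and `signal.csv` (one row per
#' sample, one column per channel, header = channel names).  The
#' `biopatrec_mat` dialect imports a MATLAB MAT-file containing a
#' `recSession` record as distributed with BioPatRec-style recording tools;
#' field names are mapped leniently (see [read_biopatrec_mat()]).
#'
#' @param path directory (native) or `.mat` file (biopatrec_mat).
#' @param dialect `"native"` or `"biopatrec_mat"`.
#' @return a validated [recording_session()].
#' @export
read_session <- function(path, dialect = c("native", "biopatrec_mat")) {
  dialect <- match.arg(dialect)
  if (dialect == "biopatrec_mat") {
    return(read_biopatrec_mat(path))
  }
  meta_path <- file.path(path, "session.json")
  sig_path <- file.path(path, "signal.csv")
  if (!file.exists(meta_path) || !file.exists(sig_path)) {
    stop("malformed session: expected session.json and signal.csv under ",
         path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("sampling_rate_hz", "movements", "n_repetitions",
            "contraction_s", "rest_s", "channel_names")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("malformed session: session.json missing field(s) ",
         paste(miss, collapse = ", "))
  }
  sig <- as.matrix(as.data.frame(data.table::fread(sig_path, header = TRUE)))
  if (ncol(sig) != length(meta$channel_names)) {
    stop("inconsistent session: metadata declares ",
         length(meta$channel_names), " channels but signal has ",
         ncol(sig), " columns")
  }
  recording_session(
    signal = sig,
    sampling_rate_hz = meta$sampling_rate_hz,
    movements = meta$movements,
    n_repetitions = meta$n_repetitions,
    contraction_s = meta$contraction_s,
    rest_s = meta$rest_s,
    channel_names = meta$channel_names,
    adc_bits = meta$adc_bits
  )
}

#' Write a recording session in the native dialect
#'
#' Produces `session.json` and `signal.csv` under `path` (created if
#' needed).  [read_session()] on the result restores the session up to
#' floating-point text representation.
#'
#' @param session a valid [recording_session()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (length(session$movements) == 0L) stop("malformed session: no movements")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    sampling_rate_hz = session$sampling_rate_hz,
    movements = session$movements,
    n_repetitions = session$n_repetitions,
    contraction_s = session$contraction_s,
    rest_s = session$rest_s,
    channel_names = session$channel_names
  )
  if (!is.null(session$adc_bits)) meta$adc_bits <- session$adc_bits
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  df <- as.data.frame(session$signal)
  names(df) <- session$channel_names
  data.table::fwrite(df, file.path(path, "signal.csv"))
  invisible(path)
}

#' Write a complexity or feature-set report
#'
#' Lossless serialization of [cce_result] objects, feature-set reports and
#' plain tables to JSON or CSV.  JSON keeps the full structure (per-movement
#' values, average, algorithm metadata); CSV flattens to one row per
#' movement (CCE results) or one row per candidate set (feature-set
#' reports).
#'
#' @param report a `cce_result`, `feature_set_report`, or data.frame.
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(report, "cce_result")) {
    if (format == "json") {
      out <- list(
        algorithm = report$algorithm,
        parameters = report$parameters,
        individual = as.list(report$individual),
        average = report$average
      )
      if (!is.null(report$conflict)) out$conflict <- as.list(report$conflict)
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      df <- data.frame(movement = names(report$individual),
                       value = unname(report$individual),
                       stringsAsFactors = FALSE)
      if (!is.null(report$conflict)) {
        df$most_conflicting <- unname(report$conflict)
      }
      df <- rbind(df, data.frame(movement = "average",
                                 value = report$average,
                                 most_conflicting = if (is.null(report$conflict)) NULL else NA)
                  [, names(df), drop = FALSE])
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else if (inherits(report, "feature_set_report")) {
    df <- report$ranking
    df$features <- vapply(df$features, paste, "", collapse = "+")
    if (format == "json") {
      jsonlite::write_json(
        list(ccea = report$ccea, set_size = report$set_size,
             best = report$best, ranking = df),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else if (is.data.frame(report)) {
    if (format == "json") {
      jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      utils::write.csv(report, path, row.names = FALSE)
    }
  } else {
    stop("unknown report type: ", paste(class(report), collapse = "/"))
  }
  invisible(path)
}
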