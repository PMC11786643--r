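#' Multichannel physiological recording
#'
#' Container for a simultaneously sampled EEG/ECG trial: a channels-by-samples
#' numeric matrix plus its sampling rate, channel labels and per-channel kind
#' tags. EEG samples are conventionally in microvolts and ECG in millivolts;
#' the connectivity estimators are scale-invariant so no unit conversion is
#' performed.
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of channel names, one per row.
#' @param kinds per-channel tag, each `"EEG"` or `"ECG"`. If `NULL`, inferred
#'   from labels: names starting with `EXG` (or `ECG`) are tagged ECG, all
#'   others EEG.
#' @param emotion optional trial label, one of `"happiness"`, `"disgust"`,
#'   `"fear"`, `"sadness"`.
#' @param subject_id optional subject identifier.
#' @return an object of class `mc_recording`.
#' @export
recording <- function(samples, fs, labels = NULL, kinds = NULL,
                      emotion = NULL, subject_id = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  m <- nrow(samples)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(m))
  if (length(labels) != m)
    stop("length(labels) [", length(labels), "] != number of channels [", m, "]")
  if (is.null(kinds)) kinds <- infer_kinds(labels)
  if (length(kinds) != m)
    stop("length(kinds) [", length(kinds), "] != number of channels [", m, "]")
  if (!all(kinds %in% c("EEG", "ECG")))
    stop("kinds must be 'EEG' or 'ECG'; got: ",
         paste(unique(setdiff(kinds, c("EEG", "ECG"))), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (!is.null(emotion)) emotion <- match.arg(emotion, emotion_classes())
  structure(
    list(samples = samples, fs = as.numeric(fs),
         labels = as.character(labels), kinds = as.character(kinds),
         emotion = emotion, subject_id = subject_id),
    class = "mc_recording")
}

#' The four emotional state labels
#' @return character vector of the class names, in canonical order.
#' @export
emotion_classes <- function() c("happiness", "disgust", "fear", "sadness")

infer_kinds <- function(labels) {
  ifelse(grepl("^(EXG|ECG)", labels, ignore.case = TRUE), "ECG", "EEG")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d channels (%d EEG, %d ECG), %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), sum(x$kinds == "EEG"), sum(x$kinds == "ECG"),
              ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  if (!is.null(x$emotion)) cat("  emotion:", x$emotion, "\n")
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$samples)

assert_recording <- function(rec) {
  if (!inherits(rec, "mc_recording")) stop("expected an mc_recording object")
  if (any(!is.finite(rec$samples))) stop("recording contains NaN/Inf samples")
  invisible(rec)
}

#' Read a multichannel recording from disk
#'
#' Supported formats: BioSemi BDF (24-bit), EDF/EDF+ (16-bit), and the
#' package's plain-text matrix format (see [write_recording_matrix()]).
#' Format is inferred from the file extension when `format = "auto"`.
#'
#' @param path file path.
#' @param format `"auto"`, `"bdf"`, `"edf"` or `"matrix"`.
#' @param kinds optional explicit per-channel kind override (`"EEG"`/`"ECG"`);
#'   by default kinds are inferred from labels (`EXG*`/`ECG*` are ECG).
#' @return an [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "bdf", "edf", "matrix"),
                           kinds = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bdf = "bdf", edf = "edf",
                     txt = "matrix", mat = "matrix", tsv = "matrix",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  rec <- switch(format,
    bdf = read_edf_file(path, bdf = TRUE),
    edf = read_edf_file(path, bdf = FALSE),
    matrix = read_recording_matrix(path))
  if (!is.null(kinds)) rec$kinds <- kinds
  if (n_channels(rec) < 2L)
    stop("recording has fewer than 2 channels: ", path)
  assert_recording(rec)
}

#' Write / read the plain-text matrix recording format
#'
#' A self-describing text format: `#` header lines carry `fs`, `labels`,
#' `kinds` and optional `emotion`/`subject` metadata; each subsequent line is
#' one channel's samples, whitespace-separated.
#'
#' @param rec an [recording()] object.
#' @param path destination file.
#' @param digits significant digits written (default 10).
#' @return `path`, invisibly (writer); an `mc_recording` (reader).
#' @export
write_recording_matrix <- function(rec, path, digits = 10) {
  assert_recording(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#fs %.10g", rec$fs),
    paste("#labels", paste(rec$labels, collapse = " ")),
    paste("#kinds", paste(rec$kinds, collapse = " ")),
    if (!is.null(rec$emotion)) paste("#emotion", rec$emotion),
    if (!is.null(rec$subject_id)) paste("#subject", rec$subject_id)), con)
  apply(rec$samples, 1L, function(row)
    writeLines(paste(formatC(row, digits = digits, format = "g"),
                     collapse = " "), con))
  invisible(path)
}

#' @rdname write_recording_matrix
#' @export
read_recording_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_hdr <- function(key) {
    hit <- grep(paste0("^#", key, " "), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^#", key, " +"), "", hit[[1L]])
  }
  fs <- get_hdr("fs")
  if (is.null(fs)) stop("matrix format error: missing '#fs' header in ", path)
  labels <- strsplit(get_hdr("labels") %||% "", " +")[[1L]]
  kinds <- get_hdr("kinds")
  if (!is.null(kinds)) kinds <- strsplit(kinds, " +")[[1L]]
  samples <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]])))
  if (length(labels) && length(labels) != nrow(samples))
    stop("matrix format error: ", length(labels), " labels but ",
         nrow(samples), " channel rows in ", path)
  recording(samples, as.numeric(fs),
            labels = if (length(labels)) labels else NULL,
            kinds = kinds, emotion = get_hdr("emotion"),
            subject_id = get_hdr("subject"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
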