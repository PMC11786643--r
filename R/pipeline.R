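#' Recordings to labeled connectivity-image dataset
#'
#' Convenience glue over the whole estimation chain: each recording is
#' preprocessed (band-pass, decimation, common average reference, windowing,
#' stationarity flagging), per-window connectivity is estimated for one
#' method and one band, matrices are put in canonical channel order when the
#' montage matches, and rendered to colour images.
#'
#' @param recordings list of labeled [recording()] objects.
#' @param method `"DTF"`, `"PDC"` or `"GC"`.
#' @param band a [band_definition()] (default alpha).
#' @param order MVAR order (default 10).
#' @param size rendered image edge length; default 35 = native matrix
#'   resolution (upscaling adds no information, only pixels).
#' @param target_fs,band_limits,window_ms,overlap preprocessing settings.
#' @param drop_nonstationary drop windows failing the variance-ratio test.
#' @param diagnostics diagnostics level per window (see
#'   [window_connectivity()]).
#' @param progress print a line per recording.
#' @return an [image_dataset()] (labels = recording emotions, subjects
#'   carried through).
#' @export
build_image_dataset <- function(recordings, method = "DTF",
                                band = band_definitions()$alpha, order = 10,
                                size = 35, target_fs = 128,
                                band_limits = c(0.5, 45), window_ms = 5000,
                                overlap = 0.5, drop_nonstationary = FALSE,
                                diagnostics = "stability", progress = FALSE) {
  images <- list()
  labels <- character()
  subjects <- character()
  canon <- canonical_montage()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    if (is.null(rec$emotion)) stop("recording ", ri, " has no emotion label")
    wins <- preprocess(rec, band = band_limits, target_fs = target_fs,
                       window_ms = window_ms, overlap = overlap,
                       drop_nonstationary = drop_nonstationary)
    for (w in wins) {
      cms <- window_connectivity(w, method = method, bands = list(band),
                                 order = order, diagnostics = diagnostics)
      if (!length(cms)) next                    # unstable fit, skipped
      cm <- cms[[1L]]
      if (setequal(cm$labels, canon)) cm <- order_channels(cm, canon)
      images[[length(images) + 1L]] <- render_image(cm, size = size)
      labels <- c(labels, rec$emotion)
      subjects <- c(subjects, rec$subject_id %||% NA_character_)
    }
    if (progress)
      message(sprintf("[%d/%d] %s: %d windows", ri, length(recordings),
                      rec$emotion, length(wins)))
  }
  if (!length(images)) stop("no connectivity images produced")
  image_dataset(images, factor(labels, levels = intersect(emotion_classes(),
                                                          unique(labels))),
                subjects = subjects)
}

#' Save a dataset's images as a PNG directory tree
#'
#' Layout: `<out>/<band>/<method>/<emotion>/<subject>_<index>.png`.
#'
#' @param dataset an [image_dataset()] of `connectivity_image`s.
#' @param out root output directory.
#' @return character vector of written paths, invisibly.
#' @export
save_image_dataset <- function(dataset, out) {
  paths <- character(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    img <- dataset$images[[i]]
    dir_ <- file.path(out, img$meta$band, img$meta$method,
                      as.character(dataset$labels[i]))
    dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
    subj <- dataset$subjects[i] %||% "S00"
    paths[i] <- file.path(dir_, sprintf("%s_%05d.png", subj, i))
    save_image(img, paths[i])
  }
  invisible(paths)
}
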