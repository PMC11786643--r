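#' Per-band directed connectivity for one analysis window
#'
#' The PDC/DTF path fits one joint MVAR model to the window (order 10 by
#' default), evaluates the spectral coefficient/transfer matrices on a
#' 0.25 Hz grid, and band-averages the per-frequency coupling matrices.
#' The GC path computes pairwise time-domain Granger causality per band with
#' band-pass pre-filtering. Model diagnostics are attached per the
#' `diagnostics` level; windows whose joint fit is unstable are skipped with
#' a warning.
#'
#' @param win a `window_segment` (canonically 35 channels; any m >= 2 is
#'   accepted with a montage warning).
#' @param method `"DTF"`, `"PDC"` or `"GC"`.
#' @param bands list of [band_definition()]s (default the five standard
#'   bands); for GC, `NULL` computes one broadband matrix.
#' @param order MVAR order (default 10, the standard choice for this
#'   pipeline).
#' @param freqs frequency grid for the spectral path.
#' @param diagnostics `"stability"` (default: companion spectral radius
#'   only), `"full"` (adds whiteness and consistency) or `"none"`.
#' @param pdc_squared use squared PDC values.
#' @param singular_ok tolerate exact collinearity in the joint fit (the
#'   common-average-referenced montage requires this; see [fit_mvar()]).
#' @return list of `connectivity_matrix` objects, one per band (empty if the
#'   window was skipped as unstable).
#' @export
window_connectivity <- function(win, method = c("DTF", "PDC", "GC"),
                                bands = band_definitions(), order = 10,
                                freqs = NULL,
                                diagnostics = c("stability", "full", "none"),
                                pdc_squared = FALSE, singular_ok = TRUE) {
  method <- match.arg(method)
  diagnostics <- match.arg(diagnostics)
  win <- as_window_checked(win)
  m <- nrow(win$samples)
  if (m < 2L) stop("need at least 2 channels")
  if (!setequal(win$labels, canonical_montage()))
    warning("non-canonical montage (", m, " channels); proceeding anyway")
  meta <- list(start_s = win$start_s, emotion = win$emotion,
               subject = win$subject_id, order = order,
               orientation = "rows=target, cols=source")

  if (method == "GC") {
    if (is.null(bands)) {
      gcm <- granger_pairwise(win, order = order, band = NULL)
      return(list(connectivity_matrix(gcm, "GC", "broadband",
                                      labels = win$labels, kinds = win$kinds,
                                      meta = meta)))
    }
    return(lapply(bands, function(b) {
      gcm <- granger_pairwise(win, order = order, band = b)
      connectivity_matrix(gcm, "GC", b$name, labels = win$labels,
                          kinds = win$kinds, meta = meta)
    }))
  }

  model <- fit_mvar(win, order = order, singular_ok = singular_ok)
  if (diagnostics != "none") {
    diag_ <- if (diagnostics == "full") validate_mvar(model, win)
             else check_stability(model)
    meta$diagnostics <- diag_
    if (!diag_$stable) {
      warning("unstable MVAR fit (spectral radius ",
              signif(diag_$spectral_radius, 4), "); window skipped")
      return(list())
    }
  }
  if (is.null(freqs)) {            # grid points inside any requested band
    freqs <- default_freq_grid(win$fs)
    in_band <- Reduce(`|`, lapply(bands, function(b)
      freqs >= b$f_lo & freqs < b$f_hi))
    freqs <- freqs[in_band]
  }
  st <- spectral_coefficients(model, freqs)
  stack <- if (method == "PDC") pdc(st, squared = pdc_squared) else dtf(st)
  lapply(bands, function(b)
    band_average(stack, freqs, b, method = method, labels = win$labels,
                 kinds = win$kinds, meta = meta))
}
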