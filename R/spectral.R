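#' Spectral MVAR coefficient and transfer matrices
#'
#' Evaluates the frequency-domain coefficient matrix
#' `Abar(f) = I - sum_r A[r] exp(-i 2 pi (f/fs) r)` and the transfer matrix
#' `H(f) = Abar(f)^{-1}` on a frequency grid. `Abar(0)` equals
#' `I - sum_r A[r]` exactly.
#'
#' @param model a stable `mvar_model`.
#' @param freqs frequency grid in Hz, within `[0, fs/2]`.
#' @return object of class `spectral_transfer`: `freqs`, complex arrays
#'   `Abar` and `H` of dim `m x m x n_freq`, plus `fs` and `labels`.
#' @export
spectral_coefficients <- function(model, freqs = default_freq_grid(model$fs)) {
  stopifnot(inherits(model, "mvar_model"))
  if (any(freqs < 0 | freqs > model$fs / 2))
    stop("frequencies must lie in [0, fs/2]")
  m <- nrow(model$sigma); P <- model$order
  Abar <- array(0i, c(m, m, length(freqs)))
  H <- array(0i, c(m, m, length(freqs)))
  I <- diag(m)
  for (k in seq_along(freqs)) {
    ph <- exp(-2i * pi * (freqs[k] / model$fs) * seq_len(P))
    Af <- I + 0i
    for (r in seq_len(P)) Af <- Af - model$A[[r]] * ph[r]
    Hf <- tryCatch(solve(Af), error = function(e)
      stop("singular spectral coefficient matrix at f = ", freqs[k],
           " Hz (near-unit-root model)"))
    Abar[, , k] <- Af
    H[, , k] <- Hf
  }
  structure(list(freqs = freqs, Abar = Abar, H = H, fs = model$fs,
                 labels = model$labels, kinds = model$kinds),
            class = "spectral_transfer")
}

#' Default analysis frequency grid
#'
#' 0.25 Hz spacing from 0.25 Hz up to 45 Hz (capped below Nyquist), giving at
#' least 19 grid points in the narrowest analysis band.
#'
#' @param fs sampling rate in Hz.
#' @return numeric vector of frequencies.
#' @export
default_freq_grid <- function(fs) {
  seq(0.25, min(45, fs / 2 - 0.25), by = 0.25)
}

#' Partial directed coherence
#'
#' Column-normalized magnitude of the spectral coefficient matrix:
#' `pi_ij(f) = |Abar_ij(f)| / sqrt(sum_m |Abar_mj(f)|^2)` (the standard
#' Baccala-Sameshima form, with the square root in the denominator, which
#' guarantees values in `[0, 1]` and the per-column quadratic normalization
#' `sum_i pi_ij(f)^2 = 1`). Set `squared = TRUE` for the squared variant.
#'
#' @param st a `spectral_transfer`.
#' @param squared return squared PDC values.
#' @return real array `m x m x n_freq`, entry `[i, j, k]` = coupling from
#'   source j to target i at `st$freqs[k]`.
#' @export
pdc <- function(st, squared = FALSE) {
  stopifnot(inherits(st, "spectral_transfer"))
  mag2 <- Mod(st$Abar)^2
  out <- array(0, dim(mag2))
  for (k in seq_len(dim(mag2)[3L])) {
    cn <- colSums(mag2[, , k, drop = FALSE][, , 1L])
    if (any(cn <= 0))
      stop("degenerate model: zero column norm in Abar at f = ",
           st$freqs[k], " Hz")
    out[, , k] <- sweep(Mod(st$Abar[, , k]), 2L, sqrt(cn), "/")
  }
  if (squared) out <- out^2
  out
}

#' Directed transfer function
#'
#' Row-normalized magnitude of the transfer matrix:
#' `DTF_ij(f) = |H_ij(f)| / sqrt(sum_m |H_im(f)|^2)`; values in `[0, 1]`
#' with per-row quadratic normalization `sum_j DTF_ij(f)^2 = 1`. Unlike PDC,
#' DTF transmits cascaded (indirect) influence because `H` is the inverse of
#' `Abar`.
#'
#' @param st a `spectral_transfer`.
#' @return real array `m x m x n_freq` (target in rows, source in columns).
#' @export
dtf <- function(st) {
  stopifnot(inherits(st, "spectral_transfer"))
  mag2 <- Mod(st$H)^2
  out <- array(0, dim(mag2))
  for (k in seq_len(dim(mag2)[3L])) {
    rn <- rowSums(mag2[, , k, drop = FALSE][, , 1L])
    if (any(rn <= 0))
      stop("degenerate model: zero row norm in H at f = ", st$freqs[k], " Hz")
    out[, , k] <- sweep(Mod(st$H[, , k]), 1L, sqrt(rn), "/")
  }
  out
}

#' The five standard EEG analysis bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz
#' (disjoint, ordered; configurable by building your own list of
#' [band_definition()]s).
#'
#' @return named list of `band_definition`s.
#' @export
band_definitions <- function() {
  list(delta = band_definition("delta", 0.5, 4),
       theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 30, 45))
}

#' @rdname band_definitions
#' @param name band name.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (f_lo < 0 || f_lo >= f_hi) stop("need 0 <= f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' Average a per-frequency coupling stack over a band
#'
#' Arithmetic mean of the per-frequency matrices over grid points with
#' `f_lo <= f < f_hi`.
#'
#' @param stack real array `m x m x n_freq` (e.g. from [pdc()] or [dtf()]).
#' @param freqs the frequency grid of `stack`.
#' @param band a `band_definition`.
#' @param method method tag for the result (`"PDC"`, `"DTF"`, `"GC"`).
#' @param labels,kinds channel metadata.
#' @param meta optional provenance list.
#' @return a `connectivity_matrix`.
#' @export
band_average <- function(stack, freqs, band, method, labels = NULL,
                         kinds = NULL, meta = list()) {
  stopifnot(inherits(band, "band_definition"))
  sel <- which(freqs >= band$f_lo & freqs < band$f_hi)
  if (!length(sel))
    stop("band '", band$name, "' [", band$f_lo, ", ", band$f_hi,
         ") overlaps no grid frequencies")
  vals <- apply(stack[, , sel, drop = FALSE], c(1L, 2L), mean)
  connectivity_matrix(vals, method = method, band = band$name,
                      labels = labels, kinds = kinds, meta = meta)
}

#' Directed-coupling matrix container
#'
#' Orientation: rows are targets (sinks), columns are sources. PDC/DTF
#' values lie in `[0, 1]`; GC values in `[0, Inf)`.
#'
#' @param values m-by-m non-negative matrix.
#' @param method `"GC"`, `"PDC"` or `"DTF"`.
#' @param band band name.
#' @param labels,kinds channel metadata.
#' @param meta provenance list (window start, emotion, subject, ...).
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, method, band, labels = NULL,
                                kinds = NULL, meta = list()) {
  values <- as.matrix(values)
  m <- nrow(values)
  if (ncol(values) != m) stop("values must be square")
  if (any(!is.finite(values))) stop("non-finite connectivity values")
  if (any(values < 0)) stop("negative connectivity values")
  method <- match.arg(method, c("GC", "PDC", "DTF"))
  labels <- labels %||% sprintf("ch%02d", seq_len(m))
  dimnames(values) <- list(target = labels, source = labels)
  structure(list(values = values, method = method, band = band,
                 labels = labels, kinds = kinds %||% rep("EEG", m),
                 meta = meta),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s / %s band, %d x %d (rows=target, cols=source)\n",
              x$method, x$band, nrow(x$values), ncol(x$values)))
  invisible(x)
}
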