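#' Pairwise time-domain Granger causality
#'
#' For every ordered channel pair (target x, source y) compares the residual
#' variance of a restricted univariate AR(P) model of x against the full
#' bivariate VAR(P) model of (x, y):
#' `GC_{y->x} = ln(V_restricted / V_full)`, clipped below at 0. Matrix entry
#' `[i, j]` is `GC_{j->i}`; the diagonal is 0 by convention. When `band` is
#' given the window is zero-phase band-pass filtered to that band first
#' (GC is a time-domain quantity; per-band GC is obtained by pre-filtering,
#' which can bias GC slightly - see the methods vignette).
#'
#' @param win a `window_segment` (or channels-by-samples matrix).
#' @param order AR model order P for both restricted and full fits.
#' @param band optional [band_definition()] for band-limited GC.
#' @return m-by-m non-negative matrix (rows = target, cols = source).
#' @export
granger_pairwise <- function(win, order, band = NULL) {
  win <- as_window_checked(win)
  x <- win$samples
  m <- nrow(x); n <- ncol(x); P <- as.integer(order)
  if (n <= 2L * P + P) stop("window too short for bivariate order-", P, " fits")
  if (!is.null(band)) {
    stopifnot(inherits(band, "band_definition"))
    lo <- band$f_lo; hi <- min(band$f_hi, win$fs / 2 * 0.98)
    gain <- function(f) {
      w <- ifelse(f > 0, (f^2 - lo * hi) / (f * (hi - lo)), Inf)
      1 / (1 + w^8)
    }
    x <- t(apply(x, 1L, fft_apply_gain, fs = win$fs, gain = gain))
  }

  resid_var <- function(xm) {                  # ML residual variances
    fit <- mvar_ols(xm, P, skip = P)
    colSums(fit$E^2) / nrow(fit$E)
  }

  v_restricted <- vapply(seq_len(m), function(i)
    tryCatch(resid_var(x[i, , drop = FALSE]),
             error = function(e) stop("restricted fit failed for channel ",
                                      win$labels[i], ": ", conditionMessage(e))),
    numeric(1))

  gc <- matrix(0, m, m, dimnames = list(target = win$labels,
                                        source = win$labels))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      v_full <- tryCatch(resid_var(x[c(i, j), , drop = FALSE]),
                         error = function(e)
                           stop("full fit failed for pair (", win$labels[i],
                                ", ", win$labels[j], "): ", conditionMessage(e)))
      gc[i, j] <- max(0, log(v_restricted[i] / v_full[1L]))  # j -> i
      gc[j, i] <- max(0, log(v_restricted[j] / v_full[2L]))  # i -> j
    }
  }
  gc
}
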