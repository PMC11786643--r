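#' Fit a multivariate autoregressive (MVAR) model to a window
#'
#' Multivariate ordinary least squares on the lag-stacked regression
#' `x(t) = sum_r A[r] x(t-r) + e(t)`. Channel means are removed before
#' fitting. The residual covariance uses denominator `n_eff - m*P`.
#'
#' After common-average re-referencing the EEG block is exactly collinear
#' (one redundant direction per lag). By default such rank deficiency is an
#' error naming the channels involved; with `singular_ok = TRUE` the aliased
#' regression directions are pinned to zero via pivoted QR, a deterministic
#' representative of the least-squares solution set (fitted values and
#' residuals are unique regardless).
#'
#' @param win a `window_segment`, `mc_recording`, or channels-by-samples
#'   matrix (pass `fs` via an `mc_recording`/`window_segment` for spectral
#'   use downstream).
#' @param order model order P (number of lags).
#' @param singular_ok tolerate an exactly rank-deficient regressor matrix.
#' @return an object of class `mvar_model` with fields `order`, `A` (list of
#'   P coefficient matrices, entry `[i, j]` = influence of channel j on
#'   channel i), `sigma`, `fs`, `labels`, `kinds`, `diagnostics`.
#' @export
fit_mvar <- function(win, order, singular_ok = FALSE) {
  win <- as_window_checked(win)
  x <- win$samples
  m <- nrow(x); n <- ncol(x); P <- as.integer(order)
  if (P < 1L) stop("order must be >= 1")
  if (n <= m * P + P)
    stop("window too short: need n > m*P + P = ", m * P + P, ", have ", n)
  vars <- apply(x, 1L, stats::var)
  if (any(vars <= 0))
    stop("singular fit: zero-variance channel(s): ",
         paste(win$labels[vars <= 0], collapse = ", "))
  fit <- mvar_ols(x, P, skip = P)
  if (fit$rank < ncol(fit$X)) {
    bad_cols <- fit$aliased
    bad_ch <- unique(win$labels[((bad_cols - 1L) %% m) + 1L])
    if (!singular_ok)
      stop("singular fit: rank-deficient regressors (", ncol(fit$X) - fit$rank,
           " aliased column(s)) involving channel(s): ",
           paste(bad_ch, collapse = ", "))
  }
  n_eff <- nrow(fit$Y)
  sigma <- crossprod(fit$E) / (n_eff - m * P)
  sigma <- (sigma + t(sigma)) / 2
  A <- lapply(seq_len(P), function(r) {
    Ar <- t(fit$B[(r - 1L) * m + seq_len(m), , drop = FALSE])
    dimnames(Ar) <- list(win$labels, win$labels)
    Ar
  })
  structure(list(order = P, A = A, sigma = sigma, fs = win$fs,
                 labels = win$labels, kinds = win$kinds,
                 n_eff = n_eff, diagnostics = NULL),
            class = "mvar_model")
}

as_window_checked <- function(win) {
  w <- if (inherits(win, "window_segment")) win else as_window(win, fs = attr(win, "fs") %||% 1)
  if (any(!is.finite(w$samples))) stop("window contains non-finite samples")
  w
}

# core OLS on the lag-stacked regression; skip >= P initial samples so
# different orders can share one effective sample span
mvar_ols <- function(x, P, skip = P) {
  m <- nrow(x); n <- ncol(x)
  x <- x - rowMeans(x)
  idx <- (skip + 1L):n
  Y <- t(x[, idx, drop = FALSE])
  X <- matrix(0, length(idx), m * P)
  for (r in seq_len(P))
    X[, (r - 1L) * m + seq_len(m)] <- t(x[, idx - r, drop = FALSE])
  qr_ <- qr(X, LAPACK = FALSE)
  B <- qr.coef(qr_, Y)
  aliased <- which(apply(is.na(B), 1L, any))
  B[is.na(B)] <- 0
  E <- Y - X %*% B
  list(B = B, E = E, Y = Y, X = X, rank = qr_$rank, aliased = aliased)
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> m=%d channels, order P=%d, fs=%g Hz, n_eff=%d\n",
              nrow(x$sigma), x$order, x$fs, x$n_eff))
  if (!is.null(x$diagnostics))
    cat(sprintf("  stable=%s (rho=%.3f), min whiteness p=%.3g, consistency=%.1f%%\n",
                x$diagnostics$stable, x$diagnostics$spectral_radius,
                x$diagnostics$whiteness_p, x$diagnostics$consistency_pct))
  invisible(x)
}

#' Select the MVAR order by the Akaike Information Criterion
#'
#' Fits orders `1..max_order` on the same effective sample span and computes
#' `AIC(P) = n_eff * ln det(Sigma_ML) + 2 * m^2 * P`.
#'
#' @param win window (see [fit_mvar()]).
#' @param max_order largest order tried.
#' @param singular_ok passed to the per-order fits.
#' @return list with `best_order` (argmin) and `aic_curve` (data frame with
#'   columns `order`, `aic`).
#' @export
select_order_aic <- function(win, max_order, singular_ok = FALSE) {
  win <- as_window_checked(win)
  x <- win$samples
  m <- nrow(x); n <- ncol(x)
  if (max_order < 1L) stop("max_order must be >= 1")
  if (n <= m * max_order + max_order)
    stop("window too short for max_order=", max_order)
  aic <- rep(NA_real_, max_order)
  for (P in seq_len(max_order)) {
    res <- tryCatch({
      fit <- mvar_ols(x, P, skip = max_order)
      if (fit$rank < ncol(fit$X) && !singular_ok)
        stop("rank deficient at order ", P)
      n_eff <- nrow(fit$Y)
      sig <- crossprod(fit$E) / n_eff
      ld <- determinant(sig, logarithm = TRUE)
      if (ld$sign <= 0) stop("non-PD residual covariance at order ", P)
      n_eff * as.numeric(ld$modulus) + 2 * m^2 * P
    }, error = function(e) NA_real_)
    aic[P] <- res
  }
  if (all(is.na(aic))) stop("all candidate orders failed to fit")
  list(best_order = which.min(aic),
       aic_curve = data.frame(order = seq_len(max_order), aic = aic))
}

#' MVAR stability check via the companion matrix
#'
#' Stacks the coefficient matrices into the `mP x mP` companion form; the
#' process is stable (stationary) iff the spectral radius is < 1.
#'
#' @param model an `mvar_model`.
#' @return list with `stable` (logical) and `spectral_radius`.
#' @export
check_stability <- function(model) {
  rho <- companion_spectral_radius(model$A)
  list(stable = rho < 1, spectral_radius = rho)
}

companion_matrix <- function(A) {
  m <- nrow(A[[1L]]); P <- length(A)
  C <- matrix(0, m * P, m * P)
  for (r in seq_len(P)) C[seq_len(m), (r - 1L) * m + seq_len(m)] <- A[[r]]
  if (P > 1L)
    C[m + seq_len(m * (P - 1L)), seq_len(m * (P - 1L))] <-
      diag(m * (P - 1L))
  C
}

companion_spectral_radius <- function(A) {
  max(Mod(eigen(companion_matrix(A), only.values = TRUE)$values))
}

#' Residual whiteness (Ljung-Box portmanteau) check
#'
#' Recomputes the fit residuals on `win` and tests each channel's residual
#' autocorrelations up to `lags` with the Ljung-Box statistic. A well
#' specified model leaves white residuals (large p values).
#'
#' @param model an `mvar_model` fitted on `win`.
#' @param win the window the model was fitted on.
#' @param lags number of autocorrelation lags tested (default 20).
#' @return data frame (channel, p) with attribute `min_p`.
#' @export
check_whiteness <- function(model, win, lags = 20) {
  win <- as_window_checked(win)
  if (lags >= ncol(win$samples)) stop("lags must be < window length")
  E <- mvar_residuals(model, win)
  p <- vapply(seq_len(ncol(E)), function(i)
    stats::Box.test(E[, i], lag = lags, type = "Ljung-Box")$p.value,
    numeric(1))
  out <- data.frame(channel = model$labels, p = p)
  attr(out, "min_p") <- min(p)
  out
}

mvar_residuals <- function(model, win) {
  x <- win$samples - rowMeans(win$samples)
  m <- nrow(x); n <- ncol(x); P <- model$order
  idx <- (P + 1L):n
  Y <- t(x[, idx, drop = FALSE])
  pred <- matrix(0, length(idx), m)
  for (r in seq_len(P))
    pred <- pred + t(model$A[[r]] %*% x[, idx - r, drop = FALSE])
  Y - pred
}

#' Correlation-structure consistency of an MVAR fit
#'
#' Simulates a synthetic trace of the window's length from the fitted model
#' and compares the stacked auto/cross-correlation matrices (lags 0..P) of
#' data and simulation:
#' `100 * (1 - ||R_data - R_sim||_F / ||R_data||_F)`, clipped below at 0.
#'
#' @param model a stable `mvar_model` fitted on `win`.
#' @param win the window the model was fitted on.
#' @param seed RNG seed for the synthetic trace.
#' @return consistency percentage in `[0, 100]`.
#' @export
check_consistency <- function(model, win, seed = 1L) {
  win <- as_window_checked(win)
  st <- check_stability(model)
  if (!st$stable)
    stop("cannot simulate from an unstable model (spectral radius ",
         signif(st$spectral_radius, 4), ")")
  n <- ncol(win$samples)
  sim <- simulate_var(model$A, n = n, sigma = model$sigma, seed = seed)
  Rd <- corr_stack(win$samples, model$order)
  Rs <- corr_stack(sim, model$order)
  max(0, 100 * (1 - sqrt(sum((Rd - Rs)^2)) / sqrt(sum(Rd^2))))
}

# stacked correlation matrices at lags 0..P; rows are channels
corr_stack <- function(x, P) {
  x <- x - rowMeans(x)
  n <- ncol(x)
  sds <- sqrt(rowMeans(x^2))
  sds[sds == 0] <- 1
  x <- x / sds
  do.call(rbind, lapply(0:P, function(tau) {
    (x[, seq_len(n - tau), drop = FALSE] %*%
       t(x[, tau + seq_len(n - tau), drop = FALSE])) / (n - tau)
  }))
}

#' Run the full MVAR diagnostic battery
#'
#' Stability (companion spectral radius), residual whiteness (minimum
#' Ljung-Box p over channels) and correlation-structure consistency.
#'
#' @inheritParams check_whiteness
#' @param seed seed for the consistency simulation.
#' @return list (`stable`, `spectral_radius`, `whiteness_p`,
#'   `consistency_pct`).
#' @export
validate_mvar <- function(model, win, lags = 20, seed = 1L) {
  st <- check_stability(model)
  wp <- if (lags < ncol(as_window_checked(win)$samples))
    attr(check_whiteness(model, win, lags = lags), "min_p") else NA_real_
  cp <- if (st$stable) check_consistency(model, win, seed = seed) else 0
  list(stable = st$stable, spectral_radius = st$spectral_radius,
       whiteness_p = wp, consistency_pct = cp)
}
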