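test_that("fit_mvar recovers known coefficients and improves with n", {
  A1 <- bivar_A1()
  sys <- generate_mvar_system(list(A1), n = 20000, seed = 42)
  fit <- fit_mvar(sys$recording, order = 1)
  expect_lt(max(abs(fit$A[[1]] - A1)), 0.02)
  # sigma symmetric PSD with the (n_eff - m*P) denominator
  expect_equal(fit$sigma, t(fit$sigma))
  expect_true(all(eigen(fit$sigma, only.values = TRUE)$values > 0))
  # error decreases with n
  sys_s <- generate_mvar_system(list(A1), n = 1280, seed = 42)
  fit_s <- fit_mvar(sys_s$recording, order = 1)
  expect_lt(max(abs(fit$A[[1]] - A1)), max(abs(fit_s$A[[1]] - A1)))
})

test_that("degenerate windows raise singular-fit errors naming channels", {
  zero <- ecimage:::as_window(matrix(0, 3, 500), fs = 128,
                              labels = c("a", "b", "c"))
  expect_error(fit_mvar(zero, 2), "zero-variance")
  set.seed(1)
  dup <- matrix(rnorm(2 * 500), 2, 500)
  dup <- rbind(dup, dup[1, ])
  w <- ecimage:::as_window(dup, fs = 128, labels = c("a", "b", "a2"))
  expect_error(fit_mvar(w, 2), "singular fit")
  expect_match(tryCatch(fit_mvar(w, 2), error = conditionMessage), "a")
  # singular_ok pins aliased directions instead
  fit <- fit_mvar(w, 2, singular_ok = TRUE)
  expect_true(all(is.finite(fit$A[[1]])))
})

test_that("white-noise fits give small coefficients and whiteness holds", {
  max_coefs <- vapply(1:10, function(s) {
    w <- white_window(3, 10000, seed = 100 + s)
    fit <- fit_mvar(w, order = 10)
    max(abs(unlist(fit$A)))
  }, numeric(1))
  expect_lt(max(max_coefs), 0.1)
})

test_that("least-squares residuals are orthogonal to regressors", {
  for (s in 1:5) {
    A <- random_stable_A(3, 2, seed = s)
    sys <- generate_mvar_system(A, n = 2000, seed = s + 50)
    x <- sys$recording$samples
    fit <- ecimage:::mvar_ols(x, 2, skip = 2)
    scale_ <- max(abs(fit$X)) * max(abs(fit$E)) * nrow(fit$E)
    expect_lt(max(abs(crossprod(fit$X, fit$E))), 1e-8 * scale_)
  }
})

test_that("AIC selects the true order of a strong VAR(3)", {
  A <- list(diag(0.4, 3), diag(-0.35, 3), diag(0.35, 3))
  A[[1]][2, 1] <- 0.35; A[[3]][3, 2] <- -0.3
  hits <- vapply(1:10, function(s) {
    sys <- generate_mvar_system(A, n = 2560, seed = 200 + s)
    select_order_aic(sys$recording, max_order = 6)$best_order
  }, numeric(1))
  expect_gte(mean(hits == 3), 0.8)
})

test_that("AIC on white noise picks order 1 (no spurious structure)", {
  best <- vapply(1:10, function(s) {
    select_order_aic(white_window(3, 2560, seed = 300 + s),
                     max_order = 5)$best_order
  }, numeric(1))
  expect_gte(mean(best == 1), 0.8)
  # the pipeline honours a fixed order-10 setting
  w <- white_window(3, 2000, seed = 1)
  expect_identical(fit_mvar(w, order = 10)$order, 10L)
})

test_that("stability check matches hand-computed spectral radii", {
  m_tri <- model_from_coefs(list(bivar_A1()))
  st <- check_stability(m_tri)
  expect_true(st$stable)
  expect_equal(st$spectral_radius, 0.5, tolerance = 1e-12)
  m_unit <- model_from_coefs(list(diag(2)))
  st_u <- check_stability(m_unit)
  expect_false(st_u$stable)
  expect_equal(st_u$spectral_radius, 1, tolerance = 1e-12)
  # generator guarantee
  for (s in 1:5) {
    A <- ecimage:::stabilize_coefficients(
      lapply(1:2, function(r) matrix(rnorm(9, sd = 0.8), 3, 3)))
    expect_true(check_stability(model_from_coefs(A))$stable)
  }
})

test_that("whiteness test passes well-specified fits, fails under-fits", {
  A <- list(diag(0.4, 2), diag(-0.35, 2), diag(0.3, 2))
  A[[1]][2, 1] <- 0.35
  ok <- 0L; fail_underfit <- 0L
  for (s in 1:10) {
    sys <- generate_mvar_system(A, n = 2560, seed = 400 + s)
    w <- ecimage:::as_window(sys$recording$samples, fs = 128)
    fit3 <- fit_mvar(w, 3)
    if (attr(check_whiteness(fit3, w), "min_p") > 0.05) ok <- ok + 1L
    fit1 <- fit_mvar(w, 1)
    if (attr(check_whiteness(fit1, w), "min_p") < 0.05)
      fail_underfit <- fail_underfit + 1L
  }
  expect_gte(ok, 7L)
  expect_gte(fail_underfit, 9L)
  # lags precondition
  expect_error(check_whiteness(fit_mvar(white_window(2, 200, seed = 2), 1),
                               white_window(2, 200, seed = 2), lags = 500),
               "lags")
})

test_that("whiteness p-values are calibrated on analytically white residuals", {
  # zero-coefficient model => residuals are the (demeaned) data itself
  m <- 200L; n <- 512L
  set.seed(77)
  w <- ecimage:::as_window(matrix(rnorm(m * n), m, n), fs = 128)
  model <- model_from_coefs(list(matrix(0, m, m)))
  model$labels <- w$labels
  tab <- check_whiteness(model, w)
  expect_gt(mean(tab$p), 0.4)
  expect_lt(mean(tab$p), 0.6)
})

test_that("consistency is high for self-generated data and ordered", {
  A <- random_stable_A(3, 2, seed = 9)
  sys <- generate_mvar_system(A, n = 10000, seed = 91)
  w <- ecimage:::as_window(sys$recording$samples, fs = 128)
  fit <- fit_mvar(w, 2)
  self_c <- check_consistency(fit, w, seed = 5)
  expect_gte(self_c, 85)
  # same model evaluated against an unrelated white-noise surrogate
  surrogate <- white_window(3, 10000, seed = 92)
  cross_c <- check_consistency(fit, surrogate, seed = 5)
  expect_lt(cross_c, self_c)
  # unstable model cannot be simulated
  expect_error(check_consistency(model_from_coefs(list(diag(2))),
                                 white_window(2, 500, seed = 3)),
               "unstable")
})

test_that("validate_mvar bundles the full diagnostic battery", {
  A <- random_stable_A(2, 1, seed = 13)
  sys <- generate_mvar_system(A, n = 3000, seed = 14)
  w <- ecimage:::as_window(sys$recording$samples, fs = 128)
  fit <- fit_mvar(w, 1)
  d <- validate_mvar(fit, w)
  expect_true(d$stable)
  expect_true(d$whiteness_p >= 0 && d$whiteness_p <= 1)
  expect_true(d$consistency_pct >= 0 && d$consistency_pct <= 100)
})
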