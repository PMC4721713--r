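test_that("build_system centers regressors and rejects degenerate input", {
  # symmetric points on an axis-aligned origin-centered ellipse:
  # means of xy, x, y vanish
  pts <- ellipse_points(8, 0, 0, 2, 1)
  sys <- build_system(pts)
  expect_equal(unname(sys$alpha_bar[c(1, 3, 4)]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(colMeans(sys$X), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mean(sys$Z), 0, tolerance = 1e-12)

  # 6 exact points on 0.2 x^2 + 0.8 y^2 - 0.8 = 0: residual zero at the
  # true coefficients tau' = (0, 0.8, 0, 0), F = -0.8
  ex <- data.frame(x = c(2, -2, 0, 0, sqrt(2), -sqrt(2)),
                   y = c(0, 0, 1, -1, -sqrt(0.5), sqrt(0.5)))
  sys2 <- build_system(ex)
  tau_true <- c(0, 0.8, 0, 0)
  resid <- sys2$X %*% tau_true - sys2$Z
  expect_equal(max(abs(resid)), 0, tolerance = 1e-12)

  expect_error(build_system(data.frame(x = 1:10, y = 2 * (1:10))),
               "degenerate")
  expect_error(build_system(ex[1:5, ]), "at least 6")
})

test_that("jacobi_eigen matches closed forms and the dense-solver oracle", {
  r <- jacobi_eigen(diag(c(4, 1)))
  expect_equal(r$values, c(4, 1))
  expect_equal(abs(r$vectors), diag(2), tolerance = 1e-12)

  r2 <- jacobi_eigen(matrix(c(2, 1, 1, 2), 2))
  expect_equal(r2$values, c(3, 1), tolerance = 1e-12)

  expect_error(jacobi_eigen(matrix(c(1, 2, 3, 4), 2)), "symmetric")

  set.seed(17)
  for (i in 1:20) {
    A <- matrix(rnorm(25), 5)
    Q <- A + t(A)
    r3 <- jacobi_eigen(Q)
    oracle <- eigen(Q, symmetric = TRUE)$values
    expect_equal(r3$values, oracle, tolerance = 1e-8)
    # orthonormality and reconstruction
    expect_equal(crossprod(r3$vectors), diag(5), tolerance = 1e-9)
    expect_lt(norm(r3$vectors %*% diag(r3$values) %*% t(r3$vectors) - Q, "F"),
              1e-8 * norm(Q, "F"))
  }
})

test_that("tls_solve is exact on consistent systems", {
  ex <- ellipse_points(8, 0, 0, 2, 1)  # 0.2 x^2 + 0.8 y^2 = 0.8
  sys <- build_system(ex)
  sol <- tls_solve(sys)
  expect_equal(unname(sol$tau), c(0, 0.8, 0, 0), tolerance = 1e-6)
  expect_equal(sol$gamma_min, 0, tolerance = 1e-6)
  expect_equal(recover_F(sol$tau, sys), -0.8, tolerance = 1e-6)

  # noiseless circle (x-1)^2 + (y-2)^2 = 4 at 12 angles: A = C = 0.5
  circ <- ellipse_points(12, 1, 2, 2, 2)
  f <- fit_ellipse(circ)
  expect_equal(f$B, 0, tolerance = 1e-9)
  expect_equal(f$C, 0.5, tolerance = 1e-9)
  expect_equal(f$D, -1, tolerance = 1e-9)
  expect_equal(f$E, -2, tolerance = 1e-9)
  expect_equal(unname(f$center), c(1, 2), tolerance = 1e-9)
  # plug a sample point into the fitted conic: residual ~ 0
  expect_equal(f$A * circ$x[3]^2 + f$B * circ$x[3] * circ$y[3] +
                 f$C * circ$y[3]^2 + f$D * circ$x[3] + f$E * circ$y[3] + f$F,
               0, tolerance = 1e-9)
})

test_that("ellipse_center evaluates the closed form", {
  expect_equal(unname(ellipse_center(list(B = 0, C = 0.5, D = -1, E = -2))),
               c(1, 2))
  expect_equal(unname(ellipse_center(list(B = 0, C = 0.8, D = 0, E = 0))),
               c(0, 0))
  # construction oracle: build coefficients from a known center by
  # completing the square, recover it
  set.seed(23)
  for (i in 1:20) {
    cx <- runif(1, -50, 50); cy <- runif(1, -50, 50)
    co <- ellipse_conic(cx, cy, runif(1, 2, 9), runif(1, 2, 9),
                        runif(1, 0, pi))
    ctr <- ellipse_center(as.list(co))
    expect_equal(unname(ctr), c(cx, cy), tolerance = 1e-9)
  }
  expect_error(ellipse_center(list(B = 2, C = 0.5, D = 0, E = 0)),
               "not an ellipse")
})

test_that("noiseless fits are exact for random ellipses", {
  set.seed(31)
  for (i in 1:25) {
    cx <- runif(1, 100, 540); cy <- runif(1, 100, 380)
    a <- runif(1, 25, 70); b <- runif(1, 25, 70); th <- runif(1, 0, pi)
    pts <- ellipse_points(sample(8:24, 1), cx, cy, a, b, th,
                          t = sort(runif(sample(8:24, 1), 0, 2 * pi)))
    f <- fit_ellipse(pts)
    expect_equal(f$A + f$C, 1)  # constraint exact by construction
    truth <- ellipse_conic(cx, cy, a, b, th)
    expect_equal(unlist(f[c("A", "B", "C", "D", "E", "F")]), truth,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_lt(max(abs(f$center - c(cx, cy))), 1e-9)
    resid <- f$A * pts$x^2 + f$B * pts$x * pts$y + f$C * pts$y^2 +
      f$D * pts$x + f$E * pts$y + f$F
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("fitted centers are translation-equivariant", {
  set.seed(37)
  pts <- ellipse_points(14, 20, -5, 8, 5, 0.4)
  pts$x <- pts$x + rnorm(14, 0, 0.2)
  pts$y <- pts$y + rnorm(14, 0, 0.2)
  f0 <- fit_ellipse(pts)
  shifted <- data.frame(x = pts$x + 123.25, y = pts$y - 45.5)
  f1 <- fit_ellipse(shifted)
  expect_equal(unname(f1$center), unname(f0$center) + c(123.25, -45.5),
               tolerance = 1e-6)
})

test_that("sensitivity ratio is 1 on consistent systems and ~0 when Z is orthogonal", {
  sys <- build_system(ellipse_points(10, 0, 0, 2, 1))
  sr <- sensitivity_ratio(sys)
  expect_equal(sr$r, 1, tolerance = 1e-5)
  # pathological: response orthogonal to range(X)
  set.seed(41)
  X <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  z <- rnorm(10)
  z <- z - X %*% crossprod(X, z)  # project out range(X)
  sys2 <- structure(list(X = X, Z = drop(z), L = cbind(-drop(z), X),
                         alpha_bar = rep(0, 4), beta_bar = 0, n = 10),
                    class = "tls_system")
  sr2 <- sensitivity_ratio(sys2)
  expect_lt(sr2$r, 0.2)
})

test_that("centered and un-centered TLS formulations agree on clean data", {
  set.seed(43)
  pts <- ellipse_points(16, 3, -2, 6, 4, 0.5)
  tau_unc <- pupilglint:::tls_solve_uncentered(pts)
  sys <- build_system(pts)
  sol <- tls_solve(sys)
  expect_equal(unname(sol$tau), unname(tau_unc[1:4]), tolerance = 1e-6)
  expect_equal(recover_F(sol$tau, sys), unname(tau_unc[["F"]]),
               tolerance = 1e-6)
})
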