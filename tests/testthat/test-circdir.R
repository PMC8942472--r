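# Antipodal bimodal von Mises mixture: density, sampling, MLE, kymographs,
# and reversal response times.

test_that("von Mises density has the uniform limit and peak symmetry", {
  expect_equal(vm_pdf(0.7, 2.1, 0), 1 / (2 * pi))
  for (d in c(0.2, 1, 2.5)) {
    expect_equal(vm_pdf(1 + d, 1, 3), vm_pdf(1 - d, 1, 3))
  }
  expect_error(vm_pdf(0, 0, -1), "kappa")
})

test_that("density matches an independent Bessel-series evaluation", {
  # I0(kappa) by its power series, independent of base besselI
  i0_series <- function(x) {
    s <- 0
    for (m in 0:40) s <- s + (x / 2)^(2 * m) / factorial(m)^2
    s
  }
  for (kappa in c(0.5, 2)) {
    expect_equal(vm_pdf(0, 0, kappa),
                 exp(kappa) / (2 * pi * i0_series(kappa)),
                 tolerance = 1e-10)
  }
})

test_that("density integrates to one for all tested concentrations", {
  for (kappa in c(0, 0.5, 2, 10)) {
    I <- integrate(vm_pdf, 0, 2 * pi, mu = 1.2, kappa = kappa,
                   rel.tol = 1e-12)$value
    expect_lt(abs(I - 1), 1e-8)
  }
})

test_that("MLE recovers known mixture parameters from seeded draws", {
  withr::with_seed(11, th <- rbimodal_vm(1e4, 1.0, 2, 0.7))
  fit <- fit_bimodal_vm(th)
  expect_lt(abs(fit$mu1 - 1.0), 0.05)
  expect_lt(abs(fit$kappa - 2) / 2, 0.10)
  expect_lt(abs(fit$p1 - 0.7), 0.03)
  expect_equal(fit$p1 + fit$p2, 1)
  expect_lt(abs(abs(cortwave:::ang_diff(fit$mu1, fit$mu2)) - pi), 1e-9)
  # concentrated data always beat the uniform model
  expect_gt(fit$loglik, -length(th) * log(2 * pi))
})

test_that("antipodal point masses drive kappa to its bound", {
  th <- rep(c(0, pi), each = 50)
  fit <- fit_bimodal_vm(th)
  expect_equal(fit$p1, 0.5, tolerance = 0.02)
  d <- min(abs(cortwave:::ang_diff(fit$mu1, 0)),
           abs(cortwave:::ang_diff(fit$mu1, pi)))
  expect_lt(d, 0.01)
  expect_gt(fit$kappa, 499)
})

test_that("uniform data show no appreciable concentration", {
  withr::with_seed(1, th <- runif(2e4, 0, 2 * pi))
  fit <- fit_bimodal_vm(th)
  # per-observation likelihood gain over the uniform model is negligible
  gain <- (fit$loglik + length(th) * log(2 * pi)) / length(th)
  expect_lt(gain, 5e-4)
  expect_lt(fit$kappa, 0.5)
})

test_that("fits are equivariant under rotation of all orientations", {
  withr::with_seed(21, th <- rbimodal_vm(4000, 0.6, 3, 0.75))
  f0 <- fit_bimodal_vm(th)
  delta <- 1.1
  f1 <- fit_bimodal_vm((th + delta) %% (2 * pi))
  expect_lt(abs(cortwave:::ang_diff(f1$mu1, f0$mu1 + delta)), 0.02)
  expect_lt(abs(f1$kappa - f0$kappa) / f0$kappa, 0.02)
  expect_lt(abs(f1$p1 - f0$p1), 0.01)
})

test_that("optimizer matches a brute-force grid search on small samples", {
  withr::with_seed(31, th <- rbimodal_vm(120, 2.2, 1.5, 0.65))
  fit <- fit_bimodal_vm(th)
  ll <- function(mu1, kappa, p1) {
    sum(cortwave:::bimodal_vm_logpdf(th, mu1, kappa, p1))
  }
  grid <- expand.grid(mu1 = seq(0, 2 * pi, length.out = 60),
                      kappa = seq(0, 6, length.out = 40),
                      p1 = seq(0.5, 0.99, length.out = 25))
  best <- max(mapply(ll, grid$mu1, grid$kappa, grid$p1))
  expect_gte(fit$loglik, best - 1e-6)
})

test_that("insufficient data raise an error", {
  expect_error(fit_bimodal_vm(runif(5)), "at least 10")
})

test_that("preferential direction follows the dominant component", {
  fit <- structure(list(mu1 = 0.3, mu2 = 0.3 + pi, kappa = 2,
                        p1 = 0.7, p2 = 0.3), class = "vm_fit")
  expect_equal(preferential_direction(fit), 0.3)
  raw <- structure(list(mu1 = 0.3, mu2 = 0.3 + pi, kappa = 2,
                        p1 = 0.4, p2 = 0.6), class = "vm_fit")
  expect_equal(preferential_direction(raw), 0.3 + pi)
  tie <- structure(list(mu1 = 1, mu2 = 1 + pi, kappa = 2,
                        p1 = 0.5, p2 = 0.5), class = "vm_fit")
  expect_equal(preferential_direction(tie), 1)
})

const_flow <- function(u, v, n = 10) {
  structure(
    list(u = matrix(u, n, n), v = matrix(v, n, n),
         reliability = matrix(1, n, n), valid_mask = matrix(TRUE, n, n),
         threshold = 0.5, max_disp = 9),
    class = "flow_field")
}

test_that("kymograph puts unidirectional flow in one bin and is normalized", {
  flows <- rep(list(const_flow(1, 0)), 24)
  ky <- orientation_kymograph(flows, frame_interval = 10, window = 12)
  expect_equal(dim(ky$proportions), c(2, 36))
  expect_true(all(abs(rowSums(ky$proportions) - 1) < 1e-9))
  expect_equal(ky$proportions[, 1], c(1, 1))
  expect_error(orientation_kymograph(flows[1:5], 10, window = 12), "window")
})

test_that("windows without valid vectors are flagged invalid", {
  dead <- const_flow(0, 0)
  dead$valid_mask[] <- FALSE
  flows <- c(rep(list(const_flow(0, 1)), 12), rep(list(dead), 12))
  ky <- orientation_kymograph(flows, frame_interval = 10, window = 12)
  expect_true(ky$valid[1])
  expect_false(ky$valid[2])
  expect_true(all(is.na(ky$proportions[2, ])))
})

mk_fit <- function(mu1, p1, center) {
  structure(list(mu1 = mu1, mu2 = cortwave:::wrap_angle(mu1 + pi), kappa = 3,
                 p1 = p1, p2 = 1 - p1, loglik = 0, n = 100,
                 window = c(center - 60, center + 60)), class = "vm_fit")
}

test_that("response time finds the first sustained switch", {
  fits <- c(lapply(c(60, 180, 300), mk_fit, mu1 = 0, p1 = 0.8),
            lapply(c(420, 540, 660), mk_fit, mu1 = pi, p1 = 0.8))
  expect_equal(response_time(fits, reversal_time = 360, new_direction = pi),
               60)
  # a single-window flip is not sustained
  flicker <- c(lapply(c(60, 180, 300), mk_fit, mu1 = 0, p1 = 0.8),
               list(mk_fit(pi, 0.8, 420)),
               list(mk_fit(0, 0.8, 540)),
               lapply(c(660, 780), mk_fit, mu1 = pi, p1 = 0.8))
  expect_equal(response_time(flicker, 360, pi), 300)
  # never switching yields the sentinel
  never <- lapply(c(60, 180, 300, 420, 540), mk_fit, mu1 = 0, p1 = 0.8)
  expect_true(is.na(response_time(never, 360, pi)))
  expect_error(response_time(never[1:2], 360, pi), "span")
})
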