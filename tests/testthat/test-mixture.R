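test_that("the model family has ten members with the documented structure", {
  expect_identical(model_codes(),
                   c("M1", "M2A", "M2B", "M2C", "M3A", "M3B", "M4A", "M4B",
                     "M5A", "M5B"))
  expect_equal(vapply(model_codes(), model_npar, numeric(1)),
               c(M1 = 0, M2A = 2, M2B = 2, M2C = 3, M3A = 2, M3B = 3,
                 M4A = 3, M4B = 4, M5A = 4, M5B = 5))
  expect_equal(model_modality("M1"), "uniform")
  expect_equal(model_modality("M2C"), "unimodal")
  expect_equal(model_modality("M4B"), "bimodal_axial")
  expect_equal(model_modality("M5A"), "bimodal_nonaxial")
  expect_error(model_npar("M6"), "unknown")
})

test_that("mixture densities are valid and reduce to uniform correctly", {
  th <- seq(0, 2 * pi, length.out = 7)
  expect_equal(mixture_logpdf(th, "M1"), rep(log(1 / (2 * pi)), 7))
  # a von Mises with kappa 0 is the uniform density
  expect_equal(mixture_logpdf(th, "M2A", list(q1 = 1.3, k1 = 0)),
               rep(log(1 / (2 * pi)), 7))
  expect_error(mixture_logpdf(th, "M2A", list(q1 = 1, k1 = -1)), "kappa")
  expect_error(mixture_logpdf(th, "M2C", list(q1 = 1, k1 = 1, l1 = 1.4)),
               "weights")
})

test_that("every model's density integrates to one (quadrature oracle)", {
  set.seed(7)
  params <- list(q1 = runif(1, 0, 2 * pi), q2 = runif(1, 0, 2 * pi),
                 k1 = runif(1, 0.2, 8), k2 = runif(1, 0.2, 8),
                 l1 = runif(1, 0.25, 0.7))
  for (code in model_codes()) {
    expect_equal(mixture_mass(code, params), 1, tolerance = 1e-6,
                 label = paste("mass of", code))
  }
})

test_that("optimizer objective matches the reference log-density", {
  set.seed(5)
  x <- runif(60, 0, 2 * pi)
  s <- list(q1 = 1.1, q2 = 3.3, k1 = 2, k2 = 5, l1 = 0.4)
  for (code in setdiff(model_codes(), "M1")) {
    free <- s[phenocirc:::.models[[code]]$free]
    u <- phenocirc:::to_opt(free)
    expect_equal(unname(phenocirc:::make_nll(code, x)(u)),
                 -sum(mixture_logpdf(x, code, free)),
                 tolerance = 1e-10, label = paste("nll of", code))
  }
})

test_that("the uniform model has its closed-form likelihood", {
  x <- runif(10, 0, 2 * pi)
  f <- fit_model(x, "M1")
  expect_equal(f$loglik, -10 * log(2 * pi), tolerance = 1e-12)
  expect_equal(f$loglik, -18.37877, tolerance = 1e-5)
  expect_equal(f$aic, -2 * f$loglik)
})

test_that("unimodal fits recover known von Mises parameters", {
  set.seed(101)
  x <- rvonmises(500, pi, 2)
  f <- fit_model(x, "M2A")
  expect_lt(abs(f$params$q1 - pi), 0.15)
  expect_lt(abs(f$params$k1 - 2), 0.4)
  expect_equal(f$params$l1, 1)
  # closed-form moment inversion oracle: kappa_hat ~ A^-1(rbar) within 5%
  rbar <- circ_summary(x)$r
  expect_lt(abs(f$params$k1 - a1inv_oracle(rbar)) / a1inv_oracle(rbar), 0.05)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$npar)
})

test_that("fits require enough observations", {
  expect_error(fit_model(runif(3, 0, 2 * pi), "M5B"), "at least")
  expect_error(select_model(runif(4, 0, 2 * pi)), "at least 5")
})

test_that("model selection ranks all ten models by AIC with stable ties", {
  set.seed(3)
  x <- rvonmises(120, 2, 3)
  sel <- select_model(x)
  expect_equal(nrow(sel$table), 10)
  expect_setequal(sel$table$model, model_codes())
  expect_true(all(diff(sel$table$aic) >= -1e-8))
  expect_equal(sel$best$model, sel$table$model[1])
  # aicc flag changes the criterion but still ranks 10 models
  sel2 <- select_model(x, criterion = "aicc")
  expect_equal(nrow(sel2$table), 10)
})

test_that("selection identifies the generating modality class", {
  # strongly concentrated unimodal data
  set.seed(21)
  x <- rvonmises(200, 4, 4)
  expect_true(select_model(x)$best$model %in% c("M2A", "M2B", "M2C"))
  # non-axial bimodal: equal-weight modes at 0 and 2.2 rad
  set.seed(22)
  y <- c(rvonmises(100, 0, 3), rvonmises(100, 2.2, 3))
  expect_equal(select_model(y)$best$modality, "bimodal_nonaxial")
  # uniform data: M1 is the majority (modal) choice across seeds
  best <- vapply(1:25, function(i) {
    set.seed(400 + i)
    select_model(runif(200, 0, 2 * pi))$best$model
  }, character(1))
  expect_gt(mean(best == "M1"), 0.5)
})

test_that("fits are rotation-equivariant and likelihoods respect nesting", {
  set.seed(9)
  x <- rvonmises(150, 1, 2.5)
  delta <- 1.234
  for (code in c("M2A", "M2C", "M3B", "M5A")) {
    f0 <- fit_model(x, code)
    f1 <- fit_model((x + delta) %% (2 * pi), code)
    expect_equal(f1$loglik, f0$loglik, tolerance = 1e-6,
                 label = paste("loglik", code))
    dq <- (f1$params$q1 - f0$params$q1 - delta) %% (2 * pi)
    expect_lt(min(dq, 2 * pi - dq), 1e-3)
  }
  # nested likelihood ordering on assorted samples
  for (i in 1:5) {
    set.seed(500 + i)
    z <- if (i %% 2) runif(80, 0, 2 * pi) else rvonmises(80, 2, 1.5)
    sel <- select_model(z)
    ll <- vapply(sel$fits, function(f) f$loglik, numeric(1))
    names(ll) <- vapply(sel$fits, function(f) f$model, character(1))
    tol <- 1e-4
    expect_gte(ll[["M2C"]], ll[["M2B"]] - tol)
    expect_gte(ll[["M2C"]], ll[["M2A"]] - tol)
    expect_gte(ll[["M2A"]], ll[["M1"]] - tol)
    expect_gte(ll[["M2B"]], ll[["M1"]] - tol)
    expect_gte(ll[["M5B"]], ll[["M5A"]] - tol)
    expect_gte(ll[["M4B"]], ll[["M4A"]] - tol)
    expect_gte(ll[["M3B"]], ll[["M3A"]] - tol)
  }
})
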