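test_that("UV scaling centers, standardizes and inverts exactly", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 1, 9))
  sc <- uv_scale(x)
  expect_equal(unname(colMeans(sc$x)), c(0, 0))
  expect_equal(unname(apply(sc$x, 2, sd)), c(1, 1))
  # applying fitted params to the fitting set reproduces the scaled matrix
  expect_equal(uv_scale(x, sc$params)$x, sc$x)
  # inverse transform recovers the original values
  expect_equal(uv_invert(sc$x, sc$params), x, tolerance = 1e-12)
  # zero-variance columns are dropped with a warning, missing cols error
  x0 <- cbind(a = c(1, 2, 3), z = c(4, 4, 4))
  expect_warning(sc0 <- uv_scale(x0), class = "vitisaroma_zero_variance")
  expect_equal(colnames(sc0$x), "a")
  expect_equal(sc0$params$dropped, "z")
  expect_error(uv_scale(x0[, "z", drop = FALSE], sc$params),
               class = "vitisaroma_reference_error")
})

test_that("OPLS with no orthogonal components equals textbook PLS1", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      x <- matrix(rnorm(30 * 8), 30,
                  dimnames = list(NULL, paste0("v", 1:8)))
      y <- rnorm(30)
      fit <- fit_opls(x, y, n_ortho = 0)
      oracle <- pls1_one_component(x, y)
      expect_equal(unname(fit$w), unname(oracle$w), tolerance = 1e-10)
      expect_equal(fit$q, oracle$q, tolerance = 1e-10)
      xnew <- matrix(rnorm(5 * 8), 5,
                     dimnames = list(NULL, paste0("v", 1:8)))
      expect_equal(predict(fit, xnew), oracle$predict(xnew),
                   tolerance = 1e-10)
    }
  })
})

test_that("an exactly low-rank linear problem is fitted perfectly", {
  withr::with_seed(5, {
    t_true <- rnorm(25)
    p_true <- rnorm(6)
    x <- tcrossprod(t_true, p_true)
    colnames(x) <- paste0("v", 1:6)
    y <- t_true
  })
  fit <- fit_opls(x, y, n_ortho = 0)
  expect_equal(fit$stats$r2y, 1, tolerance = 1e-10)
  expect_equal(unname(fit$fitted), unname(y), tolerance = 1e-8)
})

test_that("orthogonal components satisfy the orthogonality invariants", {
  withr::with_seed(33, {
    x <- matrix(rnorm(40 * 12), 40,
                dimnames = list(NULL, paste0("v", 1:12)))
    y <- drop(x[, 1:3] %*% c(1, -1, 0.5)) + rnorm(40, 0, 0.3)
  })
  fit <- fit_opls(x, y, n_ortho = 3)
  for (a in 1:3) {
    expect_lt(abs(sum(fit$w * fit$w_ortho[, a])), 1e-10)
    # scores mutually orthogonal
    expect_lt(abs(sum(fit$t * fit$t_ortho[, a])) /
                sqrt(sum(fit$t^2) * sum(fit$t_ortho[, a]^2)), 1e-10)
    for (b in seq_len(a - 1)) {
      expect_lt(abs(sum(fit$t_ortho[, a] * fit$t_ortho[, b])) /
                  sqrt(sum(fit$t_ortho[, a]^2) * sum(fit$t_ortho[, b]^2)),
                1e-10)
    }
  }
  expect_equal(sum(fit$w^2), 1, tolerance = 1e-12)
  expect_equal(fit$n_components_label, "1 + 3 + 0")
})

test_that("predictions are invariant to added model-orthogonal variation", {
  withr::with_seed(77, {
    x <- matrix(rnorm(30 * 10), 30,
                dimnames = list(NULL, paste0("v", 1:10)))
    y <- drop(x[, 1:2] %*% c(2, -1)) + rnorm(30, 0, 0.2)
  })
  fit <- fit_opls(x, y, n_ortho = 2)
  xnew <- matrix(rnorm(8 * 10), 8, dimnames = list(NULL, paste0("v", 1:10)))
  base <- predict(fit, xnew)
  # perturb new samples along the first orthogonal loading (scaled space)
  pert <- sweep(uv_scale(xnew, fit$x_params)$x, 2, 0, `+`) +
    outer(rnorm(8, 0, 3), fit$p_ortho[, 1])
  xpert <- uv_invert(pert, fit$x_params)
  expect_equal(predict(fit, xpert), base, tolerance = 1e-8)
  # training-set predictions reproduce fitted values, duplicates agree
  expect_equal(predict(fit, x), fit$fitted, tolerance = 1e-10)
  expect_equal(predict(fit, x[c(1, 1), ])[1],
               predict(fit, x[c(1, 1), ])[2])
})

test_that("degenerate OPLS inputs are rejected", {
  x <- matrix(rnorm(20 * 5), 20, dimnames = list(NULL, paste0("v", 1:5)))
  expect_error(fit_opls(x, rep(2, 20)),
               class = "vitisaroma_validation_error")
  expect_error(fit_opls(x, rnorm(20), n_ortho = 10),
               class = "vitisaroma_validation_error")
  expect_error(fit_opls(x, rnorm(19)),
               class = "vitisaroma_validation_error")
})

test_that("VIP satisfies its normalization and matches the direct formula", {
  withr::with_seed(55, {
    x <- matrix(rnorm(25 * 4), 25, dimnames = list(NULL, paste0("v", 1:4)))
    y <- drop(x %*% c(1, 0.5, -0.5, 0)) + rnorm(25, 0, 0.3)
  })
  fit <- fit_opls(x, y, n_ortho = 2)
  v <- vip(fit)
  expect_equal(mean(v$vip^2), 1, tolerance = 1e-8)
  oracle <- vip_direct(cbind(fit$w, fit$w_ortho), fit$ssy_components)
  expect_equal(v$vip, unname(oracle), tolerance = 1e-10)
  vp <- vip(fit, type = "predictive")
  expect_equal(mean(vp$vip^2), 1, tolerance = 1e-8)
  # single-variable model: VIP is forced to 1 exactly
  x1 <- matrix(rnorm(25), 25, dimnames = list(NULL, "only"))
  f1 <- fit_opls(x1, drop(x1) * 2 + rnorm(25, 0, 0.1), n_ortho = 0)
  expect_equal(vip(f1)$vip, 1, tolerance = 1e-12)
})

test_that("coefficient signs track the generating relationship", {
  withr::with_seed(91, {
    x <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("v", 1:6)))
    y <- drop(x %*% c(2, -2, 1, -1, 0, 0)) + rnorm(40, 0, 0.2)
  })
  fit <- fit_opls(x, y, n_ortho = 1)
  v <- vip(fit)
  expect_equal(v$direction[1:4],
               c("positive", "negative", "positive", "negative"))
})

test_that("serialized models predict identically after reloading", {
  withr::with_seed(7, {
    x <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, paste0("v", 1:6)))
    y <- drop(x[, 1:2] %*% c(1, -1)) + rnorm(30, 0, 0.2)
    xnew <- matrix(rnorm(10 * 6), 10,
                   dimnames = list(NULL, paste0("v", 1:6)))
  })
  fit <- fit_opls(x, y, n_ortho = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_opls(fit, path)
  back <- read_opls(path)
  expect_equal(predict(back, xnew), predict(fit, xnew), tolerance = 1e-12)
  expect_equal(back$stats$r2y, fit$stats$r2y, tolerance = 1e-12)
})
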