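test_that("block and path specs validate their structure", {
  expect_error(plspm_blocks(c("m1")), "named")
  expect_error(plspm_blocks(a = "m1", b = c("m1", "m2")), "more than one")
  b <- plspm_blocks(a = "m1", b = "m2")
  expect_error(plspm_paths(b, list(c("b", "a"))), "lower-triangular")
  expect_error(plspm_paths(b, list()), "endogenous")
  p <- plspm_paths(b, list(c("a", "b")))
  expect_equal(p["b", "a"], 1)
})

test_that("a single-indicator two-block model collapses to the correlation", {
  set.seed(101)
  dat <- data.frame(x = rnorm(40))
  dat$y <- 0.6 * dat$x + rnorm(40, sd = 0.8)
  blocks <- plspm_blocks(A = "x", B = "y")
  paths <- plspm_paths(blocks, list(c("A", "B")))
  fit <- fit_plspm(dat, blocks, paths)
  expect_equal(fit$path_coefficients$coefficient, cor(dat$x, dat$y),
               tolerance = 1e-9)
  expect_equal(unname(fit$r_squared["B"]), cor(dat$x, dat$y)^2,
               tolerance = 1e-9)
  # copies of the same manifest: a perfect degenerate model
  dat2 <- data.frame(x = rnorm(20))
  dat2$y <- dat2$x
  fit2 <- fit_plspm(dat2, blocks, paths)
  expect_equal(fit2$path_coefficients$coefficient, 1, tolerance = 1e-9)
  expect_equal(unname(fit2$r_squared), 1, tolerance = 1e-9)
  expect_equal(fit2$gof, 1, tolerance = 1e-9)
})

test_that("single-indicator models equal closed-form OLS among standardized variables", {
  set.seed(102)
  n <- 60
  dat <- data.frame(a = rnorm(n))
  dat$b <- 0.5 * dat$a + rnorm(n, sd = 0.7)
  dat$c <- 0.4 * dat$a - 0.6 * dat$b + rnorm(n, sd = 0.5)
  blocks <- plspm_blocks(A = "a", B = "b", C = "c")
  paths <- plspm_paths(blocks, list(c("A", "B"), c("A", "C"), c("B", "C")))
  fit <- fit_plspm(dat, blocks, paths)
  z <- as.data.frame(scale(dat))
  ols <- lm(c ~ a + b, data = z)
  expect_equal(unname(fit$path_matrix["C", c("A", "B")]),
               unname(coef(ols)[c("a", "b")]), tolerance = 1e-8)
  expect_equal(unname(fit$r_squared["C"]), summary(ols)$r.squared,
               tolerance = 1e-8)
})

test_that("latent scores are standardized and fits are affine-invariant", {
  sim <- simulate_path_model(n = 80, p = 3, seed = 9)
  fit <- fit_plspm(sim$data, sim$blocks, sim$paths)
  expect_true(fit$converged)
  expect_lt(fit$last_delta, 1e-7)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-9)
  expect_lt(max(abs(apply(fit$scores, 2, sd) - 1)), 1e-9)
  # affine rescaling of manifests leaves the model unchanged
  dat2 <- sim$data
  dat2$soil_m1 <- dat2$soil_m1 * 37 - 5
  dat2$yield_m2 <- dat2$yield_m2 / 1000 + 2
  fit2 <- fit_plspm(dat2, sim$blocks, sim$paths)
  expect_equal(fit$path_coefficients$coefficient,
               fit2$path_coefficients$coefficient, tolerance = 1e-8)
  expect_equal(fit$gof, fit2$gof, tolerance = 1e-8)
})

test_that("goodness of fit obeys its defining identity", {
  sim <- simulate_path_model(n = 60, p = 2, seed = 4)
  fit <- fit_plspm(sim$data, sim$blocks, sim$paths)
  multi <- lengths(fit$blocks) > 1
  expect_equal(fit$gof^2,
               mean(fit$communality[multi]) * mean(fit$r_squared),
               tolerance = 1e-12)
  expect_true(fit$gof >= 0 && fit$gof <= 1)
  # hand case: mean communality 0.81, mean R^2 0.49 -> GoF 0.63
  mock <- structure(list(blocks = plspm_blocks(A = c("x", "y"), B = "z"),
                         communality = c(A = 0.81, B = 1),
                         r_squared = c(B = 0.49)),
                    class = "plspm_result")
  expect_equal(gof(mock), 0.63)
})

test_that("path-sign recovery on a known five-latent model", {
  sim <- simulate_path_model(n = 200, p = 2, seed = 31)
  fit <- fit_plspm(sim$data, sim$blocks, sim$paths)
  pc <- fit$path_coefficients
  for (e in sim$true_signs) {
    est <- pc$coefficient[pc$from == e$from & pc$to == e$to]
    expect_equal(sign(est), e$sign)
  }
})

test_that("singular predecessor sets are rejected", {
  set.seed(103)
  dat <- data.frame(x = rnorm(20))
  dat$x2 <- dat$x           # collinear duplicate
  dat$y <- rnorm(20)
  blocks <- plspm_blocks(A = "x", B = "x2", C = "y")
  paths <- plspm_paths(blocks, list(c("A", "C"), c("B", "C")))
  expect_error(fit_plspm(dat, blocks, paths), "singular predecessor")
})

test_that("bootstrap is deterministic and calibrated on strong vs null paths", {
  sim <- simulate_path_model(n = 120, p = 2, seed = 8)
  bt1 <- bootstrap_paths(sim$data, sim$blocks, sim$paths, n_boot = 120,
                         seed = 77)
  bt2 <- bootstrap_paths(sim$data, sim$blocks, sim$paths, n_boot = 120,
                         seed = 77)
  expect_identical(bt1, bt2)
  expect_true(all(c("ci_lower", "ci_upper", "p_value", "flag") %in%
                    names(bt1)))
  expect_true(all(bt1$ci_lower <= bt1$estimate + 1e-12))
  expect_true(all(bt1$ci_upper >= bt1$estimate - 1e-12))
  # the strong treatment -> soil path (0.7 at n = 120) must be flagged
  strong <- bt1[bt1$from == "treatment" & bt1$to == "soil", ]
  expect_equal(strong$flag, "*")
  expect_error(bootstrap_paths(sim$data, sim$blocks, sim$paths, n_boot = 10),
               ">= 100")
})

test_that("null paths are rarely starred", {
  # two independent latents, single indicators: generating path = 0
  stars <- vapply(1:25, function(i) {
    set.seed(1000 + i)
    dat <- data.frame(x = rnorm(100), y = rnorm(100))
    blocks <- plspm_blocks(A = "x", B = "y")
    paths <- plspm_paths(blocks, list(c("A", "B")))
    bt <- bootstrap_paths(dat, blocks, paths, n_boot = 100, seed = i)
    bt$flag == "*"
  }, logical(1))
  expect_lte(mean(stars), 0.15)
})
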