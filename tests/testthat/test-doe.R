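test_that("factor coding is an exact involution", {
  expect_equal(code_levels(67.77, 67.77, 33.56), 0)
  with_seed(5, {
    x <- stats::runif(50, -200, 200)
    c0 <- stats::runif(50, -10, 10)
    h <- stats::runif(50, 0.1, 40)
    expect_equal(decode_levels(code_levels(x, c0, h), c0, h), x,
                 tolerance = 1e-12)
  })
  expect_error(code_levels(1, 0, 0), "positive")
  expect_error(decode_levels(1, 0, -2), "positive")
})

test_that("mass coding parameters are recoverable from the printed pairs", {
  d <- doe_design_table()
  cod <- recover_coding(d$mass_mg, d$coded_B)
  expect_lt(abs(cod$center - 67.77), 0.05)
  expect_lt(abs(cod$half_range - 33.56), 0.05)
  # the recovered coding reproduces each printed code closely
  back <- code_levels(d$mass_mg, cod$center, cod$half_range)
  expect_lt(max(abs(back - d$coded_B)), 2e-4)
})

test_that("the interaction fit matches the normal-equations oracle", {
  d <- doe_design_table()
  fit <- fit_interaction_model(d)
  X <- cbind(1, d$coded_A, d$coded_B, d$coded_A * d$coded_B)
  y <- d$retention_pct
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-9)
  # residuals orthogonal to every design column
  r <- y - X %*% beta
  expect_lt(max(abs(t(X) %*% r)), 1e-8)
  # standard errors from sigma^2 (X'X)^-1
  s2 <- sum(r^2) / (nrow(X) - 4)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(unname(fit$standard_errors), se, tolerance = 1e-9)
})

test_that("degenerate designs are rejected", {
  d <- doe_design_table()
  bad <- d
  bad$coded_B <- bad$coded_A          # collinear: AB = A^2 ... rank 3
  expect_error(fit_interaction_model(bad), "singular|deficien")
  flat <- d
  flat$retention_pct <- rep(50, nrow(d))
  expect_error(fit_interaction_model(flat), "R-squared")
  expect_error(fit_interaction_model(d[1:4, ]), "at least 5")
})

test_that("adding a response offset moves only the intercept", {
  d <- doe_design_table()
  f1 <- fit_interaction_model(d)
  d$retention_pct <- d$retention_pct + 17
  f2 <- fit_interaction_model(d)
  expect_equal(f2$coefficients["b0"], f1$coefficients["b0"] + 17,
               tolerance = 1e-9)
  expect_equal(f2$coefficients[2:4], f1$coefficients[2:4],
               tolerance = 1e-9)
})

test_that("an injected dominant effect is the one flagged significant", {
  pts <- data.frame(coded_A = c(-1, 1, -1, 1, 0, 0.5, -0.5, 0),
                    coded_B = c(-1, -1, 1, 1, 0, -0.5, 0.5, 0))
  d <- make_noisy_design(c(50, 30, 0.05, -0.05), pts, noise_sd = 0.5,
                         seed = 6)
  eff <- standardized_effects(fit_interaction_model(d))
  expect_true(eff$significant[eff$term == "A"])
  expect_false(any(eff$significant[eff$term != "A"]))
})

test_that("coefficient recovery is unbiased with good interval coverage", {
  b_true <- c(90, 3, -2, 1.5)
  pts <- data.frame(coded_A = c(-1, 1, -1, 1, 0, 0, 0),
                    coded_B = c(-1, -1, 1, 1, 0, 0, 0))
  n_rep <- 400
  est <- matrix(NA_real_, n_rep, 4)
  cover <- matrix(NA, n_rep, 4)
  for (r in seq_len(n_rep)) {
    d <- make_noisy_design(b_true, pts, noise_sd = 1, seed = 1000 + r)
    f <- fit_interaction_model(d)
    est[r, ] <- f$coefficients
    half <- f$critical_t_95 * f$standard_errors
    cover[r, ] <- abs(f$coefficients - b_true) <= half
  }
  expect_lt(max(abs(colMeans(est) - b_true)), 0.1)
  cv <- colMeans(cover)
  expect_true(all(cv >= 0.90 & cv <= 0.99))
})

test_that("the response surface evaluates the fitted polynomial", {
  d <- doe_design_table()
  model <- fit_interaction_model(d)
  b <- model$coefficients
  surf <- response_surface(model, grid_a = c(-1, 0, 1),
                           grid_b = c(-1, 0, 1))
  expect_equal(surf$predicted[surf$A == 0 & surf$B == 0],
               unname(b[1]), tolerance = 1e-12)
  expect_equal(surf$predicted[surf$A == 1 & surf$B == 1],
               unname(b[1] + b[2] + b[3] + b[4]), tolerance = 1e-12)
  am <- attr(surf, "argmax")
  expect_equal(am$value, max(surf$predicted))
  expect_error(response_surface(model, grid_a = numeric(0)), "empty")
  # symmetric coefficients give a transpose-symmetric surface
  sym <- model
  sym$coefficients[2:3] <- c(2, 2)
  g <- response_surface(sym, grid_a = c(-1, 0, 1), grid_b = c(-1, 0, 1))
  M <- matrix(g$predicted, 3, 3)
  expect_equal(M, t(M), tolerance = 1e-12)
})

test_that("absorption percentage follows the absorbance ratio", {
  expect_equal(absorption_percent(1.0, 0.0), 100)
  expect_equal(absorption_percent(1.0, 1.0), 0)
  expect_equal(absorption_percent(0.84, 0.21), 75, tolerance = 1e-12)
  expect_error(absorption_percent(0, 0.1), "positive")
})
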