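test_that("the MSE is the mean of squared residuals over observed points", {
  rt <- data.frame(node = "X", residual = c(0, 0, 0))
  expect_equal(mse_residuals(rt), 0)
  rt$residual <- rep(0.1, 3)
  expect_equal(mse_residuals(rt), 0.01)
  rt4 <- data.frame(node = "X", residual = c(0, 0.1, 0.2, 0.3))
  expect_equal(mse_residuals(rt4), 0.035)
  rt4$node <- c("X", "X", "Y", "Y")
  expect_equal(mse_residuals(rt4, "X"), 0.005)
  expect_error(mse_residuals(rt4, character(0)), "empty")
})

test_that("the AIC formula is n ln(MSE) + 2k with the documented behaviour", {
  expect_equal(aic_score(1, 50, 7), 14)
  expect_equal(aic_score(0.5, 50, 8) - aic_score(0.5, 50, 7), 2)
  expect_equal(aic_score(0.25, 100, 10), 100 * log(0.25) + 20)  # -118.629...
  expect_warning(v <- aic_score(0, 10, 2), "-Inf")
  expect_identical(v, -Inf)
  ## strictly increasing in n_params and in mse
  expect_gt(aic_score(0.3, 60, 5), aic_score(0.3, 60, 4))
  expect_gt(aic_score(0.31, 60, 4), aic_score(0.3, 60, 4))
})

two_node_fixture <- function() {
  net <- logic_network(
    nodes = data.frame(name = c("NaCl", "Phe", "A", "B"),
                       role = c("STIMULUS", "STIMULUS", "PPEP", "PPEP"),
                       measured = c(FALSE, FALSE, TRUE, TRUE)),
    edges = data.frame(source = c("NaCl", "A"), sign = 1,
                       target = c("A", "B")))
  true <- default_ode_params(net)
  true$tau[c("A", "B")] <- c(0.5, 0.2)
  list(net = net, true = true,
       data = simulate_training_data(net, true))
}

test_that("fitting is deterministic given the seed", {
  fx <- two_node_fixture()
  f1 <- fit_logic_ode(fx$net, fx$data, free = "tau", restarts = 3,
                      eval_budget = 600, seed = 21)
  f2 <- fit_logic_ode(fx$net, fx$data, free = "tau", restarts = 3,
                      eval_budget = 600, seed = 21)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$mse, f2$mse)
  expect_equal(f1$evals_used, f2$evals_used)
})

test_that("more restarts never worsen the best fit", {
  fx <- two_node_fixture()
  f1 <- fit_logic_ode(fx$net, fx$data, free = "tau", restarts = 1,
                      eval_budget = 150, seed = 4)
  f5 <- fit_logic_ode(fx$net, fx$data, free = "tau", restarts = 5,
                      eval_budget = 750, seed = 4)
  expect_lte(min(f5$best_per_restart), min(f1$best_per_restart) + 1e-12)
})

test_that("noise-free two-node data is refit essentially exactly", {
  fx <- two_node_fixture()
  fit <- fit_logic_ode(fx$net, fx$data, free = "tau", restarts = 3,
                       eval_budget = 900, seed = 2)
  expect_lt(fit$mse, 1e-6)
  expect_equal(unname(fit$params$tau[c("A", "B")]),
               unname(fx$true$tau[c("A", "B")]), tolerance = 0.02)
  ## fit result invariants
  expect_equal(fit$aic,
               aic_score(fit$mse, fit$n_points, fit$n_params))
  expect_s3_class(fit, "logic_ode_fit")
})

test_that("fit methods expose coefficients, residuals and predictions", {
  fx <- two_node_fixture()
  fit <- fit_logic_ode(fx$net, fx$data, free = "tau", restarts = 2,
                       eval_budget = 300, seed = 3)
  expect_named(coef(fit), c("tau.A", "tau.B"))
  expect_length(residuals(fit), nrow(fit$residual_table))
  expect_equal(fitted(fit) + residuals(fit) * -1 + residuals(fit),
               fitted(fit))
  pred <- predict(fit, times = c(0, 5, 10))
  expect_setequal(unique(pred$node), c("A", "B"))
  expect_true(all(pred$value >= 0 & pred$value <= 1))
  sims <- simulate(fit, nsim = 2, times = c(0, 5))
  expect_length(sims, 2)
  expect_identical(sims[[1]], sims[[2]])
  expect_output(print(fit), "MSE")
})

test_that("model comparison ranks by AIC with a common node subset", {
  fx <- two_node_fixture()
  fit1 <- fit_logic_ode(fx$net, fx$data, free = "tau", restarts = 2,
                        eval_budget = 300, seed = 5)
  ## same data, one extra free parameter family: same fit, more params
  fit2 <- fit_logic_ode(fx$net, fx$data, free = c("tau", "k"), restarts = 2,
                        eval_budget = 300, seed = 5)
  tab <- compare_models(list(lean = fit1, rich = fit2))
  expect_equal(names(tab), c("model", "mse", "n_params", "aic"))
  expect_equal(tab$model[which.min(tab$aic)], tab$model[1])
  ## equal-mse tie goes to fewer parameters
  if (abs(fit1$mse - fit2$mse) < 1e-8)
    expect_equal(tab$model[1], "lean")
  expect_error(compare_models(list(fit1), node_subset = "Q"), "subset")
})
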