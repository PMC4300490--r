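test_that("Hill normalisation matches its closed form", {
  expect_equal(hill_normalize(2, k = 2), 0.5)
  expect_equal(hill_normalize(4, k = 2), 16 / 17)      # x = 2k, n = 4
  expect_equal(hill_normalize(1e9, k = 2), 1, tolerance = 1e-6)
  expect_equal(hill_normalize(1e-9, k = 2), 0, tolerance = 1e-6)
  ## default k is the per-peptide median (CDF midpoint)
  x <- c(1, 2, 3, 4, 100)
  expect_equal(hill_normalize(x)[3], 0.5)
  expect_error(hill_normalize(rep(5, 4)), "identical")
  expect_error(hill_normalize(c(-1, 2)), "positive")
})

single_edge_net <- function(sign = 1) logic_network(
  nodes = data.frame(name = c("U", "X"), role = c("STIMULUS", "PPEP"),
                     measured = c(FALSE, TRUE)),
  edges = data.frame(source = "U", sign = sign, target = "X"))

test_that("single-edge steady states match the transfer closed form", {
  sys <- logic_ode_system(single_edge_net())
  p <- default_ode_params(sys)
  end <- function(u) {
    tr <- simulate_logic_ode(sys, p, inputs = c(U = u), times = c(0, 100))
    tr$X[2]
  }
  expect_equal(end(1), 1, tolerance = 1e-5)
  expect_equal(end(0), 0, tolerance = 1e-6)
  ## f(c) = c^4 (1 + k^4) / (c^4 + k^4) at c = k = 0.5
  expect_equal(end(0.5), 0.53125, tolerance = 1e-5)
  ## inhibition-only input at u = 1 relaxes to 0
  sysi <- logic_ode_system(single_edge_net(-1))
  tri <- simulate_logic_ode(sysi, default_ode_params(sysi),
                            inputs = c(U = 1), times = c(0, 100),
                            y0 = c(X = 1))
  expect_equal(tri$X[2], 0, tolerance = 1e-5)
})

test_that("zero-input nodes stay at their initial state", {
  net <- logic_network(
    nodes = data.frame(name = c("U", "X", "Z"),
                       role = c("STIMULUS", "PPEP", "PPEP"),
                       measured = c(FALSE, TRUE, TRUE)),
    edges = data.frame(source = "U", sign = 1, target = "X"))
  sys <- logic_ode_system(net)
  tr <- simulate_logic_ode(sys, default_ode_params(sys),
                           inputs = c(U = 0), times = c(0, 10, 20),
                           y0 = c(Z = 0.37))
  expect_equal(tr$Z, rep(0.37, 3))
  expect_equal(tr$X, rep(0, 3), tolerance = 1e-8)
})

test_that("a fast time scale reaches its gate value within the first step", {
  sys <- logic_ode_system(single_edge_net())
  p <- default_ode_params(sys, tau = 50)
  tr <- simulate_logic_ode(sys, p, inputs = c(U = 1), times = c(0, 1, 5))
  expect_equal(tr$X[2], 1, tolerance = 1e-3)
})

test_that("trajectories stay within [0, 1] for random valid parameters", {
  net <- toy_crosstalk_network()
  sys <- logic_ode_system(net)
  set.seed(31)
  for (i in 1:10) {
    p <- default_ode_params(sys)
    p$tau[] <- runif(length(p$tau), 0.05, 5)
    p$n[] <- runif(length(p$n), 1, 10)
    p$k[] <- runif(length(p$k), 0.05, 0.95)
    tr <- simulate_logic_ode(sys, p, inputs = c(NaCl = 1, Phe = 1),
                             times = seq(0, 45, by = 5))
    vals <- unlist(tr[sys$states])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("grid refinement changes trajectories by less than the tolerance", {
  sys <- logic_ode_system(toy_crosstalk_network())
  p <- toy_crosstalk_params()
  coarse <- simulate_logic_ode(sys, p, c(NaCl = 1, Phe = 0),
                               times = c(0, 10, 45))
  fine <- simulate_logic_ode(sys, p, c(NaCl = 1, Phe = 0),
                             times = seq(0, 45, by = 0.5))
  at <- match(c(10, 45), fine$time)
  expect_equal(unlist(coarse[2:3, sys$states]),
               unlist(fine[at, sys$states]), tolerance = 1e-4)
})

test_that("Boolean-limit steady states match exhaustive Boolean evaluation", {
  ## acyclic toys with up to 5 clamped inputs, all input vectors
  mk_gate_net <- function() {
    nodes <- data.frame(
      name = c(paste0("I", 1:5), "X", "Y", "Z"),
      role = c(rep("STIMULUS", 5), rep("PPEP", 3)),
      measured = c(rep(FALSE, 5), rep(TRUE, 3)))
    edges <- data.frame(
      source = c("I1", "I2", "I3", "X", "I5"),
      sign   = c(1, -1, 1, 1, -1),
      target = c("X", "X", "Y", "Y", "Z"))
    gates <- list(list(id = "and1",
                       inputs = data.frame(source = c("I4", "Y"),
                                           sign = c(1, 1)),
                       target = "Z"))
    logic_network(nodes, edges, gates)
  }
  nets <- list(
    chain = logic_network(
      nodes = data.frame(name = c("I1", "I2", "A", "B", "C"),
                         role = c("STIMULUS", "STIMULUS", rep("PPEP", 3)),
                         measured = c(FALSE, FALSE, rep(TRUE, 3))),
      edges = data.frame(source = c("I1", "A", "I2", "B"),
                         sign = c(1, 1, -1, 1),
                         target = c("A", "B", "B", "C"))),
    gated = mk_gate_net())
  for (net in nets) {
    sys <- logic_ode_system(net)
    p <- default_ode_params(sys, tau = 5, n = 10, k = 0.5)
    stims <- sys$stimuli
    m <- length(stims)
    for (bits in 0:(2^m - 1)) {
      inp <- as.numeric(intToBits(bits)[1:m])
      names(inp) <- stims
      tr <- simulate_logic_ode(sys, p, inputs = inp, times = c(0, 80))
      got <- round(unlist(tr[2, sys$states]))
      want <- boolean_eval(net, inp)[sys$states]
      expect_equal(unname(got), unname(want))
    }
  }
})
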