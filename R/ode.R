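## Logic-ODE transform, simulation and data normalisation.

#' Hill normalisation of intensities to \[0, 1\]
#'
#' Nonlinear normalisation `x -> x^n / (x^n + k^n)` with Hill coefficient
#' 4 by default; the half-effect coefficient k is the middle point of the
#' cumulative distribution of all data points of the peptide (its
#' median).  This prevents very large values from dominating the model
#' fit.
#'
#' @param x Positive numeric vector (all data points of one peptide).
#' @param n Hill coefficient.
#' @param k Half-effect constant; default the median of `x`.
#' @return Values in \[0, 1\].
#' @export
hill_normalize <- function(x, n = 4, k = NULL) {
  if (any(x[!is.na(x)] <= 0)) stopf("hill_normalize requires positive values")
  if (is.null(k)) {
    if (length(unique(x[!is.na(x)])) < 2)
      stopf("all values identical; Hill midpoint is degenerate")
    k <- stats::median(x, na.rm = TRUE)
  }
  x^n / (x^n + k^n)
}

#' Hill-normalise a whole mean surface
#'
#' Applies [hill_normalize()] per phosphopeptide across all its surface
#' cells.
#'
#' @param surface A `mean_surface`.
#' @param n Hill coefficient.
#' @return The surface with `mean` replaced by normalised values.
#' @export
hill_normalize_surface <- function(surface, n = 4) {
  stopifnot(inherits(surface, "mean_surface"))
  surface$mean <- t(apply(surface$mean, 1, hill_normalize, n = n))
  surface
}

#' Compile a logic network into a logic-ODE system
#'
#' Every non-stimulus node x gets `dx/dt = tau_x (Phi_x(inputs) - x)`,
#' where incoming edges and AND gates combine as OR gates
#' (`1 - prod(1 - term)`), an AND gate is the product of its members'
#' transfers, an activating edge contributes the normalised Hill
#' transfer `f(u) = u^n (1 + k^n) / (u^n + k^n)` (so f(0) = 0 and
#' f(1) = 1) and an inhibiting edge `1 - f(u)`.  Stimulus nodes are
#' clamped to their condition value from t = 0.  Nodes without inputs
#' stay at their initial state.
#'
#' @param network A `logic_network`.
#' @return Object of class `logic_ode_system` holding the state and
#'   stimulus names, the flattened structure for the compiled
#'   right-hand side, and the per-edge parameter ids.
#' @export
logic_ode_system <- function(network) {
  stopifnot(inherits(network, "logic_network"))
  states <- network$nodes$name[network$nodes$role != "STIMULUS"]
  stims <- network$nodes$name[network$nodes$role == "STIMULUS"]
  sidx <- function(x) {
    i <- match(x, states)
    j <- match(x, stims)
    ifelse(!is.na(i), i, -j)
  }
  gcount <- integer(length(states))
  mcount <- integer(0)
  msrc <- integer(0); msign <- integer(0); mid <- character(0)
  for (i in seq_along(states)) {
    nd <- states[i]
    ein <- network$edges[network$edges$target == nd, , drop = FALSE]
    gin <- Filter(function(g) g$target == nd, network$gates)
    gcount[i] <- nrow(ein) + length(gin)
    if (nrow(ein)) {
      mcount <- c(mcount, rep(1L, nrow(ein)))
      msrc <- c(msrc, sidx(ein$source))
      msign <- c(msign, as.integer(ein$sign))
      mid <- c(mid, edge_id(ein$source, nd))
    }
    for (g in gin) {
      mcount <- c(mcount, nrow(g$inputs))
      msrc <- c(msrc, sidx(g$inputs$source))
      msign <- c(msign, as.integer(g$inputs$sign))
      mid <- c(mid, paste0(edge_id(g$inputs$source, nd), "@", g$id))
    }
  }
  mid <- make.unique(mid, sep = "#")
  sint <- as.integer(c(length(states), length(stims), sum(gcount),
                       length(msrc), gcount, mcount, msrc, msign))
  measured <- intersect(states,
                        network$nodes$name[network$nodes$measured])
  structure(list(states = states, stimuli = stims, edge_ids = mid,
                 has_input = gcount > 0, sint = sint,
                 measured = measured, network = network),
            class = "logic_ode_system")
}

#' Default parameters for a logic-ODE system
#'
#' @param network A `logic_network` or `logic_ode_system`.
#' @param tau,n,k Fill values (time scale 1/min; Hill coefficient;
#'   half-effect constant).
#' @return Object of class `ode_params`: list of named vectors `tau`
#'   (every non-stimulus node with inputs), `n` and `k` (every edge).
#' @export
default_ode_params <- function(network, tau = 1, n = 4, k = 0.5) {
  sys <- if (inherits(network, "logic_ode_system")) network
         else logic_ode_system(network)
  tau_v <- rep(tau, length(sys$states)); names(tau_v) <- sys$states
  n_v <- rep(n, length(sys$edge_ids)); names(n_v) <- sys$edge_ids
  k_v <- rep(k, length(sys$edge_ids)); names(k_v) <- sys$edge_ids
  structure(list(tau = tau_v, n = n_v, k = k_v), class = "ode_params")
}

check_ode_params <- function(sys, params) {
  stopifnot(inherits(params, "ode_params"))
  if (!all(sys$states %in% names(params$tau)))
    stopf("tau missing for node '%s'",
          setdiff(sys$states, names(params$tau))[1])
  if (!all(sys$edge_ids %in% names(params$n)) ||
      !all(sys$edge_ids %in% names(params$k)))
    stopf("Hill parameters missing for some edges")
  if (any(params$tau < 0)) stopf("tau must be positive")
  invisible(TRUE)
}

pack_par <- function(sys, params, inputs) {
  stim <- rep(0, length(sys$stimuli)); names(stim) <- sys$stimuli
  hit <- intersect(names(inputs), sys$stimuli)
  stim[hit] <- inputs[hit]
  c(unname(params$tau[sys$states]), unname(params$n[sys$edge_ids]),
    unname(params$k[sys$edge_ids]), unname(stim))
}

#' Simulate a logic-ODE system
#'
#' Integrates the system with a stiff-capable solver (lsoda) under
#' constant stimulus clamps, and reports trajectories clipped to \[0, 1\].
#'
#' @param sys A `logic_ode_system`.
#' @param params An `ode_params` object.
#' @param inputs Named stimulus clamp values (e.g. `c(NaCl = 1, Phe = 0)`);
#'   stimuli not named are 0.  Clamps may be fractional.
#' @param times Output time grid (minutes); the first element is the
#'   initial time.
#' @param y0 Named initial states; default 0 for every node.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame `time` plus one column per state.
#' @export
simulate_logic_ode <- function(sys, params, inputs, times,
                               y0 = NULL, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(sys, "logic_ode_system"))
  check_ode_params(sys, params)
  y <- rep(0, length(sys$states)); names(y) <- sys$states
  if (!is.null(y0)) {
    hit <- intersect(names(y0), sys$states)
    y[hit] <- y0[hit]
  }
  if (length(times) < 2) {
    return(as.data.frame(c(list(time = times),
                           as.list(pmin(pmax(y, 0), 1)))))
  }
  par <- pack_par(sys, params, inputs)
  .Call("costim_set_model", sys$sint, par, PACKAGE = "costim")
  out <- deSolve::lsoda(y = y, times = times, func = "costim_derivs",
                        parms = NULL, dllname = "costim",
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stopf("integration failed for inputs (%s)",
          paste(sprintf("%s=%g", names(inputs), inputs), collapse = ", "))
  df <- as.data.frame(out)
  df[sys$states] <- lapply(df[sys$states], function(v) pmin(1, pmax(0, v)))
  df
}
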