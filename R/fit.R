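## Model fitting: seeded multistart optimisation of logic-ODE parameters
## against MIDAS-style training data, with MSE / AIC model comparison.

#' Mean squared error of simulated trajectories against data
#'
#' Mean of squared residuals over the observed (non-missing) data points
#' of the requested nodes, across all treatment conditions and times.
#'
#' @param residual_table Data frame with columns `node` and `residual`
#'   (e.g. from a `logic_ode_fit`).
#' @param node_subset Nodes to include; must be non-empty.
#' @return Non-negative scalar.
#' @export
mse_residuals <- function(residual_table, node_subset = NULL) {
  if (!is.null(node_subset)) {
    if (!length(node_subset)) stopf("node subset is empty")
    residual_table <- residual_table[residual_table$node %in% node_subset, ]
  }
  r <- residual_table$residual
  r <- r[!is.na(r)]
  if (!length(r)) stopf("no observed data points for the requested nodes")
  mean(r^2)
}

#' Akaike information criterion from an MSE
#'
#' Default formula `n * ln(MSE) + 2 * k` with n data points and k free
#' parameters; higher values indicate more information loss.  An MSE of
#' zero returns `-Inf` with a warning.
#'
#' @param mse Mean squared error.
#' @param n_points Number of data points.
#' @param n_params Number of free parameters.
#' @param formula Currently `"n_log_mse"`.
#' @return AIC value.
#' @export
aic_score <- function(mse, n_points, n_params, formula = "n_log_mse") {
  formula <- match.arg(formula, "n_log_mse")
  if (mse < 0) stopf("mse must be non-negative")
  if (mse == 0) {
    warnf("mse is exactly 0; AIC is -Inf")
    return(-Inf)
  }
  n_points * log(mse) + 2 * n_params
}

## simulate all treatment patterns of a data table and return residuals
sim_residuals <- function(sys, params, data, y0 = NULL, rtol = 1e-6,
                          atol = 1e-8) {
  pats <- unique(data[, c("tr_nacl", "tr_phe")])
  res <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    sel <- data$tr_nacl == pats$tr_nacl[i] & data$tr_phe == pats$tr_phe[i]
    d <- data[sel, ]
    tt <- sort(unique(c(0, d$time)))
    tr <- simulate_logic_ode(sys, params,
                             inputs = c(NaCl = pats$tr_nacl[i],
                                        Phe = pats$tr_phe[i]),
                             times = tt, y0 = y0, rtol = rtol, atol = atol)
    ti <- match(d$time, tr$time)
    nodes <- intersect(unique(d$node), sys$states)
    keep <- d$node %in% nodes
    sim <- vapply(which(keep), function(r) tr[ti[r], d$node[r]], numeric(1))
    res[[i]] <- data.frame(tr_nacl = d$tr_nacl[keep], tr_phe = d$tr_phe[keep],
                           time = d$time[keep], node = d$node[keep],
                           observed = d$value[keep], simulated = sim,
                           residual = d$value[keep] - sim,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Fit a logic-ODE model to MIDAS-style data
#'
#' Transforms the network into logic ODEs and estimates the free
#' parameters by seeded multistart optimisation: `restarts` bounded
#' quasi-Newton runs (the first from the default mid-range parameter
#' values, the rest from uniform random points within the bounds), each
#' minimising the mean squared error between simulated and observed
#' trajectories, under a total objective-evaluation budget.  The
#' best-of-restarts result is returned; identical seeds give identical
#' fits.
#'
#' @param network A `logic_network` (or a precompiled
#'   `logic_ode_system`).
#' @param data Long measurement table with columns `tr_nacl`, `tr_phe`,
#'   `time`, `node`, `value` (see [read_midas()]), values in \[0,1\].
#' @param free Which parameter families to estimate: subset of
#'   `c("tau", "n", "k")`.
#' @param params Starting/fixed parameter values; default
#'   [default_ode_params()].
#' @param restarts Number of optimisation restarts.
#' @param eval_budget Total objective-evaluation budget across restarts.
#' @param seed Integer seed.
#' @param basal Optional named vector of measured basal values used as
#'   initial states (default: the data values at the all-zero treatment,
#'   time 0, when present; otherwise 0).
#' @param bounds List of `c(lower, upper)` per family; defaults
#'   tau 0.05-10, n 1-10, k 0.01-0.99.
#' @param aic_formula Passed to [aic_score()].
#' @return Object of class `logic_ode_fit`.
#' @export
fit_logic_ode <- function(network, data, free = c("tau", "k"),
                          params = NULL, restarts = 10,
                          eval_budget = 20000, seed = 1, basal = NULL,
                          bounds = list(tau = c(0.05, 10), n = c(1, 10),
                                        k = c(0.01, 0.99)),
                          aic_formula = "n_log_mse") {
  sys <- if (inherits(network, "logic_ode_system")) network
         else logic_ode_system(network)
  free <- match.arg(free, c("tau", "n", "k"), several.ok = TRUE)
  if (is.null(params)) params <- default_ode_params(sys)
  check_ode_params(sys, params)
  data <- data[data$node %in% sys$states & !is.na(data$value), ]
  if (!nrow(data)) stopf("no usable data points for this model")
  if (is.null(basal)) {
    b0 <- data[data$tr_nacl == 0 & data$tr_phe == 0 & data$time == 0, ]
    basal <- stats::setNames(b0$value, b0$node)
  }

  ## free-parameter vector layout
  layout <- list()
  if ("tau" %in% free)
    layout$tau <- names(params$tau)[sys$has_input]
  if ("n" %in% free) layout$n <- names(params$n)
  if ("k" %in% free) layout$k <- names(params$k)
  theta0 <- unlist(lapply(names(layout), function(f) params[[f]][layout[[f]]]))
  lower <- unlist(lapply(names(layout), function(f)
    rep(bounds[[f]][1], length(layout[[f]]))))
  upper <- unlist(lapply(names(layout), function(f)
    rep(bounds[[f]][2], length(layout[[f]]))))
  n_free <- length(theta0)
  if (!n_free) stopf("no free parameters selected")

  unpack <- function(theta) {
    p <- params
    off <- 0
    for (f in names(layout)) {
      len <- length(layout[[f]])
      p[[f]][layout[[f]]] <- theta[off + seq_len(len)]
      off <- off + len
    }
    p
  }
  ## precomputed simulation plan: one entry per treatment pattern with the
  ## output-matrix indices of every observed data point
  y0 <- rep(0, length(sys$states)); names(y0) <- sys$states
  hit <- intersect(names(basal), sys$states)
  y0[hit] <- basal[hit]
  pats <- unique(data[, c("tr_nacl", "tr_phe")])
  plan <- lapply(seq_len(nrow(pats)), function(i) {
    sel <- data$tr_nacl == pats$tr_nacl[i] & data$tr_phe == pats$tr_phe[i]
    d <- data[sel, ]
    tt <- sort(unique(c(0, d$time)))
    list(inputs = c(NaCl = pats$tr_nacl[i], Phe = pats$tr_phe[i]),
         times = tt,
         idx = cbind(match(d$time, tt), match(d$node, sys$states) + 1L),
         obs = d$value)
  })
  n_obs <- sum(vapply(plan, function(p) length(p$obs), integer(1)))
  evals <- 0L
  objective <- function(theta) {
    evals <<- evals + 1L
    p <- unpack(theta)
    sse <- 0
    for (pl in plan) {
      if (length(pl$times) < 2) {
        sim <- pmin(pmax(y0[pl$idx[, 2] - 1L], 0), 1)
      } else {
        par <- pack_par(sys, p, pl$inputs)
        .Call("costim_set_model", sys$sint, par, PACKAGE = "costim")
        out <- try(deSolve::lsoda(y0, pl$times, "costim_derivs",
                                  parms = NULL, dllname = "costim",
                                  rtol = 1e-6, atol = 1e-8), silent = TRUE)
        if (inherits(out, "try-error") || nrow(out) < length(pl$times))
          return(1e6)
        sim <- pmin(pmax(out[pl$idx], 0), 1)
      }
      sse <- sse + sum((pl$obs - sim)^2)
    }
    sse / n_obs
  }

  per_restart <- max(50L, floor(eval_budget / restarts))
  best <- NULL
  per_restart_best <- numeric(restarts)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      start <- if (r == 1) theta0 else
        lower + stats::runif(n_free) * (upper - lower)
      opt <- stats::nlminb(start, objective, lower = lower, upper = upper,
                           control = list(eval.max = per_restart,
                                          iter.max = per_restart))
      per_restart_best[r] <- opt$objective
      if (is.null(best) || opt$objective < best$objective) best <- opt
      if (evals >= eval_budget) {
        per_restart_best <- per_restart_best[seq_len(r)]
        break
      }
    }
  })
  fitted_params <- unpack(best$par)
  resid <- sim_residuals(sys, fitted_params, data, y0 = basal)
  mse <- mse_residuals(resid)
  n_points <- sum(!is.na(resid$residual))
  aic <- withCallingHandlers(
    aic_score(mse, n_points, n_free, aic_formula),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(system = sys, params = fitted_params, free = layout,
                 mse = mse, n_points = n_points, n_params = n_free,
                 aic = aic, aic_formula = aic_formula, seed = seed,
                 evals_used = evals, best_per_restart = per_restart_best,
                 residual_table = resid, data = data, basal = basal,
                 call = match.call()),
            class = "logic_ode_fit")
}

#' @export
print.logic_ode_fit <- function(x, ...) {
  cat(sprintf(
    "logic_ode_fit: %d states, %d free parameters\n  MSE = %.5g on %d points, AIC = %.4g (%s)\n  %d restarts (best per restart: %s), %d evaluations, seed %d\n",
    length(x$system$states), x$n_params, x$mse, x$n_points, x$aic,
    x$aic_formula, length(x$best_per_restart),
    paste(signif(sort(x$best_per_restart)[seq_len(min(3, length(x$best_per_restart)))], 3),
          collapse = ", "), x$evals_used, x$seed))
  invisible(x)
}

#' @export
summary.logic_ode_fit <- function(object, ...) {
  print(object)
  cat("\nTime scales (tau, 1/min):\n")
  print(signif(object$params$tau[object$system$has_input], 3))
  cat("\nResiduals by node (RMS):\n")
  rms <- sqrt(tapply(object$residual_table$residual^2,
                     object$residual_table$node, mean, na.rm = TRUE))
  print(signif(sort(rms, decreasing = TRUE), 3))
  invisible(object)
}

#' @export
coef.logic_ode_fit <- function(object, ...) {
  unlist(lapply(names(object$free), function(f) {
    v <- object$params[[f]][object$free[[f]]]
    names(v) <- paste0(f, ".", object$free[[f]])
    v
  }))
}

#' @export
residuals.logic_ode_fit <- function(object, ...) {
  object$residual_table$residual
}

#' @export
fitted.logic_ode_fit <- function(object, ...) {
  object$residual_table$simulated
}

#' Predict trajectories from a fitted logic-ODE model
#'
#' @param object A `logic_ode_fit`.
#' @param treatments Data frame `tr_nacl`, `tr_phe`; default the fitted
#'   treatment patterns.
#' @param times Output times (minutes).
#' @param ... Unused.
#' @return Long data frame `tr_nacl`, `tr_phe`, `time`, `node`, `value`.
#' @export
predict.logic_ode_fit <- function(object, treatments = NULL,
                                  times = NULL, ...) {
  if (is.null(treatments))
    treatments <- unique(object$data[, c("tr_nacl", "tr_phe")])
  if (is.null(times)) times <- sort(unique(c(0, object$data$time)))
  out <- lapply(seq_len(nrow(treatments)), function(i) {
    tr <- simulate_logic_ode(object$system, object$params,
                             inputs = c(NaCl = treatments$tr_nacl[i],
                                        Phe = treatments$tr_phe[i]),
                             times = times, y0 = object$basal)
    data.frame(tr_nacl = treatments$tr_nacl[i],
               tr_phe = treatments$tr_phe[i],
               time = rep(tr$time, length(object$system$states)),
               node = rep(object$system$states, each = nrow(tr)),
               value = unlist(tr[object$system$states], use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate from a fitted logic-ODE model
#'
#' @param object A `logic_ode_fit`.
#' @param nsim Number of simulations (trajectories are deterministic, so
#'   repetitions are identical; provided for generic compatibility).
#' @param seed Ignored (deterministic model).
#' @param ... Passed to [predict.logic_ode_fit()].
#' @return A list of `nsim` prediction tables.
#' @export
simulate.logic_ode_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lapply(seq_len(nsim), function(i) predict(object, ...))
}

#' Plot fitted trajectories against the training data
#'
#' One panel per treatment pattern for a chosen node.
#'
#' @param x A `logic_ode_fit`.
#' @param node Node to display; default the worst-fitting node.
#' @param ... Unused.
#' @export
plot.logic_ode_fit <- function(x, node = NULL, ...) {
  rt <- x$residual_table
  if (is.null(node)) {
    rms <- tapply(rt$residual^2, rt$node, mean, na.rm = TRUE)
    node <- names(which.max(rms))
  }
  pats <- unique(rt[, c("tr_nacl", "tr_phe")])
  old <- graphics::par(mfrow = c(1, nrow(pats)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  times <- sort(unique(c(0, rt$time)))
  pred <- predict(x, times = seq(0, max(times), length.out = 50))
  for (i in seq_len(nrow(pats))) {
    d <- rt[rt$tr_nacl == pats$tr_nacl[i] & rt$tr_phe == pats$tr_phe[i] &
              rt$node == node, ]
    p <- pred[pred$tr_nacl == pats$tr_nacl[i] &
                pred$tr_phe == pats$tr_phe[i] & pred$node == node, ]
    graphics::plot(p$time, p$value, type = "l", ylim = c(0, 1),
                   xlab = "time (min)", ylab = node,
                   main = sprintf("NaCl=%g Phe=%g", pats$tr_nacl[i],
                                  pats$tr_phe[i]))
    graphics::points(d$time, d$observed, pch = 16)
  }
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' Recomputes each fit's MSE on a common measured-node subset (the nodes
#' present in every compared model by default) and ranks the ensemble by
#' AIC ascending.
#'
#' @param fits Named list of `logic_ode_fit` objects.
#' @param node_subset Nodes on which the MSE is evaluated; default the
#'   intersection of measured nodes across all fits.
#' @return Data frame `model`, `mse`, `n_params`, `aic`, sorted by AIC.
#' @export
compare_models <- function(fits, node_subset = NULL) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "logic_ode_fit")))
  if (is.null(names(fits)))
    names(fits) <- sprintf("M%02d", seq_along(fits))
  measured <- lapply(fits, function(f)
    intersect(f$system$measured, unique(f$residual_table$node)))
  common <- Reduce(intersect, measured)
  if (is.null(node_subset)) node_subset <- common
  if (!length(node_subset)) stopf("empty node subset")
  if (!all(node_subset %in% common))
    stopf("node subset not evaluated in every fit: %s",
          paste(setdiff(node_subset, common), collapse = ", "))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    m <- mse_residuals(f$residual_table, node_subset)
    n <- sum(!is.na(f$residual_table$residual[
      f$residual_table$node %in% node_subset]))
    a <- withCallingHandlers(aic_score(m, n, f$n_params, f$aic_formula),
                             warning = function(w) invokeRestart("muffleWarning"))
    data.frame(model = nm, mse = m, n_params = f$n_params, aic = a,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  out
}
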