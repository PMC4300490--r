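#' Measurement noise model
#'
#' Log-normal multiplicative measurement noise with per-run scale factors
#' (one MS run = one condition x replicate) and missing-completely-at-
#' random dropout.  An optional intensity-dependent dropout (logistic in
#' log-intensity) is available for robustness experiments.
#'
#' @param cv_multiplicative Coefficient of variation of the multiplicative
#'   noise (fraction, >= 0).  The log-normal sigma is
#'   `sqrt(log(1 + cv^2))`.
#' @param tic_spread Standard deviation (log scale) of the per-run scale
#'   factor.
#' @param missing_rate Probability that a single (peptide, condition,
#'   replicate) observation is missing; must be < 1.
#' @param dropout_intensity Optional list `list(mid=, slope=)`: when
#'   given, dropout probability follows
#'   `plogis(-(log10(x) - mid) * slope)` instead of `missing_rate`.
#' @param background_factor The recorded run TIC is the sum of the
#'   panel's observed intensities plus a stable background representing
#'   the rest of the detected phosphoproteome (an MS run's TIC is
#'   dominated by peptides outside any one pathway panel); the background
#'   equals this factor times the panel-average run total, scaled by the
#'   run factor.  Set to 0 for a panel-only TIC.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(cv_multiplicative = 0.2, tic_spread = 0.15,
                        missing_rate = 0.05, dropout_intensity = NULL,
                        background_factor = 20) {
  if (cv_multiplicative < 0) stopf("cv_multiplicative must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must be in [0, 1)")
  if (background_factor < 0) stopf("background_factor must be >= 0")
  structure(list(cv_multiplicative = cv_multiplicative,
                 tic_spread = tic_spread, missing_rate = missing_rate,
                 dropout_intensity = dropout_intensity,
                 background_factor = background_factor),
            class = "noise_model")
}

#' Add measurement noise to a truth object
#'
#' Turns noise-free surfaces into a replicate-level co-stimulation dataset:
#' observed = truth x run scale x exp(eps), with eps ~ Normal(0, sigma) and
#' sigma matching the multiplicative CV; each observation is independently
#' missing with the configured probability.  The total ion current (TIC)
#' of each run is recorded as the sum of all observed intensities in that
#' run.  Per-peptide overrides in the panel (`cv`, `missing_rate`,
#' `drop_conditions`) take precedence over the global noise model.
#'
#' @param truth Result of [generate_truth()].
#' @param design A [stim_design()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical inputs and seed give identical
#'   datasets.
#' @return A `costim_data` long-format data frame (see
#'   [as_costim_data()]); planted labels are attached as attribute
#'   `"labels"`.
#' @export
add_noise <- function(truth, design, noise = noise_model(), seed = 1) {
  stopifnot(inherits(design, "stim_design"), inherits(noise, "noise_model"))
  panel <- truth$panel
  arr <- truth$intensity
  ppeps <- dimnames(arr)[[1]]
  conds <- design$conditions
  nrep <- design$n_replicates
  n_ppep <- length(ppeps); n_cond <- nrow(conds)

  cvs <- rep(noise$cv_multiplicative, n_ppep)
  mrs <- rep(noise$missing_rate, n_ppep)
  drops <- rep("", n_ppep)
  if (!is.null(panel)) {
    idx <- match(ppeps, panel$ppep_id)
    ok <- !is.na(idx)
    if (!is.null(panel$cv))
      cvs[ok] <- ifelse(is.na(panel$cv[idx[ok]]), cvs[ok], panel$cv[idx[ok]])
    if (!is.null(panel$missing_rate))
      mrs[ok] <- ifelse(is.na(panel$missing_rate[idx[ok]]), mrs[ok],
                        panel$missing_rate[idx[ok]])
    if (!is.null(panel$drop_conditions))
      drops[ok] <- panel$drop_conditions[idx[ok]]
  }
  sigmas <- sqrt(log(1 + cvs^2))

  i_nacl <- match(conds$t_nacl, design$nacl_times)
  i_phe <- match(conds$t_phe, design$phe_times)
  cond_lab <- condition_name(conds$t_nacl, conds$t_phe)
  background <- noise$background_factor * sum(arr) / n_cond

  with_seed(seed, {
    rows <- vector("list", n_cond * nrep)
    run_bgs <- numeric(n_cond * nrep)
    run_names <- character(n_cond * nrep)
    k <- 0L
    for (ci in seq_len(n_cond)) {
      tru <- arr[, i_nacl[ci], i_phe[ci]]
      for (rep_i in seq_len(nrep)) {
        run_scale <- exp(stats::rnorm(1, 0, noise$tic_spread))
        run_bg <- background * run_scale
        eps <- stats::rnorm(n_ppep, 0, sigmas)
        obs <- tru * run_scale * exp(eps)
        if (is.null(noise$dropout_intensity)) {
          miss <- stats::runif(n_ppep) < mrs
        } else {
          p <- stats::plogis(-(log10(obs) - noise$dropout_intensity$mid) *
                               noise$dropout_intensity$slope)
          miss <- stats::runif(n_ppep) < p
        }
        miss <- miss | vapply(drops, function(d)
          nzchar(d) && cond_lab[ci] %in% strsplit(d, ";")[[1]], logical(1))
        obs[miss] <- NA_real_
        k <- k + 1L
        run_bgs[k] <- run_bg
        run_names[k] <- sprintf("%s_r%d", cond_lab[ci], rep_i)
        rows[[k]] <- data.frame(
          ppep_id = ppeps,
          t_nacl = conds$t_nacl[ci], t_phe = conds$t_phe[ci],
          replicate = rep_i,
          run_id = sprintf("%s_r%d", cond_lab[ci], rep_i),
          intensity = obs, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (!is.null(panel)) {
      m <- match(out$ppep_id, panel$ppep_id)
      out$protein <- panel$protein[m]
      out$sites <- panel$sites[m]
      out$sequence <- panel$sequence[m]
      out$n_phospho <- panel$n_phospho[m]
    } else {
      out$protein <- sub("_.*$", "", out$ppep_id)
      out$sites <- sub("^[^_]*_", "", out$ppep_id)
      out$sequence <- synth_sequence(out$ppep_id)
      out$n_phospho <- 1L
    }
    tic <- tapply(out$intensity, out$run_id, sum, na.rm = TRUE)
    tic <- tic + run_bgs[match(names(tic), run_names)]
    out$tic <- as.numeric(tic[out$run_id])
    out <- out[, c("ppep_id", "protein", "sites", "sequence", "n_phospho",
                   "t_nacl", "t_phe", "replicate", "run_id", "intensity",
                   "tic")]
    ds <- as_costim_data(out, design)
    attr(ds, "labels") <- truth$labels
    ds
  })
}

#' Generate a complete synthetic co-stimulation dataset
#'
#' Convenience wrapper: [generate_truth()] followed by [add_noise()].
#'
#' @inheritParams add_noise
#' @param panel An [archetype_panel()].
#' @param network,params Optional ground-truth logic network and
#'   parameters (see [generate_truth()]).
#' @return A `costim_data` long-format dataset with attribute `"labels"`.
#' @examples
#' d <- sim_costim(panel_effects(), stim_design(),
#'                 noise_model(0.05, 0, 0), seed = 1)
#' @export
sim_costim <- function(panel, design = stim_design(),
                       noise = noise_model(), seed = 1,
                       network = NULL, params = NULL) {
  truth <- generate_truth(panel, design, network = network, params = params)
  add_noise(truth, design, noise, seed = seed)
}
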