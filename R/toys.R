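## Small reference networks and training-data helpers used in examples,
## benchmarks and the acceptance analyses.

#' Six-node crosstalk benchmark network
#'
#' A compact two-pathway logic network used for parameter-recovery
#' benchmarks: a three-step cascade driven by one stimulus (A -> B -> C),
#' a two-step cascade driven by the other (D -> E), an inhibitory
#' crosstalk edge from the first cascade onto the second (A -| E), and a
#' convergence node (C and E activate F).  All six nodes are measured.
#'
#' @return A `logic_network` with stimuli `NaCl` and `Phe`.
#' @export
toy_crosstalk_network <- function() {
  logic_network(
    nodes = data.frame(
      name = c("NaCl", "Phe", "A", "B", "C", "D", "E", "F"),
      role = c("STIMULUS", "STIMULUS", rep("PPEP", 6)),
      measured = c(FALSE, FALSE, rep(TRUE, 6))),
    edges = data.frame(
      source = c("NaCl", "A", "B", "Phe", "D", "A", "C", "E"),
      sign   = c(1, 1, 1, 1, 1, -1, 1, 1),
      target = c("A", "B", "C", "D", "E", "E", "F", "F")))
}

#' Reference parameters for the benchmark network
#'
#' Heterogeneous time scales (0.25-0.9 per minute) with default Hill
#' edge parameters; used as the ground truth in parameter-recovery
#' benchmarks.
#'
#' @return An `ode_params` object for [toy_crosstalk_network()].
#' @export
toy_crosstalk_params <- function() {
  p <- default_ode_params(toy_crosstalk_network())
  p$tau[c("A", "B", "C", "D", "E", "F")] <- c(0.6, 0.3, 0.9, 0.4, 0.7, 0.25)
  p
}

#' Noise-free training data from a known logic-ODE model
#'
#' Simulates the common-time-origin training conditions of a design
#' (stimulus alone and simultaneous co-stimulation; see
#' [select_training_conditions()]) and returns the measured node values
#' as a long MIDAS-style table -- the input expected by
#' [fit_logic_ode()].
#'
#' @param network A `logic_network` (or `logic_ode_system`).
#' @param params An `ode_params` object.
#' @param design A [stim_design()].
#' @return Data frame `tr_nacl`, `tr_phe`, `time`, `node`, `value`.
#' @export
simulate_training_data <- function(network, params,
                                   design = stim_design()) {
  sys <- if (inherits(network, "logic_ode_system")) network
         else logic_ode_system(network)
  tc <- select_training_conditions(design)
  rows <- unique(data.frame(tr_nacl = as.numeric(tc$t_nacl > 0),
                            tr_phe = as.numeric(tc$t_phe > 0),
                            time = pmax(tc$t_nacl, tc$t_phe)))
  out <- lapply(split(rows, paste(rows$tr_nacl, rows$tr_phe)), function(g) {
    tt <- sort(unique(c(0, g$time)))
    tr <- simulate_logic_ode(sys, params,
                             inputs = c(NaCl = g$tr_nacl[1],
                                        Phe = g$tr_phe[1]), times = tt)
    do.call(rbind, lapply(g$time, function(t1)
      data.frame(tr_nacl = g$tr_nacl[1], tr_phe = g$tr_phe[1], time = t1,
                 node = sys$measured,
                 value = unlist(tr[tr$time == t1, sys$measured]),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
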