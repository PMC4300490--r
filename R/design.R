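#' Co-stimulation design
#'
#' Builds the two-stimulus stimulation matrix: every combination of a NaCl
#' stimulation period and a pheromone stimulation period (minutes before
#' harvest).  A period of 0 means the stimulus was never applied.  The
#' default is the 6 x 6 matrix of periods 0, 1, 5, 10, 20 and 45 minutes
#' with three biological replicates per condition.
#'
#' @param nacl_times NaCl stimulation periods in minutes; must start at 0
#'   and be strictly increasing.
#' @param phe_times Pheromone stimulation periods, same constraints.
#' @param n_replicates Number of biological replicates per condition.
#' @return An object of class `stim_design`: a list with the two time
#'   vectors, the replicate count and a `conditions` data frame holding the
#'   full cross product.
#' @examples
#' d <- stim_design()
#' nrow(d$conditions)  # 36
#' @export
stim_design <- function(nacl_times = c(0, 1, 5, 10, 20, 45),
                        phe_times = c(0, 1, 5, 10, 20, 45),
                        n_replicates = 3) {
  check_times <- function(x, what) {
    if (length(x) < 1 || x[1] != 0)
      stopf("%s must start at 0 (got first value %s)", what,
            if (length(x)) x[1] else "none")
    if (any(diff(x) <= 0))
      stopf("%s must be strictly increasing", what)
    as.numeric(x)
  }
  nacl_times <- check_times(nacl_times, "nacl_times")
  phe_times <- check_times(phe_times, "phe_times")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  conditions <- expand.grid(t_nacl = nacl_times, t_phe = phe_times,
                            KEEP.OUT.ATTRS = FALSE)
  ## order: pheromone duration outer, NaCl inner (row-wise sub-experiments)
  conditions <- conditions[order(conditions$t_phe, conditions$t_nacl), ,
                           drop = FALSE]
  rownames(conditions) <- NULL
  structure(list(nacl_times = nacl_times, phe_times = phe_times,
                 n_replicates = as.integer(n_replicates),
                 conditions = conditions),
            class = "stim_design")
}

#' @export
print.stim_design <- function(x, ...) {
  cat("Co-stimulation design:",
      sprintf("%d NaCl x %d pheromone periods = %d conditions, %d replicates\n",
              length(x$nacl_times), length(x$phe_times),
              nrow(x$conditions), x$n_replicates))
  cat("  NaCl periods (min):", paste(x$nacl_times, collapse = ", "), "\n")
  cat("  Pheromone periods (min):", paste(x$phe_times, collapse = ", "), "\n")
  invisible(x)
}

#' Condition label used for surface columns
#'
#' @param t_nacl,t_phe Stimulation periods (vectors of equal length).
#' @return Character vector like `"t5_p10"`.
#' @export
condition_name <- function(t_nacl, t_phe) {
  sprintf("t%g_p%g", t_nacl, t_phe)
}

#' Training conditions for logic modelling
#'
#' The modelling stage uses only the conditions with a common time origin:
#' stimulation with NaCl only, pheromone only, and both stimuli applied
#' simultaneously -- the first row, the first column and the diagonal of
#' the stimulation matrix, with the shared basal corner counted once.  On
#' the default 6 x 6 design this selects 16 of the 36 conditions.
#'
#' @param design A [stim_design()].
#' @return Data frame with columns `t_nacl`, `t_phe`.
#' @examples
#' nrow(select_training_conditions(stim_design()))  # 16
#' @export
select_training_conditions <- function(design) {
  stopifnot(inherits(design, "stim_design"))
  row1 <- data.frame(t_nacl = design$nacl_times, t_phe = 0)
  col1 <- data.frame(t_nacl = 0, t_phe = design$phe_times)
  m <- min(length(design$nacl_times), length(design$phe_times))
  diag <- data.frame(t_nacl = design$nacl_times[seq_len(m)],
                     t_phe = design$phe_times[seq_len(m)])
  out <- unique(rbind(row1, col1, diag))
  out <- out[order(out$t_phe, out$t_nacl), , drop = FALSE]
  rownames(out) <- NULL
  out
}
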