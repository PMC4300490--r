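## Dynamic archetypes for the synthetic co-stimulation generator.
##
## Each synthetic phosphopeptide follows a base temporal shape along the
## time axis of its driving stimulus, optionally distorted by the duration
## of the other (modulating) stimulus.  The closed forms mimic the two
## canonical MAPK behaviours: a fast transient spike (maximal within 5 min,
## Hog1-like) and a gradual sigmoidal rise peaking around 20 min
## (Fus3-like).

BASE_SHAPES <- c("SPIKE", "GRADUAL", "SUSTAINED", "FLAT")
MODIFIERS <- c("NONE", "DIP_AT", "SCALE_BY_T2", "PHASE_SHIFT_BY_T2")
EFFECT_LABELS <- c("SHAPE", "INTENSITY", "NONE")

## basal fraction added to non-flat shapes so intensities stay > 0
.basal_frac <- 0.1

#' Evaluate a base temporal shape
#'
#' @param shape One of `"SPIKE"`, `"GRADUAL"`, `"SUSTAINED"`, `"FLAT"`.
#' @param t Time in minutes (vector).
#' @param peak Peak time of the spike (minutes).
#' @param half Half-rise time of the gradual sigmoid (minutes).
#' @return Shape values in (0, 1]; non-flat shapes carry a 10% basal level.
#' @keywords internal
shape_value <- function(shape, t, peak = 5, half = 10) {
  raw <- switch(shape,
    SPIKE = (t / peak) * exp(1 - t / peak),
    GRADUAL = {
      g <- 1 / (1 + exp(-(t - half) / 3))
      decay <- ifelse(t > 20, pmax(0, 1 - 0.01 * (t - 20)), 1)
      g * decay
    },
    SUSTAINED = 1 - exp(-t / 5),
    FLAT = rep(1, length(t)),
    stopf("unknown base shape '%s'", shape))
  if (shape == "FLAT") raw else .basal_frac + (1 - .basal_frac) * raw
}

#' Archetype panel constructor
#'
#' Assembles and validates a table of synthetic phosphopeptide archetypes.
#' One row per phosphopeptide; planted effect labels must be consistent
#' with the crosstalk modifier (`SCALE_BY_T2`/`DIP_AT` imply an Intensity
#' label for the modulating stimulus, `PHASE_SHIFT_BY_T2` a Shape label).
#'
#' @param df Data frame with columns `ppep_id`, `protein`, `sites`,
#'   `base_shape`, `driving` ("NaCl" or "Phe"), `modifier`, `amplitude`,
#'   and planted labels `label_nacl`, `label_phe`.  Optional columns:
#'   `dip_time`, `dip_factor`, `scale_max`, `shift_step`, `cv`,
#'   `missing_rate`, `drop_conditions`, `known_function`, `sequence`,
#'   `n_phospho`.
#' @return The validated data frame, class `archetype_panel`.
#' @export
archetype_panel <- function(df) {
  need <- c("ppep_id", "protein", "sites", "base_shape", "driving",
            "modifier", "amplitude", "label_nacl", "label_phe")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("archetype panel lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$ppep_id))
    stopf("duplicate ppep_id in archetype panel")
  bad <- setdiff(unique(df$base_shape), BASE_SHAPES)
  if (length(bad)) stopf("unknown base shape '%s'", bad[1])
  bad <- setdiff(unique(df$modifier), MODIFIERS)
  if (length(bad)) stopf("unknown crosstalk modifier '%s'", bad[1])
  if (any(df$amplitude <= 0)) stopf("amplitudes must be positive")
  stopifnot(all(df$driving %in% c("NaCl", "Phe")),
            all(df$label_nacl %in% EFFECT_LABELS),
            all(df$label_phe %in% EFFECT_LABELS))
  ## defaults for optional columns
  opt <- list(dip_time = 1, dip_factor = 0.3, scale_max = 2.5,
              shift_step = 6, peak = 5, half = 10, cv = NA_real_,
              missing_rate = NA_real_, drop_conditions = "",
              known_function = TRUE, n_phospho = NA_integer_,
              sequence = NA_character_)
  for (nm in names(opt)) if (is.null(df[[nm]])) df[[nm]] <- opt[[nm]]
  if (any(is.na(df$n_phospho)))
    df$n_phospho <- pmax(1L, lengths(strsplit(df$sites, "_")))
  if (any(is.na(df$sequence)))
    df$sequence <- synth_sequence(df$ppep_id)
  ## planted labels must agree with the modifier on the modulating axis
  mod_lab <- ifelse(df$driving == "NaCl", df$label_phe, df$label_nacl)
  chk <- function(mods, lab)
    any(df$modifier %in% mods & mod_lab != lab)
  if (chk(c("SCALE_BY_T2", "DIP_AT"), "INTENSITY"))
    stopf("SCALE_BY_T2/DIP_AT archetypes must plant an INTENSITY label for the modulating stimulus")
  if (chk("PHASE_SHIFT_BY_T2", "SHAPE"))
    stopf("PHASE_SHIFT_BY_T2 archetypes must plant a SHAPE label for the modulating stimulus")
  class(df) <- c("archetype_panel", "data.frame")
  df
}

## deterministic pseudo-tryptic backbone for a ppep id
synth_sequence <- function(ids) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  vapply(ids, function(id) {
    h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
    n <- 8 + h %% 9
    idx <- (h + cumsum(seq_len(n) * 7L)) %% length(aa) + 1L
    paste0(paste(aa[idx], collapse = ""), "K")
  }, character(1), USE.NAMES = FALSE)
}

#' Noise-free intensity surfaces for an archetype panel
#'
#' Evaluates every archetype on the stimulation matrix, giving for each
#' phosphopeptide a strictly positive noise-free intensity for every
#' condition.  If a ground-truth logic network is supplied, trajectories
#' come from the logic-ODE simulator instead of the closed forms: each
#' condition is simulated with the stimuli switched on for their respective
#' stimulation periods before harvest, and measured node states are mapped
#' to intensities.
#'
#' @param panel An [archetype_panel()] (ignored when `network` is given,
#'   except for amplitudes matched by node name).
#' @param design A [stim_design()].
#' @param network Optional `logic_network` ground truth.
#' @param params Optional `ode_params` for the network.
#' @return List with `intensity` (3-d array: ppep x NaCl period x pheromone
#'   period), `labels` (data frame of planted labels) and the panel.
#' @export
generate_truth <- function(panel, design, network = NULL, params = NULL) {
  stopifnot(inherits(design, "stim_design"))
  if (!is.null(network))
    return(truth_from_network(network, params, design, panel))
  panel <- if (inherits(panel, "archetype_panel")) panel else
    archetype_panel(panel)
  nn <- length(design$nacl_times); np <- length(design$phe_times)
  arr <- array(NA_real_, dim = c(nrow(panel), nn, np),
               dimnames = list(panel$ppep_id, NULL, NULL))
  for (r in seq_len(nrow(panel)))
    arr[r, , ] <- truth_surface(panel[r, ], design)
  stopifnot(all(arr > 0))
  labels <- data.frame(ppep_id = panel$ppep_id,
                       label_nacl = panel$label_nacl,
                       label_phe = panel$label_phe,
                       stringsAsFactors = FALSE)
  list(intensity = arr, labels = labels, panel = panel)
}

## 6 x 6 (NaCl x pheromone) noise-free surface for one archetype row
truth_surface <- function(row, design) {
  tn <- design$nacl_times; tp <- design$phe_times
  if (row$driving == "NaCl") { t1 <- tn; t2 <- tp } else { t1 <- tp; t2 <- tn }
  n1 <- length(t1); n2 <- length(t2)
  base <- shape_value(row$base_shape, t1, peak = row$peak, half = row$half)
  ## surface in (t1, t2) orientation, then transposed if pheromone-driven
  s <- matrix(base, nrow = n1, ncol = n2)
  if (row$modifier == "DIP_AT") {
    j <- match(row$dip_time, t2)
    if (is.na(j)) stopf("dip_time %g not a %s period", row$dip_time,
                        if (row$driving == "NaCl") "pheromone" else "NaCl")
    s[, j] <- s[, j] * row$dip_factor
  } else if (row$modifier == "SCALE_BY_T2") {
    sc <- 1 + (row$scale_max - 1) * (seq_len(n2) - 1) / max(1, n2 - 1)
    s <- sweep(s, 2, sc, "*")
  } else if (row$modifier == "PHASE_SHIFT_BY_T2") {
    ## characteristic time shifts in three duration groups, giving three
    ## clearly distinct curve shapes along the driving axis
    grp <- ceiling(seq_len(n2) / max(1, ceiling(n2 / 3)))
    for (j in seq_len(n2)) {
      sh <- row$shift_step * (grp[j] - 1)
      s[, j] <- shape_value(row$base_shape, t1, peak = row$peak + sh,
                            half = row$half + sh)
    }
  }
  out <- if (row$driving == "NaCl") s else t(s)
  row$amplitude * out
}

## ground-truth trajectories from a logic network: simulate each condition
## with stimuli stepped on for their stimulation periods before harvest
truth_from_network <- function(network, params, design, panel = NULL) {
  sys <- logic_ode_system(network)
  if (is.null(params)) params <- default_ode_params(network)
  meas <- network$nodes$name[network$nodes$measured]
  nn <- length(design$nacl_times); np <- length(design$phe_times)
  arr <- array(NA_real_, dim = c(length(meas), nn, np),
               dimnames = list(meas, NULL, NULL))
  amp <- rep(1e6, length(meas)); names(amp) <- meas
  if (!is.null(panel)) {
    hit <- intersect(meas, panel$ppep_id)
    amp[hit] <- panel$amplitude[match(hit, panel$ppep_id)]
  }
  for (i in seq_len(nn)) for (j in seq_len(np)) {
    a <- design$nacl_times[i]; b <- design$phe_times[j]
    state <- harvest_state(sys, params, a, b)
    arr[, i, j] <- amp * (0.05 + state[meas])
  }
  labels <- data.frame(ppep_id = meas, label_nacl = NA_character_,
                       label_phe = NA_character_)
  list(intensity = arr, labels = labels, panel = panel)
}

## simulate a (NaCl period a, pheromone period b) co-stimulation and
## return the state vector at harvest
harvest_state <- function(sys, params, a, b) {
  y0 <- rep(0, length(sys$states)); names(y0) <- sys$states
  first <- max(a, b) - min(a, b)
  inputs1 <- c(NaCl = as.numeric(a >= b & a > 0),
               Phe = as.numeric(b >= a & b > 0))
  if (first > 0) {
    tr <- simulate_logic_ode(sys, params, inputs = inputs1,
                             times = c(0, first), y0 = y0)
    y0 <- unlist(tr[nrow(tr), sys$states])
  }
  second <- min(a, b)
  inputs2 <- c(NaCl = as.numeric(a > 0), Phe = as.numeric(b > 0))
  if (second > 0) {
    tr <- simulate_logic_ode(sys, params, inputs = inputs2,
                             times = c(0, second), y0 = y0)
    y0 <- unlist(tr[nrow(tr), sys$states])
  }
  y0
}
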