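## Built-in archetype panels.
##
## `panel_effects()` is the 60-peptide panel used to benchmark the
## Shape/Intensity classifier against planted labels; `panel_modeling()`
## is the synthetic stand-in for the study's replicate-level measurement
## table, designed with known filtering ground truth (33 modelling
## peptides plus peptides planted to fail each filter).

#' 60-phosphopeptide panel with planted effect labels
#'
#' Balanced panel of dynamic archetypes covering all effect-label
#' combinations the classifier must recover: flat no-responders, spike and
#' gradual responders to a single stimulus, uniformly scaled and
#' transiently dipped intensity modulation, and phase-shifting shape
#' modulation.  Planted labels follow the archetype construction: a
#' non-flat responder is Intensity-modulated along its own driving axis
#' (its response level varies strongly with its own stimulation period),
#' the modulating axis label comes from the crosstalk modifier.
#'
#' @return An [archetype_panel()] of 60 rows.
#' @export
panel_effects <- function() {
  amp <- function(n, lo = 5, hi = 7)  # log10-spread amplitudes
    10^seq(lo, hi, length.out = n)
  mk <- function(n, prot, shape, driving, modifier, lab_n, lab_p) {
    data.frame(
      ppep_id = sprintf("%s_S%d", prot, 100 + seq_len(n)),
      protein = prot,
      sites = sprintf("S%d", 100 + seq_len(n)),
      base_shape = shape, driving = driving, modifier = modifier,
      amplitude = amp(n), label_nacl = lab_n, label_phe = lab_p,
      stringsAsFactors = FALSE)
  }
  panel <- rbind(
    mk(8, "Flt", "FLAT",    "NaCl", "NONE",              "NONE",      "NONE"),
    mk(8, "SpN", "SPIKE",   "NaCl", "NONE",              "INTENSITY", "NONE"),
    mk(6, "GrN", "GRADUAL", "NaCl", "NONE",              "INTENSITY", "NONE"),
    mk(8, "GrP", "GRADUAL", "Phe",  "NONE",              "NONE",      "INTENSITY"),
    mk(6, "SpP", "SPIKE",   "Phe",  "NONE",              "NONE",      "INTENSITY"),
    mk(8, "Scl", "SPIKE",   "NaCl", "SCALE_BY_T2",       "INTENSITY", "INTENSITY"),
    mk(6, "Dip", "SPIKE",   "NaCl", "DIP_AT",            "INTENSITY", "INTENSITY"),
    mk(10, "Shp", "SPIKE",  "NaCl", "PHASE_SHIFT_BY_T2", "SHAPE",     "SHAPE"))
  archetype_panel(panel)
}

#' Synthetic replicate-level measurement panel for the modelling filters
#'
#' Stand-in for the study's full phosphopeptide measurement table on the
#' HOG/pheromone pathway proteins, with known filtering ground truth.  It
#' contains the 33 modelling phosphopeptides (each with a distinct
#' low-noise trajectory; `known_function = TRUE`), plus 6 redundant
#' same-protein duplicates (near-identical trajectories,
#' `known_function = FALSE`, removed by affinity-propagation merging),
#' 5 high-variability peptides (replicate CV planted at 0.6, removed by
#' the CV filter) and 4 peptides with structurally missing conditions
#' (6 of the 16 training conditions undetected, removed by the
#' missingness filter).
#'
#' @return An [archetype_panel()] of 48 rows.
#' @export
panel_modeling <- function() {
  core <- modeling_ppep_table()
  ## explicit, mutually distinct dynamics for every modelling peptide;
  ## same-protein peptides differ in driving stimulus, base shape and
  ## characteristic time so affinity propagation keeps them apart, while
  ## the planted duplicates below are near-copies
  dyn <- list(                      # shape, driving, modifier, peak, half, scale_max
    Ste20_T511      = list("SPIKE",     "NaCl", "NONE",        5, 10, 2.5),
    Ste20_S195      = list("SPIKE",     "NaCl", "SCALE_BY_T2", 15, 10, 2.5),
    Ste20_T573      = list("GRADUAL",   "Phe",  "NONE",        5,  8, 2.5),
    Ste20_T203_T207 = list("SUSTAINED", "NaCl", "NONE",        5, 10, 2.5),
    Ste20_S418      = list("GRADUAL",   "NaCl", "SCALE_BY_T2", 5, 18, 2.2),
    Ste20_S192      = list("SPIKE",     "Phe",  "NONE",        5, 10, 2.5),
    Ste20_T546      = list("SUSTAINED", "Phe",  "SCALE_BY_T2", 5, 10, 2.5),
    Hog1_T174       = list("SUSTAINED", "NaCl", "NONE",        5, 10, 2.5),
    Hog1_T174_Y176  = list("SPIKE",     "NaCl", "DIP_AT",      5, 10, 2.5),
    Pbs2_S68        = list("GRADUAL",   "Phe",  "NONE",        5,  6, 2.5),
    Pbs2_S248       = list("SPIKE",     "NaCl", "SCALE_BY_T2", 5, 10, 2.5),
    Pbs2_S269       = list("SUSTAINED", "NaCl", "NONE",        5, 10, 2.5),
    Ssk1_S110       = list("GRADUAL",   "Phe",  "NONE",        5, 10, 2.5),
    Ssk1_S673       = list("SPIKE",     "NaCl", "SCALE_BY_T2", 8, 10, 2.5),
    Dig1_S272       = list("GRADUAL",   "Phe",  "SCALE_BY_T2", 5, 12, 2.0),
    Dig1_S330       = list("SPIKE",     "Phe",  "NONE",        8, 10, 2.5),
    Fus3_T180_Y182  = list("GRADUAL",   "Phe",  "SCALE_BY_T2", 5, 10, 2.5),
    Sln1_S1076      = list("SPIKE",     "NaCl", "NONE",        3, 10, 2.5),
    Ste11_S323      = list("SPIKE",     "NaCl", "DIP_AT",      5, 10, 2.5),
    Ste50_S202      = list("SPIKE",     "Phe",  "DIP_AT",      3, 10, 2.5),
    Ptp2_S258       = list("SPIKE",     "Phe",  "DIP_AT",      5, 10, 2.5),
    Gpd1_S24_S27    = list("SPIKE",     "Phe",  "NONE",        3, 10, 2.5),
    Hot1_S153       = list("SPIKE",     "NaCl", "PHASE_SHIFT_BY_T2", 5, 10, 2.5),
    Ste12_S400      = list("GRADUAL",   "Phe",  "NONE",        5, 14, 2.5),
    Dig2_T225       = list("GRADUAL",   "Phe",  "SCALE_BY_T2", 5,  8, 1.8),
    Far1_S114       = list("GRADUAL",   "Phe",  "NONE",        5, 16, 2.5),
    Ypk1_S644_S653  = list("SUSTAINED", "Phe",  "SCALE_BY_T2", 5, 10, 2.5),
    Bit61_S139_S144 = list("SPIKE",     "Phe",  "SCALE_BY_T2", 3, 10, 2.0),
    Nbp2_S196       = list("GRADUAL",   "Phe",  "DIP_AT",      5, 10, 2.5),
    Ssk2_S53_S57    = list("SPIKE",     "NaCl", "NONE",        5, 10, 2.5),
    Sko1_S126       = list("GRADUAL",   "NaCl", "NONE",        5, 12, 2.5),
    Rck2_S519      = list("SUSTAINED", "NaCl", "SCALE_BY_T2", 5, 10, 2.2),
    Msn4_S316       = list("GRADUAL",   "NaCl", "NONE",        5,  8, 2.5))
  stopifnot(setequal(names(dyn), core$ppep_id))
  dd <- dyn[core$ppep_id]
  i <- seq_len(nrow(core)) - 1L
  base_shape <- vapply(dd, `[[`, character(1), 1)
  driving <- vapply(dd, `[[`, character(1), 2)
  modifier <- vapply(dd, `[[`, character(1), 3)
  lab_mod <- c(NONE = "NONE", SCALE_BY_T2 = "INTENSITY",
               DIP_AT = "INTENSITY", PHASE_SHIFT_BY_T2 = "SHAPE")[modifier]
  lab_drv <- rep("INTENSITY", length(modifier))
  lab_drv[modifier == "PHASE_SHIFT_BY_T2"] <- "SHAPE"
  core_rows <- data.frame(
    ppep_id = core$ppep_id, protein = core$protein, sites = core$sites,
    base_shape = base_shape, driving = driving, modifier = modifier,
    amplitude = 10^(5 + (i %% 7) / 3),
    label_nacl = unname(ifelse(driving == "NaCl", lab_drv, lab_mod)),
    label_phe = unname(ifelse(driving == "NaCl", lab_mod, lab_drv)),
    cv = NA_real_, missing_rate = NA_real_, drop_conditions = "",
    known_function = TRUE, stringsAsFactors = FALSE)
  core_rows$peak <- vapply(dd, `[[`, numeric(1), 4)
  core_rows$half <- vapply(dd, `[[`, numeric(1), 5)
  core_rows$scale_max <- vapply(dd, `[[`, numeric(1), 6)
  core_rows$shift_step <- 6

  ## redundant duplicates: copy the dynamics of a known peptide of the
  ## same protein, slightly rescaled; affinity propagation merges them
  dup_of <- c("Ste20_T511", "Pbs2_S248", "Ssk1_S110", "Dig1_S272",
              "Fus3_T180_Y182", "Gpd1_S24_S27")
  dup_sites <- c("S169", "S302", "S351", "T382", "S262", "S72")
  dups <- core_rows[match(dup_of, core_rows$ppep_id), ]
  dups$sites <- dup_sites
  dups$ppep_id <- paste0(dups$protein, "_", dup_sites)
  dups$amplitude <- dups$amplitude * 1.02
  dups$known_function <- FALSE

  ## high replicate variability: removed by the CV < 0.25 filter
  hicv <- data.frame(
    ppep_id = c("Ste20_S870", "Pbs2_T610", "Ste11_S610", "Ssk2_S880",
                "Ste12_S650"),
    protein = c("Ste20", "Pbs2", "Ste11", "Ssk2", "Ste12"),
    sites = c("S870", "T610", "S610", "S880", "S650"),
    base_shape = "SPIKE", driving = "NaCl", modifier = "NONE",
    amplitude = 2e5, label_nacl = "INTENSITY", label_phe = "NONE",
    cv = 0.6, missing_rate = NA_real_, drop_conditions = "",
    known_function = FALSE, stringsAsFactors = FALSE)
  hicv$peak <- 5; hicv$half <- 10; hicv$scale_max <- 2.5; hicv$shift_step <- 6

  ## structural missingness: 6 of the 16 training conditions undetected
  gone <- paste(condition_name(c(1, 5, 10, 20, 45, 5),
                               c(0, 0, 0, 0, 0, 5)), collapse = ";")
  himiss <- data.frame(
    ppep_id = c("Hot1_S360", "Far1_S87", "Sko1_T215", "Rck2_S45"),
    protein = c("Hot1", "Far1", "Sko1", "Rck2"),
    sites = c("S360", "S87", "T215", "S45"),
    base_shape = "GRADUAL", driving = "Phe", modifier = "NONE",
    amplitude = 3e5, label_nacl = "NONE", label_phe = "INTENSITY",
    cv = NA_real_, missing_rate = NA_real_, drop_conditions = gone,
    known_function = FALSE, stringsAsFactors = FALSE)
  himiss$peak <- 5; himiss$half <- 10; himiss$scale_max <- 2.5
  himiss$shift_step <- 6

  archetype_panel(rbind(core_rows, dups, hicv, himiss))
}

## the 33 modelling phosphopeptides (matches the shipped modeling_ppeps
## fixture: 7 Ste20, 2 Hog1, 3 Pbs2, 2 Ssk1, 2 Dig1 and 17 singletons)
modeling_ppep_table <- function() {
  path <- system.file("extdata", "modeling_ppeps.csv", package = "costim")
  if (nzchar(path)) return(utils::read.csv(path, stringsAsFactors = FALSE))
  stopf("modeling_ppeps fixture not found")
}
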