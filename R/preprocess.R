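## Preprocessing: replicate-level intensities -> condensed, normalised
## per-peptide 6 x 6 mean surfaces.

#' Total-ion-current normalisation
#'
#' Divides every intensity by the total ion current (TIC) of its MS run
#' (one run = one condition x replicate) and rescales by the mean TIC over
#' all runs, so the overall intensity scale is preserved.  Within-run
#' ratios and rank order are unchanged.
#'
#' @param dataset A `costim_data` object with positive per-run `tic`.
#' @return The normalised dataset (TIC column reset to the new run sums).
#' @export
tic_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "costim_data"))
  tics <- tapply(dataset$tic, dataset$run_id, function(x) x[1])
  if (any(is.na(tics) | tics <= 0))
    stopf("run '%s' has missing or non-positive TIC",
          names(tics)[is.na(tics) | tics <= 0][1])
  scale <- mean(tics)
  dataset$intensity <- dataset$intensity / as.numeric(tics[dataset$run_id]) * scale
  newtic <- tapply(dataset$intensity, dataset$run_id, sum, na.rm = TRUE)
  dataset$tic <- as.numeric(newtic[dataset$run_id])
  dataset
}

#' Merge redundant MS1 features
#'
#' Features with identical peptide sequence and phosphate count are merged
#' by summing their intensities per (condition, replicate) -- the same
#' peptide observed at different charge states, retention times or
#' mass-to-charge ratios, and site permutations that MS2 spectra cannot
#' resolve.  When merged features carry different site calls the merged
#' peptide is flagged ambiguous and its sites are reported in brackets.
#'
#' @param feature_table Data frame with columns `protein`, `sites`,
#'   `sequence`, `n_phospho`, `charge`, `t_nacl`, `t_phe`, `replicate`,
#'   `intensity`.
#' @param design A [stim_design()].
#' @return A `costim_data` dataset of merged phosphopeptides.
#' @export
merge_features <- function(feature_table, design) {
  need <- c("protein", "sites", "sequence", "n_phospho", "charge",
            "t_nacl", "t_phe", "replicate", "intensity")
  miss <- setdiff(need, names(feature_table))
  if (length(miss)) stopf("feature table lacks columns: %s",
                          paste(miss, collapse = ", "))
  key <- paste(feature_table$sequence, feature_table$n_phospho, sep = "|")
  groups <- split(feature_table, key)
  rows <- lapply(groups, function(g) {
    prot <- unique(g$protein)
    if (length(prot) > 1)
      stopf("conflicting protein assignment within merge group %s/%d: %s",
            g$sequence[1], g$n_phospho[1], paste(prot, collapse = ", "))
    site_calls <- unique(g$sites)
    ambiguous <- length(site_calls) > 1
    sites <- if (ambiguous)
      paste0("(", paste(sort(site_calls), collapse = "|"), ")")
    else site_calls
    agg <- stats::aggregate(intensity ~ t_nacl + t_phe + replicate, data = g,
                            FUN = sum, na.action = stats::na.pass)
    data.frame(ppep_id = paste(prot, sites, sep = "_"), protein = prot,
               sites = sites, sequence = g$sequence[1],
               n_phospho = g$n_phospho[1],
               t_nacl = agg$t_nacl, t_phe = agg$t_phe,
               replicate = agg$replicate, intensity = agg$intensity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$run_id <- sprintf("%s_r%d", condition_name(out$t_nacl, out$t_phe),
                        out$replicate)
  tic <- tapply(out$intensity, out$run_id, sum, na.rm = TRUE)
  out$tic <- as.numeric(tic[out$run_id])
  as_costim_data(out[, LONG_CSV_COLS], design)
}

#' Detection filter
#'
#' Retains a phosphopeptide only if it was detected (in at least one
#' replicate of any condition sharing the coordinate) at a minimum number
#' of NaCl stimulation periods AND of pheromone stimulation periods --
#' at least four of the six time points on each axis by default.
#'
#' @param dataset A `costim_data` object.
#' @param min_times Minimum detected time points per axis.
#' @return Character vector of retained `ppep_id`s.
#' @export
detection_filter <- function(dataset, min_times = 4) {
  stopifnot(inherits(dataset, "costim_data"))
  obs <- dataset[!is.na(dataset$intensity), ]
  n_nacl <- tapply(obs$t_nacl, obs$ppep_id, function(x) length(unique(x)))
  n_phe <- tapply(obs$t_phe, obs$ppep_id, function(x) length(unique(x)))
  keep <- names(n_nacl)[n_nacl >= min_times &
                          n_phe[names(n_nacl)] >= min_times]
  ppeps <- unique(dataset$ppep_id)
  ppeps[ppeps %in% keep]
}

#' Average biological replicates into a mean surface
#'
#' Condenses replicate-level data into, per peptide, the stimulation-
#' matrix grid of mean intensity, standard deviation and number of
#' detected replicates.  Cells with no detected replicate are MISSING;
#' cells with a single replicate get s.d. 0 (flagged by `n = 1`) so a
#' downstream coefficient of variation stays computable.
#'
#' @param dataset A `costim_data` object.
#' @return Object of class `mean_surface`: matrices `mean`, `sd`, `n`
#'   (peptides x conditions, columns named `t<NaCl>_p<Phe>`), a character
#'   `provenance` matrix (`"OBSERVED"`, `"IMPUTED"` or `"MISSING"`), the
#'   design, and a `ppep_info` table.
#' @export
average_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "costim_data"))
  design <- attr(dataset, "design")
  conds <- design$conditions
  cn <- condition_name(conds$t_nacl, conds$t_phe)
  ppeps <- unique(dataset$ppep_id)
  mk <- function(fill) matrix(fill, length(ppeps), nrow(conds),
                              dimnames = list(ppeps, cn))
  mean_m <- mk(NA_real_); sd_m <- mk(NA_real_); n_m <- mk(0L)
  col <- match(condition_name(dataset$t_nacl, dataset$t_phe), cn)
  row <- match(dataset$ppep_id, ppeps)
  obs <- !is.na(dataset$intensity)
  for (cell in split(which(obs), paste(row[obs], col[obs]))) {
    v <- dataset$intensity[cell]
    r <- row[cell[1]]; cc <- col[cell[1]]
    mean_m[r, cc] <- mean(v)
    sd_m[r, cc] <- if (length(v) > 1) stats::sd(v) else 0
    n_m[r, cc] <- length(v)
  }
  prov <- mk("MISSING")
  prov[n_m > 0] <- "OBSERVED"
  info <- unique(dataset[, c("ppep_id", "protein", "sites", "sequence",
                             "n_phospho")])
  info <- info[match(ppeps, info$ppep_id), ]
  rownames(info) <- NULL
  structure(list(mean = mean_m, sd = sd_m, n = n_m, provenance = prov,
                 design = design, ppep_info = info),
            class = "mean_surface")
}

#' @export
print.mean_surface <- function(x, ...) {
  cat(sprintf("mean_surface: %d phosphopeptides x %d conditions (%d imputed, %d missing cells)\n",
              nrow(x$mean), ncol(x$mean), sum(x$provenance == "IMPUTED"),
              sum(x$provenance == "MISSING")))
  invisible(x)
}

#' Plot the dynamic profiles of one phosphopeptide
#'
#' Draws the 2-D chart family for one peptide: its time curves along one
#' stimulus axis, one curve per duration of the other stimulus.
#'
#' @param x A `mean_surface`.
#' @param ppep Peptide id (row name).
#' @param axis `"NaCl"` or `"Phe"`: the stimulus on the x axis.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mean_surface <- function(x, ppep = rownames(x$mean)[1],
                              axis = c("NaCl", "Phe"), ...) {
  axis <- match.arg(axis)
  cur <- extract_curves(x, axis = axis)
  m <- t(cur$curves[cur$ids$ppep_id == ppep, , drop = FALSE])
  tt <- if (axis == "NaCl") x$design$nacl_times else x$design$phe_times
  other <- if (axis == "NaCl") "pheromone" else "NaCl"
  graphics::matplot(tt, m, type = "b", pch = 16, lty = 1,
                    xlab = sprintf("%s stimulation period (min)", axis),
                    ylab = "mean intensity",
                    main = sprintf("%s (one curve per %s period)", ppep, other),
                    ...)
  invisible(x)
}

#' Cubic-spline imputation of missing surface cells
#'
#' Missing cells are estimated by natural cubic spline interpolation along
#' the NaCl axis within the fixed pheromone duration; if fewer than three
#' observed points lie on that track, the pheromone-axis track is used
#' instead.  Cells on tracks with fewer than three observed points on both
#' axes stay MISSING with a warning.  Imputed cells are flagged; observed
#' cells are never altered; negative spline output is clipped to 0.
#'
#' @param surface A `mean_surface`.
#' @return The surface with `provenance` updated to `"IMPUTED"` where
#'   filled.
#' @export
impute_spline <- function(surface) {
  stopifnot(inherits(surface, "mean_surface"))
  design <- surface$design
  tn <- design$nacl_times; tp <- design$phe_times
  cn <- colnames(surface$mean)
  grid_col <- function(i_nacl, j_phe)
    match(condition_name(tn[i_nacl], tp[j_phe]), cn)
  fill <- function(times, values, at) {
    obs <- !is.na(values)
    if (sum(obs) < 3) return(NA_real_)
    pmax(0, stats::spline(times[obs], values[obs], xout = at,
                          method = "natural")$y)
  }
  for (p in rownames(surface$mean)) {
    grid <- matrix(surface$mean[p, grid_col(rep(seq_along(tn), length(tp)),
                                            rep(seq_along(tp), each = length(tn)))],
                   nrow = length(tn))
    filled <- grid
    for (j in seq_along(tp)) {
      missing_i <- which(is.na(grid[, j]))
      for (i in missing_i) {
        v <- fill(tn, grid[, j], tn[i])            # NaCl-axis track
        if (is.na(v)) v <- fill(tp, grid[i, ], tp[j])  # pheromone fallback
        if (is.na(v)) {
          warnf("%s: cell %s not imputable (fewer than 3 observed points on both tracks)",
                p, condition_name(tn[i], tp[j]))
        } else {
          filled[i, j] <- v
          surface$provenance[p, grid_col(i, j)] <- "IMPUTED"
        }
      }
    }
    surface$mean[p, ] <- as.vector(filled)[match(cn, condition_name(
      rep(tn, length(tp)), rep(tp, each = length(tn))))]
  }
  surface
}

#' Compare a stimulation time course against its mock experiment
#'
#' Cell-wise ratio test for handling artefacts: a peptide's difference
#' between the real and the mock time course is negligible only if every
#' compared cell's larger/smaller ratio is strictly below the threshold
#' (default 1.5).
#'
#' @param real,mock Numeric matrices (peptides x compared conditions) with
#'   identical dimnames, or `mean_surface` objects restricted elsewhere.
#' @param threshold Strict ratio threshold.
#' @param eps Pseudocount for zero denominators; default 1% of the global
#'   median of the compared values.
#' @return List with `negligible` (named logical per peptide), `fraction`
#'   of negligible peptides, and the per-cell ratio matrix.
#' @export
mock_compare <- function(real, mock, threshold = 1.5, eps = NULL) {
  if (inherits(real, "mean_surface")) real <- real$mean
  if (inherits(mock, "mean_surface")) mock <- mock$mean
  stopifnot(identical(dim(real), dim(mock)),
            identical(rownames(real), rownames(mock)))
  if (is.null(eps)) eps <- 0.01 * stats::median(c(real, mock), na.rm = TRUE)
  hi <- pmax(real, mock) + eps
  lo <- pmin(real, mock) + eps
  ratio <- hi / lo
  neg <- apply(ratio, 1, function(r) all(r[!is.na(r)] < threshold))
  list(negligible = neg, fraction = mean(neg), ratio = ratio)
}
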