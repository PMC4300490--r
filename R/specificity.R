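## Stimulus-specificity ratio statistics.
##
## The specificity of a phosphopeptide for Stimulus_1 with respect to a
## modulating Stimulus_2 is the ratio between its response to Stimulus_1
## alone and its response to the combination: an entry below 1 means
## Stimulus_2 amplifies the Stimulus_1 response, above 1 that it inhibits
## it.  S_NaCl (modulating stimulus NaCl) quantifies the effect of NaCl on
## the pheromone-induced response; S_Phe the effect of pheromone on the
## NaCl-induced response.

#' Specificity matrix of one phosphopeptide
#'
#' `entry(i, j) = (I(i, 0) + eps) / (I(i, j) + eps)` where `I(i, j)` is
#' the mean intensity at Stimulus_1 period i and Stimulus_2 duration j.
#' Column j = 0 is identically 1.
#'
#' @param surface A fully imputed `mean_surface`.
#' @param ppep Peptide id.
#' @param modulating `"NaCl"` or `"Phe"` (Stimulus_2).
#' @param eps Pseudocount; default 1% of the global median intensity.
#'   With all intensities positive `eps = 0` is valid; otherwise an error
#'   advises a positive pseudocount.
#' @return A `specificity_matrix`: 6 x 6 matrix of positive ratios, rows
#'   = Stimulus_1 periods, columns = Stimulus_2 durations.
#' @export
specificity_matrix <- function(surface, ppep,
                               modulating = c("NaCl", "Phe"), eps = NULL) {
  stopifnot(inherits(surface, "mean_surface"))
  modulating <- match.arg(modulating)
  if (!ppep %in% rownames(surface$mean)) stopf("unknown peptide '%s'", ppep)
  if (is.null(eps)) eps <- 0.01 * stats::median(surface$mean, na.rm = TRUE)
  design <- surface$design
  tn <- design$nacl_times; tp <- design$phe_times
  if (modulating == "Phe") { t1 <- tn; t2 <- tp } else { t1 <- tp; t2 <- tn }
  I <- matrix(NA_real_, length(t1), length(t2),
              dimnames = list(paste0("s1_", t1), paste0("s2_", t2)))
  for (i in seq_along(t1)) for (j in seq_along(t2)) {
    I[i, j] <- if (modulating == "Phe")
      surface$mean[ppep, condition_name(t1[i], t2[j])]
    else surface$mean[ppep, condition_name(t2[j], t1[i])]
  }
  if (eps == 0 && any(I <= 0))
    stopf("non-positive intensities with eps = 0; supply a positive pseudocount")
  s <- (I[, 1] + eps) / (I + eps)
  structure(s, ppep = ppep, modulating = modulating,
            class = c("specificity_matrix", class(s)))
}

#' Collapse a specificity matrix to a vector
#'
#' Column-wise arithmetic mean of the specificity matrix: one entry per
#' Stimulus_2 duration, equal to 1 at duration 0.
#'
#' @param mat A `specificity_matrix`.
#' @return Named numeric vector of length `ncol(mat)`.
#' @export
specificity_vector <- function(mat) {
  stopifnot(inherits(mat, "specificity_matrix"))
  colMeans(mat)
}

#' Specificity vectors for all peptides of a surface
#'
#' @inheritParams specificity_matrix
#' @return Matrix (peptides x Stimulus_2 durations) of specificity-vector
#'   entries.
#' @export
specificity_vectors <- function(surface, modulating = c("NaCl", "Phe"),
                                eps = NULL) {
  modulating <- match.arg(modulating)
  t(vapply(rownames(surface$mean), function(p)
    specificity_vector(specificity_matrix(surface, p, modulating, eps)),
    numeric(if (modulating == "Phe") length(surface$design$phe_times)
            else length(surface$design$nacl_times))))
}

#' Pattern-match screen over specificity vectors
#'
#' Automated version of the search for components that directly or
#' inversely follow a reference peptide's cross-stimulation pattern (the
#' screen used to find peptides coupled to doubly phosphorylated Hog1):
#' candidates are ranked by the Pearson correlation of log-transformed
#' specificity vectors within an early-time window, so amplification and
#' inhibition are treated symmetrically.
#'
#' @param query Specificity vector of the reference peptide.
#' @param candidates Matrix of candidate specificity vectors (one row per
#'   peptide), e.g. from [specificity_vectors()].
#' @param mode `"SIMILAR"` keeps correlations `>= r_min`, `"OPPOSITE"`
#'   keeps `<= -r_min`.
#' @param window Number of leading Stimulus_2 durations compared
#'   (default 4: durations 0, 1, 5, 10 min).
#' @param r_min Absolute correlation cutoff.
#' @return Data frame `ppep_id`, `r`, ranked by `|r|`; zero-variance
#'   candidates are skipped with a warning.
#' @export
pattern_match <- function(query, candidates, mode = c("SIMILAR", "OPPOSITE"),
                          window = 4, r_min = 0.8) {
  mode <- match.arg(mode)
  w <- seq_len(min(window, length(query)))
  lq <- log(query[w])
  if (stats::sd(lq) == 0)
    stopf("query has zero variance within the window")
  rs <- vapply(rownames(candidates), function(p) {
    lc <- log(candidates[p, w])
    if (stats::sd(lc) == 0) {
      warnf("candidate '%s' has zero variance within the window; skipped", p)
      return(NA_real_)
    }
    stats::cor(lq, lc)
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  keep <- if (mode == "SIMILAR") rs >= r_min else rs <= -r_min
  out <- data.frame(ppep_id = names(rs)[keep], r = unname(rs[keep]),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}
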