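## Shape / Intensity / No Effect classification and profile clustering.

#' Extract per-peptide time curves from a surface
#'
#' For each phosphopeptide, one curve per duration of the fixed (other)
#' stimulus: `axis = "NaCl"` gives curves over the NaCl stimulation
#' periods, one per pheromone duration, and vice versa.
#'
#' @param surface A fully imputed `mean_surface`.
#' @param axis `"NaCl"` or `"Phe"`: the stimulus whose time is the x axis.
#' @return List with `curves` (matrix, one row per curve) and `ids`
#'   (data frame `ppep_id`, `fixed_other`).
#' @export
extract_curves <- function(surface, axis = c("NaCl", "Phe")) {
  stopifnot(inherits(surface, "mean_surface"))
  axis <- match.arg(axis)
  if (any(is.na(surface$mean)))
    stopf("surface has residual MISSING cells; impute first")
  design <- surface$design
  tn <- design$nacl_times; tp <- design$phe_times
  ppeps <- rownames(surface$mean)
  if (axis == "NaCl") {
    fixed <- tp
    cols <- lapply(tp, function(b) condition_name(tn, b))
  } else {
    fixed <- tn
    cols <- lapply(tn, function(a) condition_name(a, tp))
  }
  curves <- do.call(rbind, lapply(seq_along(fixed), function(j)
    surface$mean[, cols[[j]], drop = FALSE]))
  ids <- data.frame(ppep_id = rep(ppeps, length(fixed)),
                    fixed_other = rep(fixed, each = length(ppeps)),
                    stringsAsFactors = FALSE)
  ord <- order(match(ids$ppep_id, ppeps), ids$fixed_other)
  list(curves = unname(curves[ord, , drop = FALSE]), ids = ids[ord, ],
       axis = axis, times = if (axis == "NaCl") tn else tp)
}

#' K-means clustering of time curves
#'
#' Euclidean K-means over all curves of one axis, best of `restarts`
#' seeded runs by within-cluster sum of squares.  Curves are divided by
#' their own mean by default so clustering captures shape, not level.
#'
#' @param curves Numeric matrix, one curve per row.
#' @param k Number of clusters (6 for NaCl-axis curves, 8 for
#'   pheromone-axis curves in the default analysis).
#' @param seed Integer seed.
#' @param restarts Number of random restarts.
#' @param scale `"mean"` (divide each curve by its mean) or `"raw"`.
#' @return Integer cluster label per curve.
#' @export
kmeans_curves <- function(curves, k, seed = 1, restarts = 50,
                          scale = c("mean", "raw")) {
  scale <- match.arg(scale)
  if (k > nrow(curves))
    stopf("k = %d exceeds the number of curves (%d)", k, nrow(curves))
  x <- curves
  if (scale == "mean") {
    m <- rowMeans(x)
    if (any(m == 0)) stopf("curve with zero mean cannot be rescaled")
    x <- x / m
  }
  n_unique <- nrow(unique(round(x, 10)))
  if (n_unique < k) {
    warnf("only %d distinct curves; reducing k from %d", n_unique, k)
    k <- n_unique
  }
  with_seed(seed,
    stats::kmeans(x, centers = k, nstart = restarts, iter.max = 200)$cluster)
}

#' Classify Shape and Intensity effects
#'
#' For each phosphopeptide and each modulating stimulus, decides whether
#' co-stimulation changes the shape of its response curves to the other
#' stimulus (Shape Effect), only their overall level (Intensity Effect),
#' or neither.  The peptide's six curves along the other stimulus' axis
#' (one per modulating-stimulus duration) are clustered together with all
#' other peptides' curves (K = 6 for NaCl-axis curves when pheromone
#' modulates, K = 8 for pheromone-axis curves when NaCl modulates); a
#' peptide whose curves fall into three or more clusters is a Shape
#' Effect.  Otherwise its intensity score is
#' `(max(v) - min(v)) / mean(v)` where `v` holds the six per-curve mean
#' intensities indexed by the modulating-stimulus duration; a score of at
#' least 0.7 is an Intensity Effect, else No Effect.
#'
#' A configurable alternative (`score_mode = "axis_range"`) averages the
#' near-identical curves pointwise along the axis first and scores the
#' range of that average curve.
#'
#' @param surface A fully imputed `mean_surface`.
#' @param k_nacl,k_phe Cluster counts for NaCl-axis and pheromone-axis
#'   curves.
#' @param threshold Intensity-score threshold (inclusive).
#' @param seed Integer seed for the K-means runs.
#' @param restarts K-means restarts.
#' @param scale Curve rescaling before clustering (see
#'   [kmeans_curves()]).
#' @param score_mode `"curve_means"` (default) or `"axis_range"`.
#' @return Data frame of class `effect_calls`: `ppep_id`, `stimulus`
#'   (the modulating stimulus), `call`, `n_distinct_clusters`,
#'   `intensity_score`.
#' @export
classify_effects <- function(surface, k_nacl = 6, k_phe = 8,
                             threshold = 0.7, seed = 1, restarts = 50,
                             scale = c("mean", "raw"),
                             score_mode = c("curve_means", "axis_range")) {
  scale <- match.arg(scale)
  score_mode <- match.arg(score_mode)
  one_side <- function(axis, k, modulating, seed) {
    cur <- extract_curves(surface, axis = axis)
    labs <- kmeans_curves(cur$curves, k = k, seed = seed,
                          restarts = restarts, scale = scale)
    res <- lapply(split(seq_len(nrow(cur$ids)), cur$ids$ppep_id), function(ix) {
      cc <- cur$curves[ix, , drop = FALSE]
      ll <- labs[ix]
      ## numerically identical curves count as one label
      uniq <- !duplicated(round(cc, 10))
      nd <- length(unique(ll[uniq]))
      if (nd >= 3) return(data.frame(call = "SHAPE", n = nd, score = NA_real_))
      v <- if (score_mode == "curve_means") rowMeans(cc) else colMeans(cc)
      score <- (max(v) - min(v)) / mean(v)
      data.frame(call = if (score >= threshold) "INTENSITY" else "NONE",
                 n = nd, score = score)
    })
    out <- do.call(rbind, res)
    data.frame(ppep_id = names(res), stimulus = modulating,
               call = out$call, n_distinct_clusters = out$n,
               intensity_score = out$score, stringsAsFactors = FALSE)
  }
  ## pheromone modulates the NaCl-axis curves and vice versa
  out <- rbind(one_side("NaCl", k_nacl, "Phe", stage_seed(seed, "phe")),
               one_side("Phe", k_phe, "NaCl", stage_seed(seed, "nacl")))
  rownames(out) <- NULL
  class(out) <- c("effect_calls", "data.frame")
  out
}

#' Hierarchical clustering of full co-stimulation profiles
#'
#' Groups phosphopeptides by their complete 36-condition intensity
#' vectors using the Minkowski distance and complete linkage, cut into
#' `k` groups (the default analysis highlights seven main clusters).
#'
#' @param surface A fully imputed `mean_surface`.
#' @param p Minkowski order (2 = Euclidean).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param k Number of groups.
#' @param scale `"mean"` or `"raw"` profile rescaling.
#' @return Named integer vector of cluster assignments.
#' @export
hier_cluster <- function(surface, p = 2, linkage = "complete", k = 7,
                         scale = c("mean", "raw")) {
  stopifnot(inherits(surface, "mean_surface"))
  scale <- match.arg(scale)
  x <- surface$mean
  if (any(is.na(x))) stopf("surface has MISSING cells; impute first")
  if (k > nrow(x)) stopf("k = %d exceeds the number of peptides (%d)", k, nrow(x))
  if (scale == "mean") x <- x / rowMeans(x)
  d <- stats::dist(x, method = "minkowski", p = p)
  stats::cutree(stats::hclust(d, method = linkage), k = k)
}
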