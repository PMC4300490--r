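## Modelling filters: replicate consistency, missingness, and affinity-
## propagation merging of redundant trajectories.

#' Coefficient-of-variation filter
#'
#' Per phosphopeptide, the replicate CV (s.d. / mean) is computed for
#' every condition with at least two detected replicates and aggregated
#' by the median (configurable); peptides with aggregated CV strictly
#' below the threshold are retained.
#'
#' @param dataset A `costim_data` object.
#' @param threshold Strict CV threshold (default 0.25).
#' @param conditions Optional data frame `t_nacl`, `t_phe` restricting the
#'   conditions used (e.g. the modelling training conditions).
#' @param agg `"median"` or `"mean"` aggregation across conditions.
#' @return Character vector of retained `ppep_id`s.  Peptides with no
#'   condition of two or more replicates are excluded with a warning.
#' @export
cv_filter <- function(dataset, threshold = 0.25, conditions = NULL,
                      agg = c("median", "mean")) {
  stopifnot(inherits(dataset, "costim_data"))
  agg <- match.arg(agg)
  df <- as.data.frame(dataset)
  if (!is.null(conditions)) {
    keep <- paste(df$t_nacl, df$t_phe) %in%
      paste(conditions$t_nacl, conditions$t_phe)
    df <- df[keep, ]
  }
  df <- df[!is.na(df$intensity), ]
  afun <- if (agg == "median") stats::median else mean
  out <- vapply(split(df, df$ppep_id), function(g) {
    cvs <- vapply(split(g$intensity, paste(g$t_nacl, g$t_phe)), function(v) {
      if (length(v) < 2) return(NA_real_)
      stats::sd(v) / mean(v)
    }, numeric(1))
    cvs <- cvs[!is.na(cvs)]
    if (!length(cvs)) return(NA_real_)
    afun(cvs)
  }, numeric(1))
  none <- names(out)[is.na(out)]
  if (length(none))
    warnf("no condition with >= 2 replicates for: %s; excluded",
          paste(none, collapse = ", "))
  names(out)[!is.na(out) & out < threshold]
}

#' Missingness filter
#'
#' Retains a phosphopeptide only if strictly fewer than `max_fraction` of
#' its (un-imputed) surface cells are missing within the given
#' conditions -- peptides with 25% or more missing data points are
#' discarded by default.
#'
#' @param surface An un-imputed `mean_surface`.
#' @param max_fraction Missing-fraction cutoff (missing fraction `>=`
#'   this value discards).
#' @param conditions Optional data frame `t_nacl`, `t_phe`; default all
#'   conditions of the design.
#' @return Character vector of retained `ppep_id`s.
#' @export
missingness_filter <- function(surface, max_fraction = 0.25,
                               conditions = NULL) {
  stopifnot(inherits(surface, "mean_surface"))
  cols <- colnames(surface$mean)
  if (!is.null(conditions))
    cols <- condition_name(conditions$t_nacl, conditions$t_phe)
  frac <- rowMeans(surface$provenance[, cols, drop = FALSE] != "OBSERVED")
  rownames(surface$mean)[frac < max_fraction]
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by message passing (responsibilities and
#' availabilities) on a similarity matrix.  Written for the small
#' per-protein trajectory groups this package clusters.
#'
#' @param S Square similarity matrix (larger = more similar), e.g.
#'   negative squared Euclidean distances.
#' @param preference Diagonal self-similarity; default the median of the
#'   off-diagonal similarities.
#' @param damping Damping factor in (0.5, 1).
#' @param maxit Maximum iterations.
#' @param conv_its Stop after this many iterations without exemplar
#'   changes.
#' @return List with `exemplars` (indices), `assignment` (exemplar index
#'   per point) and `converged`.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 maxit = 1000, conv_its = 50) {
  n <- nrow(S)
  if (n == 1)
    return(list(exemplars = 1L, assignment = 1L, converged = TRUE))
  if (damping <= 0.5 || damping >= 1) stopf("damping must be in (0.5, 1)")
  off <- S[row(S) != col(S)]
  if (is.null(preference)) preference <- stats::median(off)
  diag(S) <- preference
  ## tiny deterministic jitter removes degenerate ties
  S <- S + (1e-12 * max(abs(S))) * outer(seq_len(n), seq_len(n), function(i, j)
    sin(i * 7 + j * 13))
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last <- integer(0); stable <- 0L; converged <- FALSE
  for (it in seq_len(maxit)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(rep(colsum, each = n), n, n) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0); diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    curex <- which(diag(A + R) > 0)
    if (length(curex) == length(last) && all(curex == last))
      stable <- stable + 1L else stable <- 0L
    last <- curex
    if (stable >= conv_its && length(curex)) { converged <- TRUE; break }
  }
  ex <- which(diag(A + R) > 0)
  if (!length(ex)) ex <- which.max(diag(A + R))
  assignment <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assignment[ex] <- ex
  list(exemplars = as.integer(ex), assignment = as.integer(assignment),
       converged = converged)
}

#' Merge redundant same-protein trajectories
#'
#' Phosphopeptides of the same protein with near-identical trajectories
#' are indistinguishable for modelling; affinity propagation (similarity
#' = negative squared Euclidean distance between mean-centred
#' log-trajectories) groups them, and one representative is kept per
#' cluster: the member with previously known function if present (ties
#' broken by lexicographic peptide id), otherwise the cluster exemplar.
#'
#' @param trajectories Matrix (peptides x conditions) of mean intensities.
#' @param protein Named or positional character vector of protein
#'   assignments, one per row.
#' @param known_function Logical vector: peptide has previously known
#'   function.
#' @param damping Affinity-propagation damping factor.
#' @param preference Affinity-propagation preference (self-similarity).
#'   The default -1 is an absolute redundancy scale: on mean-centred
#'   log-trajectories, two peptides merge only when their trajectories
#'   differ by less than about one natural-log unit in aggregate
#'   (duplicated dynamics land one to two orders of magnitude below
#'   this, genuinely distinct site dynamics well above it).  `NULL`
#'   falls back to the classic median-pairwise-similarity rule, which
#'   merges nearest neighbours even among clearly distinct
#'   trajectories.
#' @return Data frame `ppep_id`, `protein`, `cluster`, `representative`.
#' @export
ap_merge <- function(trajectories, protein, known_function,
                     damping = 0.9, preference = -1) {
  stopifnot(nrow(trajectories) == length(protein),
            length(protein) == length(known_function))
  ids <- rownames(trajectories)
  out <- lapply(split(seq_along(protein), protein), function(ix) {
    sub <- trajectories[ix, , drop = FALSE]
    if (length(ix) == 1) {
      return(data.frame(ppep_id = ids[ix], protein = protein[ix],
                        cluster = paste0(protein[ix], ".1"),
                        representative = TRUE, stringsAsFactors = FALSE))
    }
    x <- log(sub)
    x <- x - rowMeans(x)
    S <- -as.matrix(stats::dist(x))^2
    ap <- affinity_propagation(S, preference = preference, damping = damping)
    if (!ap$converged) {
      warnf("affinity propagation did not converge for %s; keeping singletons",
            protein[ix][1])
      ap <- list(assignment = seq_along(ix), exemplars = seq_along(ix))
    }
    cl <- ap$assignment
    rep_flag <- logical(length(ix))
    for (e in unique(cl)) {
      members <- which(cl == e)
      known <- members[known_function[ix][members]]
      pick <- if (length(known)) known[order(ids[ix][known])][1] else e
      rep_flag[pick] <- TRUE
    }
    data.frame(ppep_id = ids[ix], protein = protein[ix],
               cluster = paste0(protein[ix], ".", match(cl, unique(cl))),
               representative = rep_flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
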