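## MIDAS perturbation-data format (comma separated).
##
## Dialect: treatment columns "TR:NaCl" and "TR:Phe" in {0,1}; per
## measured node one "DA:<node>" time column (minutes) and one
## "DV:<node>" value column with values in \[0,1\] or NA; one row per
## (condition, time point).  The cell-line column is omitted (single
## strain).

#' Read a MIDAS file
#'
#' @param path File path.
#' @return List with `treatments` (data frame `tr_nacl`, `tr_phe`),
#'   `measurements` (long data frame `tr_nacl`, `tr_phe`, `time`, `node`,
#'   `value`) and `nodes`.
#' @export
read_midas <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- names(df)
  tr_cols <- grep("^TR:", cn, value = TRUE)
  da_cols <- grep("^DA:", cn, value = TRUE)
  dv_cols <- grep("^DV:", cn, value = TRUE)
  if (!all(c("TR:NaCl", "TR:Phe") %in% tr_cols))
    stopf("MIDAS file must have TR:NaCl and TR:Phe columns")
  dv_nodes <- sub("^DV:", "", dv_cols)
  da_nodes <- sub("^DA:", "", da_cols)
  orphan <- setdiff(dv_nodes, da_nodes)
  if (length(orphan)) stopf("DV:%s has no matching DA:%s column",
                            orphan[1], orphan[1])
  vals <- unlist(df[dv_cols], use.names = FALSE)
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(bad)) stopf("MIDAS values must lie in [0,1] (found %g)",
                      vals[bad][1])
  meas <- do.call(rbind, lapply(dv_nodes, function(nd) {
    data.frame(tr_nacl = df[["TR:NaCl"]], tr_phe = df[["TR:Phe"]],
               time = df[[paste0("DA:", nd)]], node = nd,
               value = df[[paste0("DV:", nd)]], stringsAsFactors = FALSE)
  }))
  rownames(meas) <- NULL
  list(treatments = unique(data.frame(tr_nacl = df[["TR:NaCl"]],
                                      tr_phe = df[["TR:Phe"]])),
       measurements = meas, nodes = dv_nodes)
}

#' Write a MIDAS file
#'
#' @param measurements Long data frame with columns `tr_nacl`, `tr_phe`,
#'   `time`, `node`, `value` (values in \[0,1\] or NA).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_midas <- function(measurements, path) {
  need <- c("tr_nacl", "tr_phe", "time", "node", "value")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stopf("measurements lack columns: %s",
                          paste(miss, collapse = ", "))
  v <- measurements$value
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stopf("MIDAS values must lie in [0,1]")
  nodes <- unique(measurements$node)
  keys <- unique(measurements[, c("tr_nacl", "tr_phe", "time")])
  keys <- keys[order(keys$tr_nacl + keys$tr_phe, keys$tr_nacl, keys$time), ]
  out <- data.frame(`TR:NaCl` = keys$tr_nacl, `TR:Phe` = keys$tr_phe,
                    check.names = FALSE)
  for (nd in nodes) {
    sel <- measurements$node == nd
    m <- match(paste(keys$tr_nacl, keys$tr_phe, keys$time),
               paste(measurements$tr_nacl[sel], measurements$tr_phe[sel],
                     measurements$time[sel]))
    out[[paste0("DA:", nd)]] <- keys$time
    out[[paste0("DV:", nd)]] <- measurements$value[sel][m]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Export a mean surface as training-condition MIDAS data
#'
#' Restricts a (Hill-normalised) mean surface to the common-time-origin
#' training conditions and rewrites each as a (treatment, time)
#' measurement: NaCl-only conditions become `TR:NaCl=1, TR:Phe=0` rows at
#' the NaCl stimulation period, and analogously for pheromone-only and
#' simultaneous co-stimulation; the basal corner is the all-zero
#' treatment at time 0.
#'
#' @param surface A `mean_surface` whose values lie in \[0,1\] (see
#'   [hill_normalize_surface()]).
#' @param path Optional file; when given the MIDAS file is written.
#' @return The long measurement data frame (invisibly when writing).
#' @export
midas_from_surface <- function(surface, path = NULL) {
  stopifnot(inherits(surface, "mean_surface"))
  design <- surface$design
  tc <- select_training_conditions(design)
  rows <- lapply(seq_len(nrow(tc)), function(r) {
    a <- tc$t_nacl[r]; b <- tc$t_phe[r]
    cn <- condition_name(a, b)
    data.frame(tr_nacl = as.numeric(a > 0), tr_phe = as.numeric(b > 0),
               time = max(a, b), node = rownames(surface$mean),
               value = surface$mean[, cn], stringsAsFactors = FALSE)
  })
  meas <- do.call(rbind, rows)
  rownames(meas) <- NULL
  if (!is.null(path)) {
    write_midas(meas, path)
    return(invisible(meas))
  }
  meas
}
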