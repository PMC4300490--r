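## Long-format replicate-level intensity CSV.
##
## Header (exact): ppep_id,protein,sites,sequence,n_phospho,t_nacl,t_phe,
## replicate,run_id,intensity,tic.  Missing intensity is an empty field or
## "NA"; MISSING is a first-class state distinct from 0 (zero intensity is
## invalid input).

LONG_CSV_COLS <- c("ppep_id", "protein", "sites", "sequence", "n_phospho",
                   "t_nacl", "t_phe", "replicate", "run_id", "intensity",
                   "tic")

#' Validate and classify a replicate-level co-stimulation dataset
#'
#' @param df Data frame with the long-format columns (see
#'   [read_costim_csv()]).
#' @param design A [stim_design()]; every record's condition must belong
#'   to it.
#' @return `df` with class `costim_data` and the design attached.
#' @export
as_costim_data <- function(df, design) {
  stopifnot(inherits(design, "stim_design"))
  miss <- setdiff(LONG_CSV_COLS, names(df))
  if (length(miss)) stopf("dataset lacks columns: %s",
                          paste(miss, collapse = ", "))
  extra <- setdiff(names(df), LONG_CSV_COLS)
  if (length(extra)) stopf("unknown columns: %s", paste(extra, collapse = ", "))
  ok_cond <- df$t_nacl %in% design$nacl_times & df$t_phe %in% design$phe_times
  if (!all(ok_cond))
    stopf("record condition (%g, %g) not in the design",
          df$t_nacl[!ok_cond][1], df$t_phe[!ok_cond][1])
  if (any(df$replicate < 1 | df$replicate > design$n_replicates))
    stopf("replicate index outside 1..%d", design$n_replicates)
  bad <- !is.na(df$intensity) & df$intensity <= 0
  if (any(bad))
    stopf("non-missing intensities must be > 0 (found %g for %s)",
          df$intensity[bad][1], df$ppep_id[bad][1])
  key <- paste(df$ppep_id, df$t_nacl, df$t_phe, df$replicate)
  if (anyDuplicated(key))
    stopf("duplicate (ppep, condition, replicate) key: %s",
          key[duplicated(key)][1])
  structure(df, design = design, class = c("costim_data", "data.frame"))
}

#' @export
print.costim_data <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "costim_data: %d phosphopeptides, %d conditions x %d replicates, %d records (%.1f%% missing)\n",
    length(unique(x$ppep_id)), nrow(d$conditions), d$n_replicates,
    nrow(x), 100 * mean(is.na(x$intensity))))
  NextMethod()
}

#' Write / read the long-format intensity CSV
#'
#' Lossless round trip: `write_costim_csv()` then [read_costim_csv()]
#' reproduces every field, including missing observations (written as
#' `NA`, never 0).
#'
#' @param dataset A `costim_data` object.
#' @param path File path.
#' @return `write_costim_csv()` returns `path` invisibly.
#' @export
write_costim_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "costim_data"))
  utils::write.csv(as.data.frame(dataset)[, LONG_CSV_COLS], path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_costim_csv
#' @param design Optional [stim_design()]; inferred from the observed
#'   stimulation periods and replicate indices when omitted.
#' @export
read_costim_csv <- function(path, design = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(n_phospho = "integer",
                                       replicate = "integer"))
  if (!identical(names(df), LONG_CSV_COLS))
    stopf("unexpected header: expected %s", paste(LONG_CSV_COLS, collapse = ","))
  if (is.null(design))
    design <- stim_design(sort(unique(df$t_nacl)), sort(unique(df$t_phe)),
                          max(df$replicate))
  as_costim_data(df, design)
}
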