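## Independent oracles used by the tests; deliberately written with
## different algorithms than the package code they check.

## Boolean evaluation of an acyclic logic network under clamped binary
## inputs: topological propagation with OR over edges/gates, AND within
## gates, negation for inhibitory links.
boolean_eval <- function(network, inputs) {
  vals <- as.list(inputs)
  nodes <- network$nodes$name[network$nodes$role != "STIMULUS"]
  remaining <- nodes
  guard <- 0
  while (length(remaining) && guard < 1000) {
    guard <- guard + 1
    for (nd in remaining) {
      ein <- network$edges[network$edges$target == nd, , drop = FALSE]
      gin <- Filter(function(g) g$target == nd, network$gates)
      srcs <- c(ein$source, unlist(lapply(gin, function(g) g$inputs$source)))
      if (!all(srcs %in% names(vals))) next
      terms <- logical(0)
      if (nrow(ein))
        terms <- mapply(function(s, sg) {
          v <- vals[[s]] == 1
          if (sg > 0) v else !v
        }, ein$source, ein$sign)
      for (g in gin)
        terms <- c(terms, all(mapply(function(s, sg) {
          v <- vals[[s]] == 1
          if (sg > 0) v else !v
        }, g$inputs$source, g$inputs$sign)))
      vals[[nd]] <- if (!length(terms)) 0 else as.numeric(any(terms))
      remaining <- setdiff(remaining, nd)
    }
  }
  unlist(vals[nodes])
}

## brute-force combinatorial edge count for a peptide substitution
brute_force_edge_count <- function(prior, assignment) {
  peps <- split(assignment$ppep_id, assignment$protein)
  total <- 0
  for (i in seq_len(nrow(prior$edges))) {
    e <- prior$edges[i, ]
    ns <- length(peps[[e$source]] %||% e$source)
    nt <- length(peps[[e$target]] %||% e$target)
    total <- total + ns * nt
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## tiny replicate-level dataset built cell by cell
make_toy_dataset <- function(values, design = stim_design(c(0, 1), c(0, 1), 2)) {
  ## values: named list ppep -> function(t_nacl, t_phe, replicate) -> value
  conds <- design$conditions
  rows <- list()
  for (p in names(values)) for (ci in seq_len(nrow(conds)))
    for (r in seq_len(design$n_replicates)) {
      a <- conds$t_nacl[ci]; b <- conds$t_phe[ci]
      rows[[length(rows) + 1]] <- data.frame(
        ppep_id = p, protein = sub("_.*", "", p), sites = sub("^[^_]*_", "", p),
        sequence = "PEPTIDEK", n_phospho = 1L,
        t_nacl = a, t_phe = b, replicate = r,
        run_id = sprintf("t%g_p%g_r%d", a, b, r),
        intensity = values[[p]](a, b, r), stringsAsFactors = FALSE)
    }
  df <- do.call(rbind, rows)
  tic <- tapply(df$intensity, df$run_id, sum, na.rm = TRUE)
  df$tic <- as.numeric(tic[df$run_id])
  as_costim_data(df, design)
}
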