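## Signed directed logic networks and the SIF interchange format.
##
## A logic network is a signed directed hypergraph over stimulus,
## phosphopeptide and (unmeasured) protein nodes.  AND gates are encoded
## in SIF via intermediate nodes named "and<k>", as in the common logic-
## modelling convention: "A 1 and1 / B 1 and1 / and1 1 C" is an AND gate
## with inputs A and B and target C.

#' Construct a logic network
#'
#' @param nodes Data frame with columns `name`, `role` (one of
#'   `"STIMULUS"`, `"PPEP"`, `"PROTEIN"`) and logical `measured`.
#' @param edges Data frame with columns `source`, `sign` (+1 activation,
#'   -1 inhibition) and `target`.
#' @param gates List of gates, each `list(id=, inputs=data.frame(source,
#'   sign), target=)`; gates need at least two inputs.
#' @return Object of class `logic_network`.
#' @export
logic_network <- function(nodes, edges, gates = list()) {
  stopifnot(all(c("name", "role", "measured") %in% names(nodes)),
            all(c("source", "sign", "target") %in% names(edges)) ||
              nrow(edges) == 0)
  if (anyDuplicated(nodes$name)) stopf("duplicate node names")
  if (!all(nodes$role %in% c("STIMULUS", "PPEP", "PROTEIN")))
    stopf("node roles must be STIMULUS, PPEP or PROTEIN")
  if (nrow(edges)) {
    known <- nodes$name
    bad <- setdiff(c(edges$source, edges$target), known)
    if (length(bad)) stopf("edge endpoint '%s' is not a node", bad[1])
    if (!all(edges$sign %in% c(-1, 1))) stopf("edge signs must be +1 or -1")
    stim <- nodes$name[nodes$role == "STIMULUS"]
    if (any(edges$target %in% stim))
      stopf("stimulus node '%s' cannot have incoming edges",
            intersect(edges$target, stim)[1])
    if (any(edges$source == edges$target))
      stopf("self-loop on '%s' not allowed", edges$source[edges$source == edges$target][1])
  }
  for (g in gates) {
    if (nrow(g$inputs) < 2) stopf("gate '%s' needs >= 2 inputs", g$id)
    bad <- setdiff(c(g$inputs$source, g$target), nodes$name)
    if (length(bad)) stopf("gate endpoint '%s' is not a node", bad[1])
  }
  edges <- edges[, c("source", "sign", "target")]
  rownames(edges) <- NULL
  structure(list(nodes = nodes[, c("name", "role", "measured")],
                 edges = edges, gates = gates),
            class = "logic_network")
}

#' Node and interaction counts
#'
#' `n_nodes()` counts phosphopeptide and protein nodes (stimulus nodes are
#' not counted, matching the convention "33 measured P-peps and 12
#' proteins" = 45 nodes).  `n_interactions()` counts all signed directed
#' edges, including stimulus edges and AND-gate input edges.
#'
#' @param network A `logic_network`.
#' @return Integer count.
#' @export
n_nodes <- function(network) {
  sum(network$nodes$role != "STIMULUS")
}

#' @rdname n_nodes
#' @export
n_interactions <- function(network) {
  nrow(network$edges) +
    sum(vapply(network$gates, function(g) nrow(g$inputs), integer(1)))
}

#' @export
print.logic_network <- function(x, ...) {
  r <- table(factor(x$nodes$role, c("STIMULUS", "PPEP", "PROTEIN")))
  cat(sprintf(
    "logic_network: %d nodes (%d stimuli, %d P-peps, %d proteins), %d interactions, %d AND gates\n",
    nrow(x$nodes), r[["STIMULUS"]], r[["PPEP"]], r[["PROTEIN"]],
    n_interactions(x), length(x$gates)))
  invisible(x)
}

#' Read / write SIF network files
#'
#' Whitespace-separated triples `source relation target`, relation `1`
#' for activation and `-1` for inhibition; AND gates via intermediate
#' `and<k>` nodes.  Round trips preserve node, edge and gate sets.
#'
#' @param path File path.
#' @param stimuli Node names to mark as STIMULUS.
#' @param measured Node names to mark as measured phosphopeptides; other
#'   non-stimulus nodes become unmeasured proteins.  Default: names
#'   containing a site suffix such as `_S123`, `_T174_Y176`.
#' @return A `logic_network`.
#' @export
read_sif <- function(path, stimuli = c("NaCl", "Phe"), measured = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) != 3
  if (any(bad)) stopf("malformed SIF line: '%s'", lines[bad][1])
  m <- do.call(rbind, parts)
  rel <- m[, 2]
  if (!all(rel %in% c("1", "-1")))
    stopf("unknown relation token '%s' (expected 1 or -1)",
          setdiff(rel, c("1", "-1"))[1])
  src <- m[, 1]; tgt <- m[, 3]; sign <- as.numeric(rel)
  is_and <- function(x) grepl("^and[0-9]+$", x)
  and_nodes <- unique(c(src[is_and(src)], tgt[is_and(tgt)]))
  real <- setdiff(unique(c(src, tgt)), and_nodes)
  if (is.null(measured))
    measured <- real[grepl("_[STY][0-9]+", real)]
  nodes <- data.frame(
    name = real,
    role = ifelse(real %in% stimuli, "STIMULUS",
                  ifelse(real %in% measured, "PPEP", "PROTEIN")),
    measured = real %in% measured, stringsAsFactors = FALSE)
  plain <- !is_and(src) & !is_and(tgt)
  edges <- data.frame(source = src[plain], sign = sign[plain],
                      target = tgt[plain], stringsAsFactors = FALSE)
  gates <- lapply(and_nodes, function(a) {
    ins <- which(tgt == a)
    outs <- which(src == a)
    if (length(outs) != 1)
      stopf("AND node '%s' must have exactly one target", a)
    list(id = a,
         inputs = data.frame(source = src[ins], sign = sign[ins],
                             stringsAsFactors = FALSE),
         target = tgt[outs])
  })
  logic_network(nodes, edges, gates)
}

#' @rdname read_sif
#' @param network A `logic_network` to write.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "logic_network"))
  e <- network$edges
  lines <- sprintf("%s %d %s", e$source, e$sign, e$target)
  for (g in network$gates) {
    lines <- c(lines,
               sprintf("%s %d %s", g$inputs$source, g$inputs$sign, g$id),
               sprintf("%s 1 %s", g$id, g$target))
  }
  writeLines(lines, path)
  invisible(path)
}
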