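## Phosphopeptide-level logic network construction, mechanistic variants
## and the model ensemble.

edge_id <- function(source, target) paste0(source, "->", target)

#' Substitute phosphopeptides into a protein-level prior network
#'
#' Every protein with at least one surviving phosphopeptide is replaced
#' by those peptide nodes; proteins with none are kept as unmeasured
#' protein nodes.  Each prior edge A -> B expands to all (a_i -> b_j)
#' combinations with the prior sign (combinatorial expansion; unreplaced
#' proteins count as a single node).  Stimulus nodes are untouched.
#'
#' @param prior A protein-level `logic_network`.
#' @param assignment Data frame `protein`, `ppep_id` mapping each protein
#'   to its surviving peptides; proteins must exist in the prior.
#' @return A phosphopeptide-level `logic_network`.
#' @export
build_pepnet <- function(prior, assignment) {
  stopifnot(inherits(prior, "logic_network"),
            all(c("protein", "ppep_id") %in% names(assignment)))
  known <- prior$nodes$name
  bad <- setdiff(assignment$protein, known)
  if (length(bad))
    stopf("assignment references protein '%s' absent from the prior", bad[1])
  peps <- split(assignment$ppep_id, assignment$protein)
  expand_node <- function(nm) peps[[nm]] %||% nm
  nodes <- do.call(rbind, lapply(seq_len(nrow(prior$nodes)), function(i) {
    nd <- prior$nodes[i, ]
    if (nd$role == "STIMULUS")
      return(data.frame(name = nd$name, role = "STIMULUS", measured = FALSE))
    reps <- peps[[nd$name]]
    if (is.null(reps))
      data.frame(name = nd$name, role = "PROTEIN", measured = FALSE)
    else
      data.frame(name = reps, role = "PPEP", measured = TRUE)
  }))
  edges <- do.call(rbind, lapply(seq_len(nrow(prior$edges)), function(i) {
    e <- prior$edges[i, ]
    expand.grid(source = expand_node(e$source), sign = e$sign,
                target = expand_node(e$target), KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  }))
  gates <- list()
  k <- 0
  for (g in prior$gates) {
    tgt_opts <- expand_node(g$target)
    in_opts <- lapply(g$inputs$source, expand_node)
    combos <- expand.grid(c(in_opts, list(tgt_opts)),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      k <- k + 1
      gates[[k]] <- list(
        id = paste0("and", k),
        inputs = data.frame(source = unlist(combos[r, seq_len(nrow(g$inputs))]),
                            sign = g$inputs$sign, stringsAsFactors = FALSE),
        target = combos[r, nrow(g$inputs) + 1])
    }
  }
  logic_network(nodes, edges, gates)
}

#' Mechanistic variant specification
#'
#' @param restrict_ste20_to_T511 Keep Ste20_T511 as the only Ste20
#'   phosphopeptide mediating crosstalk (all other Ste20 peptide nodes
#'   and their edges removed).
#' @param add_gpd1_hog1_loop Add the double-negative inhibition between
#'   the Gpd1 phosphopeptide and the measured Hog1 phospho-forms (mutual
#'   inhibitory edges).
#' @param removed_edges Character vector of `"source->target"` edge ids
#'   to delete; each must exist in the model.
#' @return Object of class `variant_spec`.
#' @export
variant_spec <- function(restrict_ste20_to_T511 = FALSE,
                         add_gpd1_hog1_loop = FALSE,
                         removed_edges = character()) {
  structure(list(restrict_ste20_to_T511 = restrict_ste20_to_T511,
                 add_gpd1_hog1_loop = add_gpd1_hog1_loop,
                 removed_edges = sort(unique(removed_edges))),
            class = "variant_spec")
}

variant_signature <- function(spec) {
  paste(as.integer(spec$restrict_ste20_to_T511),
        as.integer(spec$add_gpd1_hog1_loop),
        paste(spec$removed_edges, collapse = "|"), sep = "::")
}

#' Apply a mechanistic variant to a model
#'
#' Applies, in order: the Ste20_T511 restriction (removing the other
#' Ste20 peptide nodes with their incident edges and gate memberships),
#' the Gpd1-Hog1 double-negative loop (mutual inhibition, edges added
#' only if absent), and the explicit edge removals.  Unmeasured protein
#' nodes left without a directed path from any stimulus are pruned.
#' Variants never add nodes.
#'
#' @param model A `logic_network`.
#' @param spec A [variant_spec()].
#' @return The modified `logic_network`.
#' @export
apply_variant <- function(model, spec) {
  stopifnot(inherits(model, "logic_network"), inherits(spec, "variant_spec"))
  nodes <- model$nodes; edges <- model$edges; gates <- model$gates
  drop_nodes <- function(gone) {
    nodes <<- nodes[!nodes$name %in% gone, ]
    edges <<- edges[!(edges$source %in% gone | edges$target %in% gone), ]
    gates <<- Filter(Negate(is.null), lapply(gates, function(g) {
      if (g$target %in% gone) return(NULL)
      g$inputs <- g$inputs[!g$inputs$source %in% gone, , drop = FALSE]
      if (nrow(g$inputs) == 0) return(NULL)
      if (nrow(g$inputs) == 1) {
        ## gate degenerates into a plain edge
        edges <<- rbind(edges, data.frame(source = g$inputs$source,
                                          sign = g$inputs$sign,
                                          target = g$target))
        return(NULL)
      }
      g
    }))
  }
  if (spec$restrict_ste20_to_T511) {
    gone <- nodes$name[nodes$role == "PPEP" &
                         startsWith(nodes$name, "Ste20_") &
                         nodes$name != "Ste20_T511"]
    drop_nodes(gone)
  }
  if (spec$add_gpd1_hog1_loop) {
    gpd1 <- nodes$name[nodes$role == "PPEP" & startsWith(nodes$name, "Gpd1_")]
    hog1 <- nodes$name[nodes$role == "PPEP" & startsWith(nodes$name, "Hog1_")]
    if (!length(gpd1) || !length(hog1))
      stopf("Gpd1/Hog1 phosphopeptide nodes not present; cannot add loop")
    new <- rbind(expand.grid(source = gpd1, target = hog1,
                             stringsAsFactors = FALSE),
                 expand.grid(source = hog1, target = gpd1,
                             stringsAsFactors = FALSE))
    have <- edge_id(edges$source, edges$target)
    new <- new[!edge_id(new$source, new$target) %in% have, , drop = FALSE]
    if (nrow(new))
      edges <- rbind(edges, data.frame(source = new$source, sign = -1,
                                       target = new$target))
  }
  if (length(spec$removed_edges)) {
    have <- edge_id(edges$source, edges$target)
    missing <- setdiff(spec$removed_edges, have)
    if (length(missing))
      stopf("edge '%s' does not exist in the model", missing[1])
    edges <- edges[!have %in% spec$removed_edges, , drop = FALSE]
  }
  ## prune unmeasured proteins with no path from any stimulus
  repeat {
    reach <- stimulus_reachable(nodes, edges, gates)
    gone <- nodes$name[nodes$role == "PROTEIN" & !nodes$measured &
                         !nodes$name %in% reach]
    if (!length(gone)) break
    drop_nodes(gone)
  }
  logic_network(nodes, edges, gates)
}

## forward reachability from the stimulus nodes
stimulus_reachable <- function(nodes, edges, gates) {
  adj <- edges[, c("source", "target")]
  for (g in gates)
    adj <- rbind(adj, data.frame(source = g$inputs$source, target = g$target))
  frontier <- nodes$name[nodes$role == "STIMULUS"]
  seen <- frontier
  while (length(frontier)) {
    nxt <- unique(adj$target[adj$source %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Default ensemble scheme
#'
#' The default model ensemble combines (i) the four combinations of the
#' two proposed crosstalk mechanisms, (ii) four combinations of the
#' "No Effect upon NaCl" interaction removals applied to the
#' both-mechanisms model (the no-effect interaction into Ste20_T573 is
#' already absent there), and (iii) fifteen single-interaction removals
#' from the both-mechanisms model -- 23 models in total.
#'
#' @param noeffect_edges,single_removals Optional custom edge-id lists;
#'   defaults come from the shipped fixtures.
#' @return List with components `mechanisms`, `noeffect_combos`,
#'   `single_removals`.
#' @export
ensemble_scheme <- function(noeffect_edges = NULL, single_removals = NULL) {
  if (is.null(noeffect_edges)) {
    ne <- costim_noeffect_edges()
    noeffect_edges <- edge_id(ne$source, ne$target)
  }
  if (is.null(single_removals)) {
    sr <- costim_single_removals()
    single_removals <- edge_id(sr$source, sr$target)
  }
  ## the removable no-effect edges present in the both-mechanisms model
  present <- setdiff(noeffect_edges, "Sho1->Ste20_T573")
  combos <- c(list(present),
              utils::combn(present, 2, simplify = FALSE))[1:4]
  list(
    mechanisms = list(
      variant_spec(FALSE, FALSE), variant_spec(TRUE, FALSE),
      variant_spec(FALSE, TRUE), variant_spec(TRUE, TRUE)),
    noeffect_combos = combos,
    single_removals = single_removals)
}

#' Enumerate the model ensemble
#'
#' Builds the deduplicated list of model variants from a scheme: the
#' mechanism combinations, the no-effect removal combinations and the
#' single-edge removals (removals are applied on top of the
#' both-mechanisms model).
#'
#' @param base_model The phosphopeptide-level base model.
#' @param scheme An [ensemble_scheme()].
#' @return List of `list(id=, spec=, model=)`; duplicated variant specs
#'   are collapsed with a warning.
#' @export
enumerate_ensemble <- function(base_model, scheme = ensemble_scheme()) {
  specs <- scheme$mechanisms
  for (combo in scheme$noeffect_combos)
    specs <- c(specs, list(variant_spec(TRUE, TRUE, combo)))
  for (e in scheme$single_removals)
    specs <- c(specs, list(variant_spec(TRUE, TRUE, e)))
  sigs <- vapply(specs, variant_signature, character(1))
  if (anyDuplicated(sigs)) {
    warnf("%d duplicate variant specs collapsed", sum(duplicated(sigs)))
    specs <- specs[!duplicated(sigs)]
  }
  lapply(seq_along(specs), function(i)
    list(id = sprintf("M%02d", i), spec = specs[[i]],
         model = apply_variant(base_model, specs[[i]])))
}

## ---- shipped fixtures ----------------------------------------------------

extdata <- function(file) {
  path <- system.file("extdata", file, package = "costim")
  if (!nzchar(path)) stopf("fixture '%s' not found", file)
  path
}

#' Shipped network fixtures
#'
#' `costim_prior_network()` loads the protein-level prior-knowledge
#' network of the HOG and pheromone pathways (a synthetic reconstruction
#' shipped with the package); `costim_modeling_ppeps()` the 33-peptide
#' modelling list; `costim_noeffect_edges()` and
#' `costim_single_removals()` the edge lists used by the default
#' ensemble scheme; `costim_base_model()` the phosphopeptide-level base
#' model obtained by substituting the modelling peptides into the prior.
#'
#' @return A `logic_network` or a data frame, respectively.
#' @export
costim_prior_network <- function() {
  read_sif(extdata("prior_network.sif"), stimuli = c("NaCl", "Phe"),
           measured = character())
}

#' @rdname costim_prior_network
#' @export
costim_modeling_ppeps <- function() {
  utils::read.csv(extdata("modeling_ppeps.csv"), stringsAsFactors = FALSE)
}

#' @rdname costim_prior_network
#' @export
costim_noeffect_edges <- function() {
  utils::read.csv(extdata("noeffect_edges.csv"), stringsAsFactors = FALSE)
}

#' @rdname costim_prior_network
#' @export
costim_single_removals <- function() {
  utils::read.csv(extdata("single_removals.csv"), stringsAsFactors = FALSE)
}

#' @rdname costim_prior_network
#' @export
costim_base_model <- function() {
  build_pepnet(costim_prior_network(), costim_modeling_ppeps())
}
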