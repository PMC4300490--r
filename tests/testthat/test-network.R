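test_that("peptide substitution expands edges combinatorially", {
  prior <- logic_network(
    nodes = data.frame(name = c("S", "A", "B"),
                       role = c("STIMULUS", "PROTEIN", "PROTEIN"),
                       measured = FALSE),
    edges = data.frame(source = c("S", "A"), sign = 1, target = c("A", "B")))
  asg <- data.frame(protein = c("A", "A", "B", "B", "B"),
                    ppep_id = c("A_S1", "A_S2", "B_S1", "B_S2", "B_S3"))
  net <- build_pepnet(prior, asg)
  ## S->A expands to 2, A->B to 2*3 = 6
  expect_equal(nrow(net$edges), 8)
  expect_equal(sum(net$edges$source %in% c("A_S1", "A_S2") &
                     grepl("^B_", net$edges$target)), 6)
  expect_error(build_pepnet(prior, data.frame(protein = "Z", ppep_id = "Z_S1")),
               "absent")
})

test_that("edge counts equal the brute-force combinatorial enumeration", {
  set.seed(7)
  for (rep_i in 1:5) {
    prots <- paste0("P", 1:6)
    edges <- unique(data.frame(
      source = c("S", sample(prots, 7, TRUE)),
      sign = sample(c(-1, 1), 8, TRUE),
      target = c(sample(prots, 1), sample(prots, 7, TRUE)),
      stringsAsFactors = FALSE))
    edges <- edges[edges$source != edges$target, ]
    prior <- logic_network(
      nodes = data.frame(name = c("S", prots),
                         role = c("STIMULUS", rep("PROTEIN", 6)),
                         measured = FALSE),
      edges = edges)
    npep <- sample(0:3, 6, TRUE)
    asg <- do.call(rbind, lapply(seq_along(prots), function(i) {
      if (npep[i] == 0) return(NULL)
      data.frame(protein = prots[i],
                 ppep_id = sprintf("%s_S%d", prots[i], seq_len(npep[i])))
    }))
    if (is.null(asg)) next
    net <- build_pepnet(prior, asg)
    expect_equal(n_interactions(net), brute_force_edge_count(prior, asg))
  }
})

test_that("unreplaced proteins stay as unmeasured nodes", {
  base <- costim_base_model()
  prot <- base$nodes[base$nodes$role == "PROTEIN", ]
  expect_equal(nrow(prot), 12)
  expect_true(all(!prot$measured))
  expect_true("Ste11_Ste50_complex" %in% prot$name)
})

test_that("the shipped fixtures build the 45-node / 93-interaction base model", {
  base <- costim_base_model()
  expect_equal(n_nodes(base), 45)
  expect_equal(n_interactions(base), 93)
  expect_equal(sum(base$nodes$role == "PPEP"), 33)
})

test_that("both mechanisms give the 39-node / 73-interaction model", {
  base <- costim_base_model()
  both <- apply_variant(base, variant_spec(TRUE, TRUE))
  expect_equal(n_nodes(both), 39)
  expect_equal(n_interactions(both), 73)
  ## the only Ste20 peptide left is T511
  expect_equal(grep("^Ste20_", both$nodes$name, value = TRUE), "Ste20_T511")
})

test_that("the empty variant is the identity and mechanisms are idempotent", {
  base <- costim_base_model()
  same <- apply_variant(base, variant_spec())
  expect_equal(n_nodes(same), n_nodes(base))
  expect_equal(n_interactions(same), n_interactions(base))
  both <- apply_variant(base, variant_spec(TRUE, TRUE))
  again <- apply_variant(both, variant_spec(TRUE, TRUE))
  expect_equal(again$edges[order(again$edges$source, again$edges$target), ],
               both$edges[order(both$edges$source, both$edges$target), ],
               ignore_attr = TRUE)
})

test_that("no-effect edge removal drops the interaction count by exactly 4", {
  base <- costim_base_model()
  ne <- costim_noeffect_edges()
  ids <- paste0(ne$source, "->", ne$target)
  cut <- apply_variant(base, variant_spec(removed_edges = ids))
  expect_equal(n_interactions(base) - n_interactions(cut), 4)
  expect_error(apply_variant(base, variant_spec(removed_edges = "X->Y")),
               "X->Y")
})

test_that("variants never add unmeasured nodes", {
  base <- costim_base_model()
  for (spec in list(variant_spec(TRUE, FALSE), variant_spec(FALSE, TRUE),
                    variant_spec(TRUE, TRUE))) {
    v <- apply_variant(base, spec)
    new_prot <- setdiff(v$nodes$name[!v$nodes$measured &
                                       v$nodes$role == "PROTEIN"],
                        base$nodes$name)
    expect_length(new_prot, 0)
  }
})

test_that("the default scheme enumerates 23 distinct models", {
  base <- costim_base_model()
  ens <- enumerate_ensemble(base)
  expect_length(ens, 23)
  sigs <- vapply(ens, function(m) costim:::variant_signature(m$spec),
                 character(1))
  expect_false(anyDuplicated(sigs) > 0)
})

test_that("custom schemes enumerate by simple arithmetic", {
  base <- costim_base_model()
  one <- list(mechanisms = list(variant_spec()), noeffect_combos = list(),
              single_removals = character())
  expect_length(enumerate_ensemble(base, one), 1)
  five <- list(mechanisms = list(variant_spec(), variant_spec(TRUE, TRUE)),
               noeffect_combos = list(),
               single_removals = c("Ptc1->Hog1_T174", "Ptc1->Hog1_T174_Y176",
                                   "Nbp2_S196->Ptc1"))
  expect_length(enumerate_ensemble(base, five), 5)
})
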