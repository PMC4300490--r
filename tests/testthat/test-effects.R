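## small hand-built surface helper: values[i, j] over a design
surface_from_matrix <- function(mats, design = stim_design()) {
  tn <- design$nacl_times; tp <- design$phe_times
  cn <- condition_name(rep(tn, length(tp)), rep(tp, each = length(tn)))
  mean_m <- do.call(rbind, lapply(mats, function(m) as.vector(m)))
  dimnames(mean_m) <- list(names(mats), cn)
  structure(list(mean = mean_m, sd = mean_m * 0,
                 n = matrix(3L, nrow(mean_m), ncol(mean_m),
                            dimnames = dimnames(mean_m)),
                 provenance = matrix("OBSERVED", nrow(mean_m), ncol(mean_m),
                                     dimnames = dimnames(mean_m)),
                 design = design,
                 ppep_info = data.frame(
                   ppep_id = names(mats),
                   protein = sub("_.*", "", names(mats)),
                   sites = sub("^[^_]*_", "", names(mats)),
                   sequence = "PEPK", n_phospho = 1L)),
            class = "mean_surface")
}

test_that("curve extraction gives one curve per fixed other-stimulus duration", {
  d <- stim_design()
  s <- surface_from_matrix(list(A_S1 = matrix(2, 6, 6)), d)
  cn <- extract_curves(s, "NaCl")
  cp <- extract_curves(s, "Phe")
  expect_equal(nrow(cn$curves), 6)
  expect_equal(nrow(cp$curves), 6)
  expect_true(all(cn$curves == 2) && all(cp$curves == 2))
  s$mean[1, 3] <- NA
  expect_error(extract_curves(s, "NaCl"), "MISSING")
})

test_that("a planted dip is the minimum of every pheromone-axis curve", {
  p <- archetype_panel(data.frame(
    ppep_id = "Dip_S1", protein = "Dip", sites = "S1", base_shape = "SPIKE",
    driving = "NaCl", modifier = "DIP_AT", amplitude = 1, dip_time = 1,
    dip_factor = 0.3, label_nacl = "INTENSITY", label_phe = "INTENSITY"))
  d <- stim_design()
  arr <- generate_truth(p, d)$intensity[1, , ]
  s <- surface_from_matrix(list(Dip_S1 = arr), d)
  cur <- extract_curves(s, "Phe")
  j <- match(1, d$phe_times)
  for (r in seq_len(nrow(cur$curves)))
    expect_equal(which.min(cur$curves[r, ]), j)
})

test_that("k-means separates planted curve families and validates k", {
  set.seed(1)
  fam1 <- matrix(rep(c(1, 5, 1, 1, 1, 1), 10), 10, byrow = TRUE)
  fam2 <- matrix(rep(c(1, 1, 1, 1, 5, 1), 10), 10, byrow = TRUE)
  x <- rbind(fam1, fam2) * (1 + 0.02 * matrix(rnorm(120), 20))
  labs <- kmeans_curves(x, k = 2, seed = 1)
  expect_equal(length(unique(labs[1:10])), 1)
  expect_equal(length(unique(labs[11:20])), 1)
  expect_false(labs[1] == labs[11])
  expect_error(kmeans_curves(x, k = 21, seed = 1), "exceeds")
  ## identical curves: k collapses to the number of distinct points
  same <- matrix(1, 10, 6)
  expect_warning(l2 <- kmeans_curves(same, k = 3, seed = 1), "distinct")
  expect_equal(length(unique(l2)), 1)
})

test_that("a constant peptide is No Effect for both stimuli", {
  s <- surface_from_matrix(list(A_S1 = matrix(4, 6, 6)))
  calls <- suppressWarnings(
    classify_effects(s, k_nacl = 2, k_phe = 2, seed = 1))
  expect_equal(calls$call, c("NONE", "NONE"))
  expect_equal(calls$intensity_score, c(0, 0))
})

test_that("intensity score matches the hand-computed range/mean rule", {
  ## NaCl-axis curves are constant with per-curve means (1,1,1,1,1,2):
  ## score (2-1)/(7/6) = 6/7 >= 0.7 -> Intensity for pheromone
  m <- matrix(1, 6, 6); m[, 6] <- 2
  s <- surface_from_matrix(list(A_S1 = m))
  calls <- suppressWarnings(
    classify_effects(s, k_nacl = 2, k_phe = 2, seed = 1))
  phe <- calls[calls$stimulus == "Phe", ]
  expect_equal(phe$intensity_score, 6 / 7, tolerance = 1e-12)
  expect_equal(phe$call, "INTENSITY")
})

test_that("classification is invariant to a global intensity rescaling", {
  d <- stim_design()
  ds <- sim_costim(panel_effects(), d, noise_model(0.05, 0, 0), seed = 2)
  s <- impute_spline(average_replicates(tic_normalize(ds)))
  s2 <- s; s2$mean <- s2$mean * 1000
  c1 <- classify_effects(s, seed = 3)
  c2 <- classify_effects(s2, seed = 3)
  expect_equal(c1$call, c2$call)
  expect_equal(c1$intensity_score, c2$intensity_score, tolerance = 1e-9)
})

test_that("planted phase-shift peptides are Shape Effects at low noise", {
  d <- stim_design()
  ds <- sim_costim(panel_effects(), d, noise_model(0.05, 0, 0), seed = 5)
  s <- impute_spline(average_replicates(tic_normalize(ds)))
  calls <- classify_effects(s, seed = 5)
  shp <- calls[grepl("^Shp_", calls$ppep_id) & calls$stimulus == "Phe", ]
  expect_true(all(shp$call == "SHAPE"))
})

test_that("hierarchical clustering co-clusters duplicates and splits families", {
  d <- stim_design()
  m1 <- outer(costim:::shape_value("SPIKE", d$nacl_times), rep(1, 6))
  m2 <- outer(costim:::shape_value("GRADUAL", d$nacl_times), rep(1, 6))
  s <- surface_from_matrix(list(A_S1 = m1, A_S2 = m1, B_S1 = m2, B_S2 = m2), d)
  cl <- hier_cluster(s, k = 2)
  expect_equal(cl[["A_S1"]], cl[["A_S2"]])
  expect_equal(cl[["B_S1"]], cl[["B_S2"]])
  expect_false(cl[["A_S1"]] == cl[["B_S1"]])
  expect_error(hier_cluster(s, k = 10), "exceeds")
})
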