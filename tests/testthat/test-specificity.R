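spec_surface <- function(m, design = stim_design())
  structure(list(mean = matrix(as.vector(m), 1,
                               dimnames = list("A_S1",
                                               condition_name(
                                                 rep(design$nacl_times, length(design$phe_times)),
                                                 rep(design$phe_times, each = length(design$nacl_times))))),
                 design = design),
            class = "mean_surface")

test_that("no modulation gives the all-ones matrix and vector", {
  s <- spec_surface(matrix(3, 6, 6))
  m <- specificity_matrix(s, "A_S1", "Phe", eps = 0)
  expect_equal(unclass(m), matrix(1, 6, 6), ignore_attr = TRUE)
  expect_equal(unname(specificity_vector(m)), rep(1, 6))
})

test_that("uniform doubling and halving give ratios 0.5 and 2", {
  base <- matrix(4, 6, 6)
  doubled <- base; doubled[, 2:6] <- 8    # Stimulus_2 amplifies
  halved <- base; halved[, 2:6] <- 2      # Stimulus_2 inhibits
  m_amp <- specificity_matrix(spec_surface(doubled), "A_S1", "Phe", eps = 0)
  m_inh <- specificity_matrix(spec_surface(halved), "A_S1", "Phe", eps = 0)
  expect_equal(unique(as.vector(m_amp[, 2:6])), 0.5)
  expect_equal(unique(as.vector(m_inh[, 2:6])), 2)
  expect_equal(unname(m_amp[, 1]), rep(1, 6))
})

test_that("the 2x2 toy matches the hand computation", {
  d <- stim_design(c(0, 5), c(0, 5), 1)
  I <- matrix(c(4, 8, 2, 8), 2)   # rows i (Stimulus_1), cols j (Stimulus_2)
  s <- spec_surface(I, d)
  m <- specificity_matrix(s, "A_S1", "Phe", eps = 0)
  expect_equal(unclass(m), matrix(c(1, 1, 2, 1), 2), ignore_attr = TRUE)
  expect_equal(unname(specificity_vector(m)), c(1, 1.5))
})

test_that("column averaging is the arithmetic mean", {
  m <- structure(cbind(rep(1, 6), 1:6), modulating = "Phe",
                 class = c("specificity_matrix", "matrix"))
  expect_equal(unname(specificity_vector(m)), c(1, 3.5))
})

test_that("specificity is exactly scale invariant (eps scaled too)", {
  d <- stim_design()
  ds <- sim_costim(panel_effects()[1:10, ], d, noise_model(0.1, 0, 0), seed = 8)
  s <- impute_spline(average_replicates(ds))
  m1 <- specificity_matrix(s, rownames(s$mean)[3], "Phe")
  s2 <- s; s2$mean <- s2$mean * 137
  m2 <- specificity_matrix(s2, rownames(s$mean)[3], "Phe")
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-12)
})

test_that("the pattern screen ranks self first and log-reciprocals opposite", {
  q <- c(1, 3, 0.6, 1.2, 1, 1)
  cand <- rbind(A_S1 = q, B_S1 = 1 / q, C_S1 = c(1, 1.1, 0.9, 1, 1, 1))
  sim <- pattern_match(q, cand, "SIMILAR", window = 4, r_min = 0.9)
  expect_equal(sim$ppep_id[1], "A_S1")
  expect_equal(sim$r[1], 1)
  opp <- pattern_match(q, cand, "OPPOSITE", window = 4, r_min = 0.9)
  expect_equal(opp$ppep_id[1], "B_S1")
  expect_equal(opp$r[1], -1)
})

test_that("zero-variance candidates are skipped with a warning", {
  q <- c(1, 2, 3, 4, 1, 1)
  cand <- rbind(Flat_S1 = rep(1, 6), B_S1 = q)
  expect_warning(out <- pattern_match(q, cand, "SIMILAR", r_min = 0.5),
                 "zero variance")
  expect_false("Flat_S1" %in% out$ppep_id)
})

test_that("planted dip-vs-bump specificity vectors are strongly opposite", {
  d <- stim_design()
  mk <- function(f) archetype_panel(data.frame(
    ppep_id = paste0(f, "_S1"), protein = f, sites = "S1",
    base_shape = "SPIKE", driving = "NaCl", modifier = "DIP_AT",
    amplitude = 1e6, dip_time = 1, dip_factor = if (f == "Dip") 0.3 else 3,
    label_nacl = "INTENSITY", label_phe = "INTENSITY"))
  pan <- rbind(mk("Dip"), mk("Bmp"))
  ds <- sim_costim(pan, d, noise_model(0.02, 0, 0), seed = 3)
  s <- impute_spline(average_replicates(tic_normalize(ds)))
  v <- specificity_vectors(s, "Phe")
  out <- pattern_match(v["Dip_S1", ], v["Bmp_S1", , drop = FALSE],
                       "OPPOSITE", window = 4, r_min = 0.9)
  expect_equal(out$ppep_id, "Bmp_S1")
  expect_lte(out$r, -0.9)
})
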