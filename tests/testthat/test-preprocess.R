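test_that("TIC normalisation rescales runs and preserves within-run ratios", {
  d <- stim_design(c(0, 1), c(0, 1), 1)
  ## two peptides, four runs; run t1_p0 has doubled raw values and TIC
  vals <- list(
    A_S1 = function(a, b, r) if (a == 1 && b == 0) 8 else 4,
    B_S2 = function(a, b, r) if (a == 1 && b == 0) 2 else 1)
  ds <- make_toy_dataset(vals, d)
  norm <- tic_normalize(ds)
  m <- impute_spline(average_replicates(norm))$mean
  ## hand computation: TICs are (5,10,5,5), mean 6.25; normalised A is
  ## 4/5*6.25 = 5 everywhere (doubled run cancels), B is 1.25
  expect_equal(unname(m["A_S1", ]), rep(5, 4))
  expect_equal(unname(m["B_S2", ]), rep(1.25, 4))
  ## within-run ratio preserved exactly
  expect_equal(m["A_S1", ] / m["B_S2", ], rep(4, 4), ignore_attr = TRUE)
})

test_that("uniform TICs leave the dataset unchanged (incl. single run)", {
  d <- stim_design(0, 0, 1)
  ds <- make_toy_dataset(list(A_S1 = function(a, b, r) 3,
                              B_S2 = function(a, b, r) 9), d)
  expect_equal(tic_normalize(ds)$intensity, ds$intensity)
})

test_that("missing or non-positive TIC is an error", {
  d <- stim_design(0, 0, 1)
  ds <- make_toy_dataset(list(A_S1 = function(a, b, r) 3), d)
  ds$tic <- NA_real_
  expect_error(tic_normalize(ds), "TIC")
})

test_that("features merge by (sequence, phosphate count) with summed intensities", {
  ft <- data.frame(
    protein = c("Hog1", "Hog1", "Fus3"),
    sites = c("T174", "T174", "T180"),
    sequence = c("SEQA", "SEQA", "SEQB"),
    n_phospho = c(1L, 1L, 1L), charge = c(2L, 3L, 2L),
    t_nacl = 0, t_phe = 0, replicate = 1L,
    intensity = c(5, 7, 11), stringsAsFactors = FALSE)
  d <- stim_design(0, 0, 1)
  out <- merge_features(ft, d)
  expect_equal(nrow(out), 2)
  expect_equal(out$intensity[out$protein == "Hog1"], 12)
  expect_equal(out$intensity[out$protein == "Fus3"], 11)
})

test_that("ambiguous site calls merge with bracketed sites; conflicts error", {
  ft <- data.frame(
    protein = "Hog1", sites = c("T174", "Y176"), sequence = "SEQA",
    n_phospho = 1L, charge = 2L, t_nacl = 0, t_phe = 0,
    replicate = 1L, intensity = c(5, 7), stringsAsFactors = FALSE)
  out <- merge_features(ft, stim_design(0, 0, 1))
  expect_equal(nrow(out), 1)
  expect_match(out$sites, "^\\(.*T174.*Y176.*\\)$")
  expect_equal(out$intensity, 12)
  ft$protein <- c("Hog1", "Pbs2")
  expect_error(merge_features(ft, stim_design(0, 0, 1)), "conflicting protein")
})

test_that("detection filter needs four detected time points on both axes", {
  d <- stim_design()
  everywhere <- function(a, b, r) 5
  only3nacl <- function(a, b, r) if (a %in% c(0, 1, 5)) 5 else NA_real_
  exactly4 <- function(a, b, r)
    if (a %in% c(0, 1, 5, 10) && b %in% c(0, 1, 5, 10)) 5 else NA_real_
  ds <- make_toy_dataset(list(A_S1 = everywhere, B_S2 = only3nacl,
                              C_S3 = exactly4),
                         stim_design(c(0, 1, 5, 10, 20, 45),
                                     c(0, 1, 5, 10, 20, 45), 1))
  expect_setequal(detection_filter(ds), c("A_S1", "C_S3"))
})

test_that("detection filter is monotone in detections", {
  d <- stim_design(c(0, 1, 5, 10, 20, 45), c(0, 1, 5, 10, 20, 45), 1)
  base_fun <- function(a, b, r) if (a %in% c(0, 1, 5)) 5 else NA_real_
  more_fun <- function(a, b, r) if (a %in% c(0, 1, 5, 10)) 5 else NA_real_
  ds1 <- make_toy_dataset(list(A_S1 = base_fun), d)
  ds2 <- make_toy_dataset(list(A_S1 = more_fun), d)
  expect_true(length(detection_filter(ds1)) <= length(detection_filter(ds2)))
})

test_that("replicate averaging records mean, sd and n per cell", {
  d <- stim_design(0, 0, 3)
  ds <- make_toy_dataset(list(A_S1 = function(a, b, r) c(2, 4, 6)[r],
                              B_S2 = function(a, b, r)
                                if (r == 1) 5 else NA_real_,
                              C_S3 = function(a, b, r) NA_real_), d)
  s <- average_replicates(ds)
  expect_equal(s$mean["A_S1", 1], 4)
  expect_equal(s$sd["A_S1", 1], 2)
  expect_equal(s$n["A_S1", 1], 3L, ignore_attr = TRUE)
  expect_equal(s$mean["B_S2", 1], 5)
  expect_equal(s$sd["B_S2", 1], 0)   # single replicate: sd recorded as 0
  expect_equal(s$n["B_S2", 1], 1L, ignore_attr = TRUE)
  expect_true(is.na(s$mean["C_S3", 1]))
  expect_equal(s$provenance["C_S3", 1], "MISSING", ignore_attr = TRUE)
})

test_that("spline imputation is exact on affine tracks and only fills gaps", {
  d <- stim_design(c(0, 1, 2, 3, 4, 5), 0, 1)
  ds <- make_toy_dataset(list(
    A_S1 = function(a, b, r) if (a == 2) NA_real_ else a + 1), d)
  s0 <- average_replicates(ds)
  s <- impute_spline(s0)
  expect_equal(unname(s$mean["A_S1", ]), 1:6)   # affine gap filled exactly
  expect_equal(unname(s$provenance["A_S1", ]),
               c("OBSERVED", "OBSERVED", "IMPUTED", "OBSERVED",
                 "OBSERVED", "OBSERVED"))
  ## no missing cells: identity
  full <- make_toy_dataset(list(A_S1 = function(a, b, r) a + 1), d)
  sf <- average_replicates(full)
  expect_equal(impute_spline(sf)$mean, sf$mean)
})

test_that("imputation falls back to the other axis and warns when stuck", {
  d <- stim_design(c(0, 1), c(0, 1, 2, 3), 1)
  ## NaCl tracks have only 2 points, pheromone tracks 4: fallback used
  ds <- make_toy_dataset(list(
    A_S1 = function(a, b, r) if (a == 0 && b == 1) NA_real_ else 10 + b), d)
  s <- impute_spline(average_replicates(ds))
  expect_equal(unname(s$mean["A_S1", condition_name(0, 1)]), 11)
  ## too few points on both axes: left missing with a warning
  d2 <- stim_design(c(0, 1), c(0, 1), 1)
  ds2 <- make_toy_dataset(list(
    A_S1 = function(a, b, r) if (a == 0 && b == 1) NA_real_ else 5), d2)
  expect_warning(s2 <- impute_spline(average_replicates(ds2)),
                 "not imputable")
  expect_true(is.na(s2$mean["A_S1", condition_name(0, 1)]))
})

test_that("the 1.5x mock rule is strict at the boundary", {
  real <- matrix(c(1, 1, 1), 3, 1, dimnames = list(c("a", "b", "c"), "t"))
  mock <- matrix(c(1, 1.6, 1.5), 3, 1, dimnames = list(c("a", "b", "c"), "t"))
  cmp <- mock_compare(real, mock, eps = 0)
  expect_true(cmp$negligible["a"])
  expect_false(cmp$negligible["b"])   # ratio 1.6
  expect_false(cmp$negligible["c"])   # ratio exactly 1.5: strict <
  expect_equal(cmp$fraction, 1 / 3)
  ident <- mock_compare(real, real, eps = 0)
  expect_equal(ident$fraction, 1)
})
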