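make_one_layer_stack <- function(values, cellsize = 1) {
  climate_stack(list(bio1 = structure(
    list(values = as.matrix(values), ncols = ncol(as.matrix(values)),
         nrows = nrow(as.matrix(values)), xll = 0, yll = 0,
         cellsize = cellsize, nodata = -9999), class = "climate_layer")))
}

test_that("envelope scores follow the piecewise-linear calibration", {
  train <- matrix(0:100, ncol = 1, dimnames = list(NULL, "bio1"))
  m <- fit_envelope(train)                      # q05 = 5, q95 = 95
  sc <- delimitax:::score_matrix
  expect_equal(sc(m, matrix(50)), 1)            # inside the band
  expect_equal(sc(m, matrix(97.5)), 0.5)        # halfway down the decay
  expect_equal(sc(m, matrix(2.5)), 0.5)
  expect_equal(sc(m, matrix(150)), 0)           # beyond the training range
  expect_equal(sc(m, matrix(-1)), 0)
  # constant training layer: no division by zero, scores 1 at the value
  mc <- fit_envelope(matrix(rep(7, 6), ncol = 1,
                            dimnames = list(NULL, "bio1")))
  expect_equal(sc(mc, matrix(7)), 1)
  expect_equal(sc(mc, matrix(8)), 0)
})

test_that("normalized surfaces sum to one and are scale invariant", {
  st <- make_one_layer_stack(matrix(runif(25, 10, 90), 5, 5))
  raw <- matrix(runif(25), 5, 5)
  s1 <- normalize_surface(suitability_surface(raw, st))
  expect_equal(sum(s1$values[s1$mask]), 1, tolerance = 1e-9)
  s2 <- normalize_surface(suitability_surface(raw * 37.5, st))
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
  # masking renormalizes over the remainder
  msk <- st$mask; msk[1, ] <- FALSE
  s3 <- normalize_surface(suitability_surface(raw, st), msk)
  expect_equal(sum(s3$values[s3$mask]), 1, tolerance = 1e-9)
  expect_error(normalize_surface(suitability_surface(matrix(0, 5, 5), st)),
               "all-zero")
})

test_that("Schoener's D matches its definition and bounds", {
  st <- make_one_layer_stack(matrix(1, 1, 2))
  surf <- function(v) normalize_surface(
    suitability_surface(matrix(v, 1, 2), st))
  expect_equal(schoener_D(surf(c(1, 0)), surf(c(0.5, 0.5))), 0.5)
  expect_equal(schoener_D(surf(c(0.3, 0.7)), surf(c(0.3, 0.7))), 1.0)
  expect_equal(schoener_D(surf(c(1, 1e-12)), surf(c(1e-12, 1))), 0,
               tolerance = 1e-9)
  # symmetry and lattice check
  a <- surf(c(0.2, 0.8)); b <- surf(c(0.9, 0.1))
  expect_equal(schoener_D(a, b), schoener_D(b, a))
  st2 <- make_one_layer_stack(matrix(1, 1, 2), cellsize = 2)
  expect_error(schoener_D(a, normalize_surface(
    suitability_surface(matrix(0.5, 1, 2), st2))), "lattice")
})

test_that("the triangle-like bound |D(a,b) - D(a,c)| <= 1 holds on random surfaces", {
  st <- make_one_layer_stack(matrix(runif(36, 0, 100), 6, 6))
  set.seed(99)
  for (i in 1:20) {
    s <- replicate(3, normalize_surface(
      suitability_surface(matrix(runif(36), 6, 6), st)), simplify = FALSE)
    dab <- schoener_D(s[[1]], s[[2]]); dac <- schoener_D(s[[1]], s[[3]])
    expect_true(abs(dab - dac) <= 1)
    expect_true(dab >= 0 && dab <= 1)
  }
})

test_that("identity test is reproducible and respects its p-value identity", {
  w <- make_small_world()
  oa <- gen_occurrences(niche_spec("A", 30), w, seed = 1)
  ob <- gen_occurrences(niche_spec("B", 45), w, seed = 2)
  it <- identity_test(oa, ob, w, reps = 50, seed = 7)
  expect_length(it$null_Ds, 50)
  expect_equal(it$p_value, (1 + sum(it$null_Ds <= it$D_obs)) / 51)
  expect_gte(it$p_value, 1 / 51)
  it2 <- identity_test(oa, ob, w, reps = 50, seed = 7)
  expect_identical(it$null_Ds, it2$null_Ds)
  expect_identical(it$D_obs, it2$D_obs)
  # strongly separated niches are rejected at the smallest attainable p
  oc <- gen_occurrences(niche_spec("C", 85, breadth = 6), w, seed = 3)
  od <- gen_occurrences(niche_spec("D", 15, breadth = 6), w, seed = 4)
  itc <- identity_test(oc, od, w, reps = 100, seed = 5)
  expect_lte(itc$p_value, 0.05)
})

test_that("minimum-training-presence range maps threshold and compare correctly", {
  w <- make_small_world()
  occ <- gen_occurrences(niche_spec("A", 40), w, seed = 11)
  clim <- extract_climate(dedup_occurrences(occ, w), w)
  m <- fit_envelope(clim)
  rm1 <- range_map(m, w, occ, k_folds = 5)
  scores <- delimitax:::score_matrix(m, clim)
  expect_true(rm1$threshold >= min(scores))
  expect_true(rm1$threshold <= 1)
  surf <- predict_surface(m, w)
  expect_true(all(surf$values[rm1$suitable] >= rm1$threshold))
  expect_false(ranges_disjoint(rm1, rm1))
  # maps suitable on opposite halves are disjoint
  half <- rm1
  half$suitable[] <- FALSE; half$suitable[, 1:12] <- TRUE
  other <- rm1
  other$suitable[] <- FALSE; other$suitable[, 13:25] <- TRUE
  expect_true(ranges_disjoint(half, other))
})

test_that("rank AUC enumerates pairs, and agrees with pROC on model scores", {
  expect_equal(delimitax:::rank_auc(c(0.9, 0.7), c(0.8, 0.1)), 0.75)
  expect_equal(delimitax:::rank_auc(c(5, 6), c(1, 2)), 1.0)
  expect_equal(delimitax:::rank_auc(c(1, 1), c(1, 1)), 0.5)  # all ties
  skip_if_not_installed("pROC")
  w <- make_small_world()
  occ <- gen_occurrences(niche_spec("A", 30), w, seed = 21)
  clim <- extract_climate(dedup_occurrences(occ, w), w)
  m <- fit_envelope(clim)
  bg <- delimitax:::background_sample(w, 300, seed = 2)
  sp <- delimitax:::score_matrix(m, clim)
  sb <- delimitax:::score_matrix(m, bg)
  ours <- auc(m, clim, bg)
  theirs <- as.numeric(pROC::auc(
    pROC::roc(response = c(rep(1, length(sp)), rep(0, length(sb))),
              predictor = c(sp, sb), quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("permutation importance sums to 100 and ignores constant layers", {
  w <- make_small_world(n_layers = 2)
  # make layer 2 constant: it carries no information
  w$layers$bio2[] <- 50
  w$layers$bio2[!w$mask] <- NA
  occ <- gen_occurrences(taxon_spec("A", niche = list(bio1 = c(30, 8)),
                                    n_occurrences = 25), w, seed = 31)
  clim <- extract_climate(dedup_occurrences(occ, w), w)
  m <- fit_envelope(clim)
  vi <- variable_importance(m, w, occ, seed = 41)
  expect_equal(sum(vi), 100, tolerance = 1e-6)
  expect_lt(vi[["bio2"]], 5)
  # single-layer stacks put all weight on the only layer
  w1 <- make_small_world(n_layers = 1)
  occ1 <- gen_occurrences(taxon_spec("A", niche = list(bio1 = c(30, 8)),
                                     n_occurrences = 25), w1, seed = 32)
  m1 <- fit_envelope(extract_climate(dedup_occurrences(occ1, w1), w1))
  expect_equal(unname(variable_importance(m1, w1, occ1, seed = 1)), 100)
})

test_that("extract_climate drops duplicates and errors with nothing usable", {
  w <- make_small_world()
  rc <- arrayInd(which(w$mask)[c(10, 10, 20)], dim(w$mask))
  xy <- delimitax:::cell_center(w, rc[, 1], rc[, 2])
  occ <- occurrence_set(data.frame(taxon = "A", longitude = xy[, 1],
                                   latitude = xy[, 2]))
  clim <- extract_climate(occ, w)   # two records share a cell
  expect_equal(nrow(clim), 2L)
  far <- occurrence_set(data.frame(taxon = "A", longitude = 500,
                                   latitude = 500))
  expect_error(suppressWarnings(extract_climate(far, w)))
})
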