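test_that("generated worlds and occurrences are seed-reproducible", {
  w1 <- gen_world(world_spec(ncols = 15, nrows = 15), seed = 3)
  w2 <- gen_world(world_spec(ncols = 15, nrows = 15), seed = 3)
  expect_identical(w1$layers, w2$layers)
  sp <- niche_spec("A", 40, n = 12)
  o1 <- gen_occurrences(sp, w1, seed = 4)
  o2 <- gen_occurrences(sp, w1, seed = 4)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
  # cell-center coordinates make deduplication a no-op
  d <- dedup_occurrences(o1, w1)
  expect_equal(nrow(d), nrow(o1))
})

test_that("occurrence sampling follows the true suitability surface", {
  w <- make_small_world(seed = 8)
  sp <- taxon_spec("A", niche = list(bio1 = c(30, 5), bio2 = c(40, 8)),
                   n_occurrences = 60)
  occ <- gen_occurrences(sp, w, seed = 9)
  clim <- extract_climate(dedup_occurrences(occ, w), w)
  # sampled bio1 values concentrate near the optimum
  expect_lt(abs(median(clim[, "bio1"]) - 30), 10)
  big <- taxon_spec("A", niche = list(bio1 = c(30, 5)),
                    n_occurrences = 10 * length(w$layers$bio1))
  expect_error(gen_occurrences(big, w, seed = 1), "only")
})

test_that("character generation recovers known fixed and gapped characters", {
  mk <- function(seed) gen_characters(list(
    taxon_spec("A", n_males = 8, n_females = 7,
               discrete = c(pores = 0), continuous = list(MBS = c(50, 2)),
               meristic = "MBS"),
    taxon_spec("B", n_males = 8, n_females = 7,
               discrete = c(pores = 1), continuous = list(MBS = c(66, 2)),
               meristic = "MBS")), seed = seed)
  hits_fixed <- 0; hits_gap <- 0
  for (s in 1:20) {
    g <- mk(s)
    d <- diagnose_discrete(g$matrix, "A", "B", "pores")
    if (isTRUE(d$fixed_difference)) hits_fixed <- hits_fixed + 1
    tis <- ti_table(g$summaries)
    if (all(gap_scan(tis)$gap)) hits_gap <- hits_gap + 1
  }
  expect_equal(hits_fixed, 20)     # freq 0 vs 1 is always fixed
  expect_gte(hits_gap, 18)         # 8 sigma separation at n = 15 per taxon
  # meristic values are integers
  g <- mk(1)
  expect_true(all(g$raw$MBS == round(g$raw$MBS)))
})

test_that("equal-frequency characters are almost never spuriously fixed", {
  n_fixed <- 0
  for (s in 1:40) {
    g <- gen_characters(list(
      taxon_spec("A", n_males = 6, n_females = 6, discrete = c(ch = 0.5)),
      taxon_spec("B", n_males = 6, n_females = 6, discrete = c(ch = 0.5))),
      seed = 1000 + s)
    if (isTRUE(diagnose_discrete(g$matrix, "A", "B", "ch")$fixed_difference))
      n_fixed <- n_fixed + 1
  }
  # analytic bound: P(fixed) <= 2 * 0.5^12 per side at n = 12; over 40 seeds
  # the expected count is << 1
  expect_lte(n_fixed, 2)
})

test_that("generated trees honour discordance and reproduce exactly", {
  tr0 <- gen_tree(c(A = 4, B = 4, C = 4), discordance = 0, seed = 5)
  expect_true(all(vapply(c("A", "B", "C"),
                         function(tx) is_monophyletic(tr0, tx), logical(1))))
  t1 <- gen_tree(c(A = 4, B = 4), discordance = 0, seed = 6)
  t2 <- gen_tree(c(A = 4, B = 4), discordance = 0, seed = 6)
  expect_identical(ape::write.tree(t1$phylo), ape::write.tree(t2$phylo))
  # full discordance breaks exclusivity essentially always
  broken <- vapply(1:10, function(s) {
    tr <- gen_tree(c(A = 6, B = 6, C = 6), discordance = 1, seed = s)
    !all(vapply(c("A", "B", "C"), function(tx) is_monophyletic(tr, tx),
                logical(1)))
  }, logical(1))
  expect_gte(mean(broken), 0.9)
})

test_that("every generated dataset passes the reader validations", {
  w <- make_small_world(seed = 12, ncols = 15, nrows = 15)
  specs <- list(
    taxon_spec("A", discrete = c(ch = 0.2), continuous = list(SVL = c(50, 3)),
               niche = list(bio1 = c(30, 8), bio2 = c(40, 10)),
               n_occurrences = 12),
    taxon_spec("B", discrete = c(ch = 0.9), continuous = list(SVL = c(55, 3)),
               niche = list(bio1 = c(60, 8), bio2 = c(40, 10)),
               n_occurrences = 12))
  g <- gen_characters(specs, seed = 13)
  td <- tempfile(); dir.create(td)
  mcsv <- file.path(td, "m.csv"); acsv <- file.path(td, "a.csv")
  write_character_matrix(g$matrix, mcsv, acsv)
  expect_s3_class(read_character_matrix(mcsv, acsv), "character_matrix")
  scsv <- file.path(td, "s.csv")
  write_continuous_summary(g$summaries, scsv)
  expect_s3_class(read_continuous_summary(scsv), "data.frame")
  occ <- gen_occurrences(specs[[1]], w, seed = 14)
  ocsv <- file.path(td, "o.csv")
  write_occurrences(occ, ocsv)
  expect_equal(nrow(read_occurrences(ocsv)), 12L)
  # layers survive an .asc round trip inside the stack
  lay <- structure(list(values = w$layers$bio1, ncols = w$ncols,
                        nrows = w$nrows, xll = w$xll, yll = w$yll,
                        cellsize = w$cellsize, nodata = -9999),
                   class = "climate_layer")
  f <- file.path(td, "bio1.asc")
  write_ascii_grid(lay, f)
  expect_equal(read_ascii_grid(f)$values, w$layers$bio1, tolerance = 1e-8)
  tre <- gen_tree(specs, discordance = 0, seed = 15)
  tf <- file.path(td, "t.nwk")
  ape::write.tree(tre$phylo, tf)
  expect_s3_class(read_taxon_tree(tf, tre$assignments), "taxon_tree")
})
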