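#' Extract climate values at deduplicated occurrence cells
#'
#' @param occ An `occurrence_set` (deduplicated with
#'   [dedup_occurrences()]; if not, deduplication is applied first).
#' @param stack A [climate_stack()].
#' @return Numeric matrix, one row per retained record, one column per
#'   layer; cell row/col indices attached as attribute `cells`.
#' @export
extract_climate <- function(occ, stack) {
  cells <- attr(occ, "cells")
  if (is.null(cells)) {
    occ <- dedup_occurrences(occ, stack)
    cells <- attr(occ, "cells")
  }
  if (nrow(occ) == 0L) stop("no occurrence records on valid climate cells")
  out <- sapply(stack$layers, function(v) v[cells])
  if (nrow(occ) == 1L)
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  attr(out, "cells") <- cells
  out
}

#' Fit a percentile-clamped climate envelope
#'
#' A BIOCLIM-style presence-only suitability model. Per layer the score of
#' a value v is 1 inside the calibration percentile band
#' \[q_lower, q_upper\] of the training values, decays linearly to 0 at the
#' training minimum/maximum, and is 0 beyond; a cell's suitability is the
#' mean of its per-layer scores. Deterministic given the training matrix.
#'
#' @param training Numeric matrix of training climate values (rows =
#'   presences, columns = layers), as from [extract_climate()].
#' @param q Length-2 percentile pair, default `c(0.05, 0.95)`.
#' @return Object of class `envelope_model` with per-layer calibration
#'   (`qlo`, `qhi`, `min`, `max`).
#' @export
fit_envelope <- function(training, q = c(0.05, 0.95)) {
  training <- as.matrix(training)
  stopifnot(nrow(training) >= 5, length(q) == 2L, q[1] < q[2])
  calib <- lapply(seq_len(ncol(training)), function(j) {
    v <- training[, j]
    qs <- quantile(v, probs = q, names = FALSE)
    list(qlo = qs[1], qhi = qs[2], min = min(v), max = max(v))
  })
  names(calib) <- colnames(training)
  structure(list(calibration = calib, q = q,
                 layers = colnames(training)), class = "envelope_model")
}

#' @export
print.envelope_model <- function(x, ...) {
  cat(sprintf("Climate envelope: %d layer(s), percentile band (%g, %g)\n",
              length(x$calibration), x$q[1], x$q[2]))
  invisible(x)
}

# Piecewise-linear per-layer score; vectorized over v. Constant training
# layers score 1 within a machine tolerance of the single value.
layer_score <- function(v, cal) {
  tol <- 1e-8 * max(1, abs(cal$min))
  if (cal$max - cal$min <= tol)
    return(as.numeric(abs(v - cal$qlo) <= tol))
  s <- numeric(length(v))
  ok <- !is.na(v)
  inside <- ok & v >= cal$qlo & v <= cal$qhi
  s[inside] <- 1
  lo <- ok & v >= cal$min & v < cal$qlo
  if (cal$qlo > cal$min)
    s[lo] <- (v[lo] - cal$min) / (cal$qlo - cal$min)
  else s[lo] <- 1
  hi <- ok & v > cal$qhi & v <= cal$max
  if (cal$max > cal$qhi)
    s[hi] <- (cal$max - v[hi]) / (cal$max - cal$qhi)
  else s[hi] <- 1
  s[is.na(v)] <- NA
  s
}

# Score a climate matrix (rows = cells/records) through the model.
score_matrix <- function(model, values) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(model$calibration))
  s <- vapply(seq_len(ncol(values)),
              function(j) layer_score(values[, j], model$calibration[[j]]),
              numeric(nrow(values)))
  if (nrow(values) == 1L) s <- matrix(s, nrow = 1)
  rowMeans(s)
}

#' Predict a suitability surface over a climate stack
#'
#' @param model An [fit_envelope()] model.
#' @param stack A [climate_stack()] whose layers match the model's.
#' @return Object of class `suitability_surface`: `values` (matrix, `NA`
#'   off-mask), `mask`, `normalized` flag, and the stack geometry.
#' @export
predict_surface <- function(model, stack) {
  stopifnot(inherits(model, "envelope_model"),
            inherits(stack, "climate_stack"))
  if (!is.null(model$layers) &&
      !identical(model$layers, names(stack$layers)))
    stop("stack layers do not match model layers")
  vals <- sapply(stack$layers, as.vector)
  suit <- score_matrix(model, vals)
  m <- matrix(suit, nrow = stack$nrows, ncol = stack$ncols)
  m[!stack$mask] <- NA_real_
  structure(list(values = m, mask = stack$mask, normalized = FALSE,
                 ncols = stack$ncols, nrows = stack$nrows, xll = stack$xll,
                 yll = stack$yll, cellsize = stack$cellsize,
                 nodata = -9999), class = "suitability_surface")
}

#' Construct a suitability surface from a value matrix
#'
#' Mostly useful for testing and for loading externally computed
#' suitability grids; [predict_surface()] is the usual constructor.
#'
#' @param values Numeric matrix of non-negative suitabilities (`NA` =
#'   invalid cell), dimensions matching the stack.
#' @param stack A [climate_stack()] supplying the lattice.
#' @return A `suitability_surface`.
#' @export
suitability_surface <- function(values, stack) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == stack$nrows, ncol(values) == stack$ncols,
            all(values >= 0, na.rm = TRUE))
  mask <- stack$mask & !is.na(values)
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, normalized = FALSE,
                 ncols = stack$ncols, nrows = stack$nrows, xll = stack$xll,
                 yll = stack$yll, cellsize = stack$cellsize,
                 nodata = -9999), class = "suitability_surface")
}

#' Normalize a suitability surface to sum to one over valid cells
#'
#' @param surface A `suitability_surface`.
#' @param mask Optional logical matrix restricting the normalization
#'   domain (intersected with the surface mask).
#' @return Normalized `suitability_surface`.
#' @export
normalize_surface <- function(surface, mask = NULL) {
  m <- surface$values
  msk <- surface$mask
  if (!is.null(mask)) {
    msk <- msk & mask
    m[!msk] <- NA_real_
  }
  tot <- sum(m[msk], na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0)
    stop("cannot normalize an all-zero suitability surface")
  surface$values <- m / tot
  surface$mask <- msk
  surface$normalized <- TRUE
  surface
}

#' Schoener's D niche overlap
#'
#' \eqn{D = 1 - \frac{1}{2}\sum_i |a_i - b_i|} over per-cell suitabilities
#' normalized to sum to 1 on the shared valid mask. 0 = no overlap,
#' 1 = identical niches. Surfaces are renormalized on the intersection of
#' their masks.
#'
#' @param a,b `suitability_surface` objects on the same lattice.
#' @return D in \[0, 1\].
#' @export
schoener_D <- function(a, b) {
  if (!isTRUE(all.equal(c(a$nrows, a$ncols, a$xll, a$yll, a$cellsize),
                        c(b$nrows, b$ncols, b$xll, b$yll, b$cellsize))))
    stop("suitability surfaces are on different lattices")
  shared <- a$mask & b$mask
  a <- normalize_surface(a, shared)
  b <- normalize_surface(b, shared)
  d <- 1 - 0.5 * sum(abs(a$values[shared] - b$values[shared]))
  min(max(d, 0), 1)
}

#' Niche identity randomization test
#'
#' Tests whether two taxa's climate envelopes are identical. The observed
#' D compares envelopes fit to each taxon's deduplicated records. Each
#' pseudoreplicate pools the records of both taxa (one record per cell
#' within each pseudo-taxon), partitions the pool at random without
#' replacement into two sets of the observed sizes, refits both envelopes
#' and records D. Identity is rejected when the observed D is low relative
#' to the null distribution (one-tailed), with the add-one permutation
#' p-value \eqn{p = (1 + \#\{D_{null} \le D_{obs}\}) / (reps + 1)}.
#'
#' @param occ_a,occ_b `occurrence_set`s for the two taxa.
#' @param stack A [climate_stack()].
#' @param reps Number of pseudoreplicates (study default 100).
#' @param seed Integer seed; results are exactly reproducible given
#'   (seed, reps).
#' @param q Envelope percentile pair.
#' @return Object of class `identity_test_result`: `D_obs`, `null_Ds`,
#'   `p_value`, `reps`, `seed`, `n_a`, `n_b`.
#' @export
identity_test <- function(occ_a, occ_b, stack, reps = 100L, seed = 1L,
                          q = c(0.05, 0.95)) {
  stopifnot(reps >= 1)
  occ_a <- dedup_occurrences(occ_a, stack)
  occ_b <- dedup_occurrences(occ_b, stack)
  clim_a <- extract_climate(occ_a, stack)
  clim_b <- extract_climate(occ_b, stack)
  na <- nrow(clim_a); nb <- nrow(clim_b)
  if (na + nb < 10L) stop("pooled sample too small to fit two envelopes")
  surf <- function(clim) predict_surface(fit_envelope(clim, q), stack)
  D_obs <- schoener_D(surf(clim_a), surf(clim_b))

  # pool unique cells so pseudo-taxa never hold duplicate cells
  cells <- rbind(attr(occ_a, "cells"), attr(occ_b, "cells"))
  keep <- !duplicated(paste(cells[, 1], cells[, 2]))
  pool <- rbind(clim_a, clim_b)[keep, , drop = FALSE]
  npool <- nrow(pool)
  na_s <- min(na, npool - 5L)
  if (na_s < 5L || npool - na_s < 5L)
    stop("pooled sample too small to fit two envelopes")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  null_Ds <- vapply(seq_len(reps), function(r) {
    ia <- sample.int(npool, na_s)
    schoener_D(surf(pool[ia, , drop = FALSE]),
               surf(pool[-ia, , drop = FALSE]))
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  p <- (1 + sum(null_Ds <= D_obs)) / (reps + 1)
  structure(list(D_obs = D_obs, null_Ds = null_Ds, p_value = p,
                 reps = as.integer(reps), seed = as.integer(seed),
                 n_a = na, n_b = nb), class = "identity_test_result")
}

#' @export
print.identity_test_result <- function(x, ...) {
  cat(sprintf(
    "Niche identity test: D_obs = %.3f, p = %.4f (%d pseudoreplicates, seed %d)\n",
    x$D_obs, x$p_value, x$reps, x$seed))
  invisible(x)
}

#' Binary range map from a minimum-training-presence threshold
#'
#' The threshold is the minimum model suitability among training
#' presences, averaged over k cross-validation folds (folds assigned in
#' record order; folds with fewer than 2 presences are merged into the
#' previous fold). Suitable cells are valid cells with suitability >=
#' threshold.
#'
#' @param model An [fit_envelope()] model.
#' @param stack A [climate_stack()].
#' @param occ_train Training `occurrence_set`.
#' @param k_folds Number of folds (study default 10).
#' @return Object of class `range_map`: `suitable` (logical matrix),
#'   `threshold`, and grid geometry.
#' @export
range_map <- function(model, stack, occ_train, k_folds = 10L) {
  stopifnot(k_folds >= 1)
  clim <- extract_climate(dedup_occurrences(occ_train, stack), stack)
  scores <- score_matrix(model, clim)
  n <- length(scores)
  k <- max(1L, min(as.integer(k_folds), n))
  fold <- ((seq_len(n) - 1L) %% k) + 1L
  counts <- tabulate(fold, nbins = k)
  # merge folds with < 2 presences into the previous fold
  for (f in seq_len(k)) if (counts[f] > 0 && counts[f] < 2 && f > 1) {
    fold[fold == f] <- f - 1L
  }
  mins <- tapply(scores, fold, min)
  threshold <- mean(mins)
  surf <- predict_surface(model, stack)
  suitable <- !is.na(surf$values) & surf$values >= threshold
  structure(list(suitable = suitable, threshold = threshold,
                 ncols = stack$ncols, nrows = stack$nrows,
                 xll = stack$xll, yll = stack$yll,
                 cellsize = stack$cellsize), class = "range_map")
}

#' Are two range maps mutually exclusive?
#' @param a,b `range_map` objects on the same lattice.
#' @return TRUE iff no cell is suitable in both.
#' @export
ranges_disjoint <- function(a, b) {
  stopifnot(inherits(a, "range_map"), inherits(b, "range_map"),
            all(dim(a$suitable) == dim(b$suitable)))
  !any(a$suitable & b$suitable)
}

#' Rank-based AUC of an envelope model
#'
#' Probability that a presence scores higher than a background cell, with
#' ties counted half: estimated over all presence x background pairs via
#' the Mann-Whitney statistic.
#'
#' @param model An [fit_envelope()] model.
#' @param presences,background Climate matrices (rows = records).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(model, presences, background) {
  rank_auc(score_matrix(model, presences), score_matrix(model, background))
}

# Mann-Whitney AUC on raw score vectors (ties count half).
rank_auc <- function(sp, sb) {
  stopifnot(length(sp) >= 1, length(sb) >= 1)
  r <- rank(c(sp, sb))
  (sum(r[seq_along(sp)]) - length(sp) * (length(sp) + 1) / 2) /
    (length(sp) * length(sb))
}

# Seeded background sample of valid-cell climate values (MAXENT-style
# default: up to 10,000 cells).
background_sample <- function(stack, n = 10000L, seed = 1L) {
  idx <- which(stack$mask)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  if (length(idx) > n) idx <- sample(idx, n)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  out <- sapply(stack$layers, function(v) v[idx])
  if (length(idx) == 1L)
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  attr(out, "cells_idx") <- idx
  out
}

#' Permutation importance of climate layers
#'
#' Importance of a layer is the drop in AUC (presences vs a fixed seeded
#' background sample) when that layer's values are permuted across valid
#' cells; negative drops are truncated at zero and the result is
#' normalized to sum to 100.
#'
#' @param model An [fit_envelope()] model.
#' @param stack A [climate_stack()].
#' @param occ `occurrence_set` of presences.
#' @param seed Integer seed (drives the background sample and the
#'   permutations).
#' @param n_background Background sample size.
#' @return Named numeric vector of importances summing to 100.
#' @export
variable_importance <- function(model, stack, occ, seed = 1L,
                                n_background = 10000L) {
  pres <- extract_climate(dedup_occurrences(occ, stack), stack)
  bg <- background_sample(stack, n_background, seed)
  base <- auc(model, pres, bg)
  nl <- length(stack$layers)
  if (nl == 1L)
    return(stats::setNames(100, names(stack$layers)))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed + 1L)
  drops <- vapply(seq_len(nl), function(j) {
    permp <- pres; permb <- bg
    allv <- c(pres[, j], bg[, j])
    perm <- sample(allv)
    permp[, j] <- perm[seq_len(nrow(pres))]
    permb[, j] <- perm[-seq_len(nrow(pres))]
    base - auc(model, permp, permb)
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  drops[drops < 0] <- 0
  if (sum(drops) == 0) drops <- rep(1, nl)
  stats::setNames(100 * drops / sum(drops), names(stack$layers))
}
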