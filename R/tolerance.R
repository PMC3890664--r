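#' Howe tolerance factor for a two-sided normal tolerance interval
#'
#' Closed-form k factor of the Howe method:
#' \deqn{k = z_{(1+P)/2} \sqrt{\frac{(n-1)(1 + 1/n)}{\chi^2_{\alpha, n-1}}}}
#' where P is the population content, \eqn{\alpha = 1 - } confidence, and
#' \eqn{\chi^2_{\alpha, n-1}} is the lower \eqn{\alpha}-quantile of the
#' chi-square distribution with n - 1 degrees of freedom. Quantiles are
#' exact numerical inversions (base R), not series approximations. k is
#' monotonically decreasing in n and tends to \eqn{z_{(1+P)/2}} as
#' \eqn{n \to \infty}.
#'
#' @param n Sample size, integer >= 2.
#' @param config A two-sided [tolerance_config()].
#' @return The tolerance factor k (positive scalar).
#' @examples
#' howe_k(32)  # ~2.524 at the 95/95 default
#' @export
howe_k <- function(n, config = tolerance_config()) {
  stopifnot(inherits(config, "tolerance_config"))
  if (config$side != "two-sided")
    stop("howe_k() requires a two-sided tolerance config")
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("n must be a single integer >= 2")
  alpha <- 1 - config$confidence
  z <- qnorm((1 + config$content) / 2)
  z * sqrt((n - 1) * (1 + 1 / n) / qchisq(alpha, df = n - 1))
}

#' Two-sided normal tolerance interval (Howe method)
#'
#' Interval expected to contain at least a proportion P of a normal
#' population with the configured confidence: mean +/- k * sd with k from
#' [howe_k()].
#'
#' @param mean,sd,n Sample mean, standard deviation (>= 0) and size (>= 2).
#'   Alternatively pass a one-row continuous summary via `summary`.
#' @param summary Optional list/row with `mean`, `sd`, `n` (overrides the
#'   scalar arguments).
#' @param config A two-sided [tolerance_config()].
#' @return Object of class `tolerance_interval` with fields `lower`,
#'   `upper`, `k`, `mean`, `sd`, `n`, `config`.
#' @examples
#' normal_ti(mean = 56.8, sd = 6.1, n = 32)  # 41.4 .. 72.2
#' @export
normal_ti <- function(mean = NULL, sd = NULL, n = NULL, summary = NULL,
                      config = tolerance_config()) {
  if (!is.null(summary)) {
    mean <- summary$mean; sd <- summary$sd; n <- summary$n
  }
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  k <- howe_k(n, config)
  structure(list(lower = mean - k * sd, upper = mean + k * sd, k = k,
                 mean = mean, sd = sd, n = n, config = config),
            class = "tolerance_interval")
}

#' @export
print.tolerance_interval <- function(x, ...) {
  cat(sprintf("Normal TI (Howe, P=%g, conf=%g, n=%d): [%.4f, %.4f]  k=%.4f\n",
              x$config$content, x$config$confidence, as.integer(x$n),
              x$lower, x$upper, x$k))
  invisible(x)
}

#' One-sided Wilson score bound on a binomial proportion
#'
#' Inverts the score test at the given one-sided confidence level
#' (z at the confidence quantile, not alpha/2).
#'
#' @param x Observed successes, 0 <= x <= n.
#' @param n Sample size, >= 1.
#' @param confidence One-sided confidence level in (0, 1).
#' @param direction `"upper"` or `"lower"`.
#' @return The bound, a proportion in \[0, 1\].
#' @examples
#' wilson_bound(0, 12)                        # upper: 0.1840
#' wilson_bound(12, 12, direction = "lower")  # 0.8160
#' @export
wilson_bound <- function(x, n, confidence = 0.95,
                         direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  stopifnot(x >= 0, x <= n, confidence > 0, confidence < 1)
  z <- qnorm(confidence)
  phat <- x / n
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  b <- if (direction == "upper") centre + half else centre - half
  min(max(b, 0), 1)
}

#' One-sided binomial tolerance bound (Wilson method)
#'
#' Bounds the number of individuals carrying the focal state in a future
#' sample of size m, such that the bound holds for a proportion P of such
#' samples with the configured confidence. Two stages: a one-sided Wilson
#' confidence bound on the state proportion, then the binomial quantile of
#' a future sample at that bounded proportion. For `direction = "upper"`
#' the count bound is the smallest c with
#' \eqn{F(c; m, p_{bound}) \ge P}; for `"lower"` it is the largest c with
#' \eqn{1 - F(c - 1; m, p_{bound}) \ge P} (the (1-P)-quantile).
#'
#' @param x Observed count with the focal state.
#' @param n Observed sample size.
#' @param m Future-sample size (defaults to n).
#' @param config A one-sided or default [tolerance_config()]; `content` is
#'   P, `confidence` drives the Wilson stage.
#' @param direction `"upper"` or `"lower"`.
#' @return Object of class `binomial_tolerance_bound` with `x`, `n`, `m`,
#'   `p_bound`, `count_bound`, `proportion_bound`, `direction`, `config`.
#' @examples
#' binomial_tolerance_bound(0, 12)  # count_bound 5 of m = 12 (41.7%)
#' @export
binomial_tolerance_bound <- function(x, n, m = n,
                                     config = tolerance_config(side = "one-sided"),
                                     direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  stopifnot(inherits(config, "tolerance_config"), m >= 1)
  p_bound <- wilson_bound(x, n, config$confidence, direction)
  P <- config$content
  count_bound <- if (direction == "upper") {
    # smallest c with CDF(c; m, p_bound) >= P
    which(pbinom(0:m, m, p_bound) >= P)[1L] - 1L
  } else {
    qbinom(1 - P, m, p_bound)
  }
  structure(list(x = x, n = n, m = as.integer(m), p_bound = p_bound,
                 count_bound = as.integer(count_bound),
                 proportion_bound = count_bound / m,
                 direction = direction, config = config),
            class = "binomial_tolerance_bound")
}

#' @export
print.binomial_tolerance_bound <- function(x, ...) {
  cat(sprintf(
    "Binomial tolerance bound (Wilson, %s): x=%d/%d, m=%d -> p_bound=%.4f, count<=%d (%.1f%%)\n",
    x$direction, x$x, x$n, x$m, x$p_bound, x$count_bound,
    100 * x$proportion_bound))
  invisible(x)
}

#' Diagnose a discrete character between two taxa
#'
#' A character is a fixed difference when the two taxa's observed state
#' sets are disjoint and non-empty (every scored individual of one taxon
#' shows one state, every scored individual of the other shows the other).
#' When fixed, a one-sided upper binomial tolerance bound quantifies, per
#' taxon, how large a share of a future sample could still carry the
#' (unobserved) alternative state.
#'
#' @param matrix A [character_matrix()].
#' @param taxon_a,taxon_b Taxon labels present in the matrix.
#' @param character Character (column) name.
#' @param config A [tolerance_config()] for the caveat bounds.
#' @param m Future-sample size for the caveat bound; `NULL` = each taxon's
#'   own scored n.
#' @return Object of class `discrete_diagnosis`: `character`, `states`
#'   (per-taxon observed state sets), `n` (per-taxon scored individuals),
#'   `fixed_difference` (logical, `NA` when either taxon has no scored
#'   individuals), `caveat_bounds` (per-taxon proportion, `NA` when not
#'   fixed).
#' @export
diagnose_discrete <- function(matrix, taxon_a, taxon_b, character,
                              config = tolerance_config(side = "one-sided"),
                              m = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (!character %in% matrix$characters$name)
    stop("unknown character: ", character)
  sub <- applicable_states(matrix, character)
  states <- lapply(c(a = taxon_a, b = taxon_b), function(tx) {
    v <- sub$state[sub$taxon == tx]
    v[!is.na(v)]
  })
  n <- vapply(states, length, integer(1))
  sets <- lapply(states, function(v) sort(unique(v)))
  res <- list(character = character, taxa = c(taxon_a, taxon_b),
              states = sets, n = n,
              fixed_difference = NA,
              caveat_bounds = c(a = NA_real_, b = NA_real_))
  if (any(n == 0L)) {
    class(res) <- "discrete_diagnosis"
    return(res)  # not assessed
  }
  fixed <- length(intersect(sets$a, sets$b)) == 0L &&
    length(sets$a) > 0L && length(sets$b) > 0L
  res$fixed_difference <- fixed
  if (fixed) {
    res$caveat_bounds <- vapply(c("a", "b"), function(k) {
      mm <- if (is.null(m)) n[[k]] else m
      binomial_tolerance_bound(0L, n[[k]], mm, config,
                               direction = "upper")$proportion_bound
    }, numeric(1))
  }
  class(res) <- "discrete_diagnosis"
  res
}

#' @export
print.discrete_diagnosis <- function(x, ...) {
  cat(sprintf("Character '%s': %s vs %s -> %s\n", x$character,
              x$taxa[1], x$taxa[2],
              if (is.na(x$fixed_difference)) "not assessed"
              else if (x$fixed_difference) "FIXED difference" else "not fixed"))
  if (isTRUE(x$fixed_difference))
    cat(sprintf("  alternative-state caveat: up to %.1f%% (%s), %.1f%% (%s)\n",
                100 * x$caveat_bounds[["a"]], x$taxa[1],
                100 * x$caveat_bounds[["b"]], x$taxa[2]))
  invisible(x)
}

#' Gap between two tolerance intervals
#'
#' TRUE iff the closed intervals are disjoint; intervals sharing an
#' endpoint count as overlapping (conservative: no gap).
#'
#' @param ti_a,ti_b Objects from [normal_ti()].
#' @return Logical.
#' @export
detect_gap <- function(ti_a, ti_b) {
  stopifnot(inherits(ti_a, "tolerance_interval"),
            inherits(ti_b, "tolerance_interval"))
  ti_a$upper < ti_b$lower || ti_b$upper < ti_a$lower
}

#' Tolerance intervals for a table of continuous summaries
#'
#' Applies [normal_ti()] to every row of a continuous summary table
#' (columns `taxon`, `character`, `mean`, `sd`, `n`).
#'
#' @param summaries Data frame from [read_continuous_summary()].
#' @param config A two-sided [tolerance_config()].
#' @return Long-format data frame: taxon, character, mean, sd, n, k, lower,
#'   upper.
#' @export
ti_table <- function(summaries, config = tolerance_config()) {
  stopifnot(all(c("taxon", "character", "mean", "sd", "n") %in%
                  names(summaries)))
  out <- summaries[, c("taxon", "character", "mean", "sd", "n")]
  tis <- lapply(seq_len(nrow(out)), function(i)
    normal_ti(summary = out[i, ], config = config))
  out$k <- vapply(tis, `[[`, numeric(1), "k")
  out$lower <- vapply(tis, `[[`, numeric(1), "lower")
  out$upper <- vapply(tis, `[[`, numeric(1), "upper")
  out
}

#' Render a tolerance-interval table in wide report format
#'
#' Characters as rows, taxa as columns, cells as `"lower-upper"` strings
#' rounded to one decimal (half away from zero), mirroring the layout of
#' published tolerance-interval tables.
#'
#' @param tis Output of [ti_table()].
#' @return Data frame with a `character` column and one column per taxon.
#' @export
ti_wide_table <- function(tis) {
  taxa <- sort(unique(tis$taxon))
  chars <- unique(tis$character)
  out <- data.frame(character = chars, stringsAsFactors = FALSE)
  for (tx in taxa) {
    out[[tx]] <- vapply(chars, function(ch) {
      r <- tis[tis$taxon == tx & tis$character == ch, ]
      if (nrow(r) == 0) return(NA_character_)
      sprintf("%.1f-%.1f", round_half_up(r$lower[1]),
              round_half_up(r$upper[1]))
    }, character(1))
  }
  out
}

#' Diagnose every character for every pair of taxa
#'
#' Applies [diagnose_discrete()] across all unordered taxon pairs and all
#' characters of a matrix.
#'
#' @param matrix A [character_matrix()].
#' @param config A [tolerance_config()] for the caveat bounds.
#' @param m Future-sample size (`NULL` = per-taxon n).
#' @param characters Optional subset of character names.
#' @return Data frame: character, taxon_a, taxon_b, n_a, n_b, fixed
#'   (logical, `NA` = not assessed), caveat_a, caveat_b (proportions).
#' @export
diagnosis_table <- function(matrix,
                            config = tolerance_config(side = "one-sided"),
                            m = NULL, characters = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  taxa <- sort(unique(matrix$individuals$taxon))
  chars <- characters %||% matrix$characters$name
  out <- list()
  for (ch in chars) for (i in seq_len(length(taxa) - 1))
    for (j in seq(i + 1, length(taxa))) {
      d <- diagnose_discrete(matrix, taxa[i], taxa[j], ch, config, m)
      out[[length(out) + 1L]] <- data.frame(
        character = ch, taxon_a = taxa[i], taxon_b = taxa[j],
        n_a = d$n[["a"]], n_b = d$n[["b"]], fixed = d$fixed_difference,
        caveat_a = d$caveat_bounds[["a"]], caveat_b = d$caveat_bounds[["b"]],
        stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}

#' Scan a tolerance-interval table for morphological gaps
#'
#' For every character and every unordered pair of taxa, tests whether the
#' two tolerance intervals are disjoint.
#'
#' @param tis Output of [ti_table()].
#' @return Data frame: character, taxon_a, taxon_b, gap (logical).
#' @export
gap_scan <- function(tis) {
  out <- list()
  for (ch in unique(tis$character)) {
    sub <- tis[tis$character == ch, ]
    taxa <- sort(unique(sub$taxon))
    if (length(taxa) < 2) next
    for (i in seq_len(length(taxa) - 1)) for (j in seq(i + 1, length(taxa))) {
      a <- sub[sub$taxon == taxa[i], ][1, ]
      b <- sub[sub$taxon == taxa[j], ][1, ]
      gap <- a$upper < b$lower || b$upper < a$lower
      out[[length(out) + 1L]] <- data.frame(
        character = ch, taxon_a = taxa[i], taxon_b = taxa[j], gap = gap,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
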