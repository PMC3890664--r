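#' Tolerance-interval configuration
#'
#' Bundles the two probabilities that govern every tolerance computation:
#' the population content P (the proportion of the population the interval
#' or bound must cover) and the confidence level 1 - alpha with which that
#' coverage is achieved. The study default is P = 0.95 at 95% confidence.
#'
#' @param content Proportion in (0, 1): population content P.
#' @param confidence Proportion in (0, 1): confidence level 1 - alpha.
#' @param side `"two-sided"` (normal tolerance intervals) or `"one-sided"`
#'   (binomial tolerance bounds).
#' @return An object of class `tolerance_config`.
#' @examples
#' tolerance_config()                    # 95% content, 95% confidence
#' tolerance_config(side = "one-sided")
#' @export
tolerance_config <- function(content = 0.95, confidence = 0.95,
                             side = c("two-sided", "one-sided")) {
  side <- match.arg(side)
  stopifnot(is.numeric(content), length(content) == 1L,
            content > 0, content < 1,
            is.numeric(confidence), length(confidence) == 1L,
            confidence > 0, confidence < 1)
  structure(list(content = content, confidence = confidence, side = side),
            class = "tolerance_config")
}

#' @export
print.tolerance_config <- function(x, ...) {
  cat(sprintf("Tolerance config: content P = %g, confidence = %g (%s)\n",
              x$content, x$confidence, x$side))
  invisible(x)
}

#' Delimitation decision rule configuration
#'
#' Parameters of the rule that converts per-pair evidence into a verdict.
#' A pair is delimited when (a) both taxa are exclusive on the gene tree
#' (or monophyly is unassessed / not required) and (b) at least
#' `min_corroborating_lines` of the three corroborating lines hold:
#' a fixed discrete difference, a continuous-character gap, or rejection of
#' niche identity at `alpha_identity`.
#'
#' @param require_monophyly Gate verdicts on reciprocal exclusivity when a
#'   tree is supplied (default `TRUE`).
#' @param min_corroborating_lines Integer in 1..3; minimum count of
#'   corroborating evidence lines (default 1, the conservative
#'   count-the-fixed-differences reading).
#' @param alpha_identity Significance level for the niche identity test.
#' @param report_caveats Print binomial caveat bounds in reports.
#' @param m_future Future-sample size for binomial tolerance bounds, or
#'   `NULL` to use each taxon's own sample size.
#' @param identity_reps Pseudoreplicates for the niche identity test.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(require_monophyly = TRUE,
                            min_corroborating_lines = 1L,
                            alpha_identity = 0.05,
                            report_caveats = TRUE,
                            m_future = NULL,
                            identity_reps = 100L) {
  min_corroborating_lines <- as.integer(min_corroborating_lines)
  stopifnot(min_corroborating_lines >= 1L, min_corroborating_lines <= 3L,
            alpha_identity > 0, alpha_identity < 1,
            is.null(m_future) || (is.numeric(m_future) && m_future >= 1))
  structure(list(require_monophyly = isTRUE(require_monophyly),
                 min_corroborating_lines = min_corroborating_lines,
                 alpha_identity = alpha_identity,
                 report_caveats = isTRUE(report_caveats),
                 m_future = if (is.null(m_future)) NULL else as.integer(m_future),
                 identity_reps = as.integer(identity_reps)),
            class = "decision_config")
}

#' Read a pipeline configuration file
#'
#' A single YAML file holds the tolerance settings, the decision rule, niche
#' settings and seeds. Missing sections fall back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `tolerance` (a [tolerance_config()]),
#'   `decision` (a [decision_config()]), and `seed` (integer or `NULL`).
#' @export
read_delimit_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  tol <- do.call(tolerance_config, as.list(raw$tolerance %||% list()))
  dec <- do.call(decision_config, as.list(raw$decision %||% list()))
  list(tolerance = tol, decision = dec,
       seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Report rounding used in rendered tables: half away from zero, one decimal,
# mirroring the source tables (base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
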