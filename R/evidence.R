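#' Assemble all lines of evidence into a per-pair evidence table
#'
#' For every unordered pair of taxa shared across the supplied sources,
#' collects: fixed discrete differences (with binomial caveat bounds),
#' continuous-character gaps from tolerance intervals, niche statistics
#' (Schoener's D, identity-test p, range-overlap flag) and per-taxon
#' monophyly flags. Any source may be `NULL`; its fields are then marked
#' not-assessed (`NA`). Verdicts are attached with [decide()].
#'
#' @param matrix Optional [character_matrix()].
#' @param summaries Optional continuous summary data frame.
#' @param tolerance A [tolerance_config()] (used two-sided for intervals,
#'   one-sided for binomial bounds).
#' @param occs Optional named list of `occurrence_set`s (names = taxa).
#' @param stack Optional [climate_stack()] (required with `occs`).
#' @param tree Optional [taxon_tree()].
#' @param decision A [decision_config()].
#' @param seed Integer seed for the identity tests.
#' @return Object of class `evidence_table`: data frame with one row per
#'   pair plus a `details` attribute holding per-pair diagnosis lists.
#' @export
build_evidence <- function(matrix = NULL, summaries = NULL,
                           tolerance = tolerance_config(),
                           occs = NULL, stack = NULL, tree = NULL,
                           decision = decision_config(), seed = 1L) {
  sources <- list()
  if (!is.null(matrix)) sources$discrete <- unique(matrix$individuals$taxon)
  if (!is.null(summaries)) sources$continuous <- unique(summaries$taxon)
  if (!is.null(occs)) {
    stopifnot(!is.null(stack))
    sources$niche <- names(occs)
  }
  if (!is.null(tree)) sources$tree <- unique(tree$assignments$taxon)
  if (length(sources) == 0L) stop("at least one evidence source is required")
  taxa <- sort(unique(unlist(sources)))
  in_all <- Reduce(intersect, sources)
  if (length(in_all) == 0L && length(sources) > 1L)
    stop("no taxa shared across the supplied evidence sources")

  tol1 <- tolerance_config(tolerance$content, tolerance$confidence,
                           side = "one-sided")
  tis <- if (!is.null(summaries)) ti_table(summaries, tolerance) else NULL
  mono <- if (!is.null(tree))
    stats::setNames(vapply(taxa, function(tx)
      if (tx %in% sources$tree) is_monophyletic(tree, tx) else NA,
      logical(1)), taxa) else stats::setNames(rep(NA, length(taxa)), taxa)

  # niche machinery per pair (envelopes refit per taxon once)
  niche_ok <- function(tx) !is.null(occs) && tx %in% names(occs)
  models <- list(); ranges <- list()
  if (!is.null(occs)) {
    for (tx in intersect(taxa, names(occs))) {
      clim <- extract_climate(dedup_occurrences(occs[[tx]], stack), stack)
      models[[tx]] <- fit_envelope(clim)
      ranges[[tx]] <- range_map(models[[tx]], stack, occs[[tx]])
    }
  }

  pairs <- utils::combn(taxa, 2)
  details <- list()
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    key <- paste(a, b, sep = " | ")
    det <- list()

    fixed <- NA_integer_; fixed_chars <- NA_character_
    if (!is.null(matrix) &&
        all(c(a, b) %in% matrix$individuals$taxon)) {
      dd <- lapply(matrix$characters$name, function(ch)
        diagnose_discrete(matrix, a, b, ch, tol1,
                          m = decision$m_future))
      names(dd) <- matrix$characters$name
      det$discrete <- dd
      fx <- vapply(dd, function(d) isTRUE(d$fixed_difference), logical(1))
      fixed <- sum(fx)
      fixed_chars <- if (fixed > 0) paste(names(dd)[fx], collapse = ";")
        else ""
    }

    gaps <- NA_integer_; gap_chars <- NA_character_
    if (!is.null(tis) && all(c(a, b) %in% tis$taxon)) {
      gs <- gap_scan(tis[tis$taxon %in% c(a, b), ])
      det$gaps <- gs
      gaps <- sum(gs$gap)
      gap_chars <- if (gaps > 0) paste(gs$character[gs$gap], collapse = ";")
        else ""
    }

    D <- NA_real_; p_id <- NA_real_; disjoint <- NA
    if (niche_ok(a) && niche_ok(b)) {
      it <- identity_test(occs[[a]], occs[[b]], stack,
                          reps = decision$identity_reps,
                          seed = seed + p)
      det$identity <- it
      D <- it$D_obs; p_id <- it$p_value
      disjoint <- ranges_disjoint(ranges[[a]], ranges[[b]])
    }

    details[[key]] <<- det
    data.frame(taxon_a = a, taxon_b = b,
               monophyly_a = mono[[a]], monophyly_b = mono[[b]],
               n_fixed_discrete = fixed, fixed_characters = fixed_chars,
               n_gaps = gaps, gap_characters = gap_chars,
               schoener_D = D, p_identity = p_id,
               ranges_disjoint = disjoint, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$verdict <- vapply(seq_len(nrow(tab)),
                        function(i) decide(tab[i, ], decision), character(1))
  structure(tab, details = details, decision = decision,
            class = c("evidence_table", "data.frame"))
}

#' Delimitation verdict for one evidence row
#'
#' The three corroborating lines are: at least one fixed discrete
#' difference, at least one continuous-character gap, and rejection of
#' niche identity at `alpha_identity`. The verdict is `"delimited"` when
#' the monophyly gate passes (both taxa exclusive, or monophyly
#' not assessed, or `require_monophyly = FALSE`) and at least
#' `min_corroborating_lines` lines hold; `"insufficient"` when every line
#' is unassessed; otherwise `"not-delimited"`. Pure function of the row
#' and config.
#'
#' @param row One row of an `evidence_table` (or a list with the same
#'   fields).
#' @param config A [decision_config()].
#' @return `"delimited"`, `"not-delimited"` or `"insufficient"`.
#' @export
decide <- function(row, config = decision_config()) {
  lines <- c(discrete = if (is.na(row$n_fixed_discrete)) NA
               else row$n_fixed_discrete > 0,
             gap = if (is.na(row$n_gaps)) NA else row$n_gaps > 0,
             niche = if (is.na(row$p_identity)) NA
               else row$p_identity <= config$alpha_identity)
  if (all(is.na(lines))) return("insufficient")
  gate <- TRUE
  if (config$require_monophyly) {
    # an assessed non-exclusive taxon blocks the pair; unassessed passes
    if ((!is.na(row$monophyly_a) && !isTRUE(row$monophyly_a)) ||
        (!is.na(row$monophyly_b) && !isTRUE(row$monophyly_b)))
      gate <- FALSE
  }
  corroborating <- sum(lines, na.rm = TRUE)
  if (gate && corroborating >= config$min_corroborating_lines)
    "delimited" else "not-delimited"
}

#' Render an evidence table to TSV or markdown
#'
#' @param evidence An `evidence_table` from [build_evidence()].
#' @param path Output file path.
#' @param format `"tsv"` (machine-readable, round-trips through
#'   `read.delim`) or `"markdown"` (per-pair evidence lists).
#' @return `path`, invisibly.
#' @export
render_report <- function(evidence, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(evidence, "evidence_table"))
  config <- attr(evidence, "decision") %||% decision_config()
  if (format == "tsv") {
    write.table(as.data.frame(evidence), path, sep = "\t",
                row.names = FALSE, quote = FALSE, na = "NA")
    return(invisible(path))
  }
  details <- attr(evidence, "details")
  lines <- c("# Species delimitation evidence", "")
  for (i in seq_len(nrow(evidence))) {
    r <- evidence[i, ]
    key <- paste(r$taxon_a, r$taxon_b, sep = " | ")
    lines <- c(lines, sprintf("## %s vs %s — **%s**", r$taxon_a, r$taxon_b,
                              r$verdict), "")
    lines <- c(lines, sprintf("- Monophyly: %s / %s",
                              fmt_flag(r$monophyly_a), fmt_flag(r$monophyly_b)))
    if (!is.na(r$n_fixed_discrete)) {
      lines <- c(lines, sprintf("- Fixed discrete differences: %d%s",
                                r$n_fixed_discrete,
                                if (r$n_fixed_discrete > 0)
                                  paste0(" (", r$fixed_characters, ")") else ""))
      if (config$report_caveats && r$n_fixed_discrete > 0) {
        dd <- details[[key]]$discrete
        for (d in dd) if (isTRUE(d$fixed_difference))
          lines <- c(lines, sprintf(
            "    - %s: alternative state possible in up to %s%% (%s) and %s%% (%s) of future samples",
            d$character,
            format(round_half_up(100 * d$caveat_bounds[["a"]]), nsmall = 1),
            d$taxa[1],
            format(round_half_up(100 * d$caveat_bounds[["b"]]), nsmall = 1),
            d$taxa[2]))
      }
    } else lines <- c(lines, "- Fixed discrete differences: not assessed")
    lines <- c(lines,
               if (is.na(r$n_gaps)) "- Continuous gaps: not assessed"
               else sprintf("- Continuous gaps: %d%s", r$n_gaps,
                            if (r$n_gaps > 0)
                              paste0(" (", r$gap_characters, ")") else ""))
    lines <- c(lines,
               if (is.na(r$schoener_D)) "- Niche: not assessed"
               else sprintf(
                 "- Niche: D = %.3f, identity-test p = %.4f, ranges %s",
                 r$schoener_D, r$p_identity,
                 if (isTRUE(r$ranges_disjoint)) "disjoint" else "overlapping"))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

fmt_flag <- function(x) {
  if (is.na(x)) "not assessed" else if (isTRUE(x)) "monophyletic"
  else "non-monophyletic"
}
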