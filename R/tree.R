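#' Read a rooted tree with tip-to-taxon assignments
#'
#' The tree is consumed as supplied (typically rooted on an outgroup); no
#' re-rooting is attempted. Every tip must map to exactly one taxon.
#'
#' @param path Newick file path, or an `ape::phylo` object.
#' @param assignments Two-column data frame (`tip`, `taxon`) or path to
#'   such a CSV.
#' @return Object of class `taxon_tree`: list with `phylo` and
#'   `assignments`.
#' @export
read_taxon_tree <- function(path, assignments) {
  phy <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick tree")
  if (is.character(assignments) && length(assignments) == 1L)
    assignments <- read.csv(assignments, stringsAsFactors = FALSE)
  stopifnot(all(c("tip", "taxon") %in% names(assignments)))
  taxon_tree(phy, assignments)
}

#' @rdname read_taxon_tree
#' @param phylo An `ape::phylo` tree with named tips.
#' @export
taxon_tree <- function(phylo, assignments) {
  stopifnot(inherits(phylo, "phylo"))
  miss <- setdiff(phylo$tip.label, assignments$tip)
  if (length(miss)) stop("tip lacking a taxon assignment: ", miss[1])
  if (anyDuplicated(assignments$tip))
    stop("tip assigned to more than one taxon: ",
         assignments$tip[duplicated(assignments$tip)][1])
  assignments <- assignments[assignments$tip %in% phylo$tip.label, ]
  if (length(unique(assignments$taxon)) < 2)
    stop("need at least 2 taxa on the tree")
  structure(list(phylo = phylo,
                 assignments = assignments[, c("tip", "taxon")]),
            class = "taxon_tree")
}

#' @export
print.taxon_tree <- function(x, ...) {
  cat(sprintf("Taxon tree: %d tips, %d taxa\n",
              length(x$phylo$tip.label),
              length(unique(x$assignments$taxon))))
  invisible(x)
}

taxon_tips <- function(tree, taxon) {
  tips <- tree$assignments$tip[tree$assignments$taxon == taxon]
  if (length(tips) == 0L) stop("unknown taxon: ", taxon)
  tips
}

#' Is a taxon's tip set exclusive (monophyletic) on the rooted tree?
#'
#' TRUE iff the smallest clade containing all the taxon's tips contains no
#' other tips. Single-tip taxa are trivially monophyletic.
#'
#' @param tree A [taxon_tree()].
#' @param taxon Taxon label.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, taxon) {
  stopifnot(inherits(tree, "taxon_tree"))
  tips <- taxon_tips(tree, taxon)
  if (length(tips) == 1L) return(TRUE)
  phy <- tree$phylo
  if (length(tips) == length(phy$tip.label)) return(TRUE)
  mrca <- ape::getMRCA(phy, tips)
  clade <- ape::extract.clade(phy, mrca)$tip.label
  length(clade) == length(tips)
}

#' Discover candidate taxa from tree exclusivity
#'
#' Flags each taxon as a candidate species when its tips form an exclusive
#' clade (and, optionally, when the clade's support label meets
#' `min_support`). Support labels are parsed from node labels and
#' auto-detected as proportions (0-1) or percentages (0-100).
#'
#' @param tree A [taxon_tree()].
#' @param min_support Optional support threshold on the 0-1 scale.
#' @return Data frame: taxon, tip_count, monophyletic, single_tip, support
#'   (`NA` when unlabeled), candidate.
#' @export
discover_candidates <- function(tree, min_support = NULL) {
  stopifnot(inherits(tree, "taxon_tree"))
  taxa <- sort(unique(tree$assignments$taxon))
  phy <- tree$phylo
  supports <- parse_support(phy)
  rows <- lapply(taxa, function(tx) {
    tips <- taxon_tips(tree, tx)
    mono <- is_monophyletic(tree, tx)
    sup <- NA_real_
    if (mono && length(tips) >= 2L && length(tips) < length(phy$tip.label)) {
      node <- ape::getMRCA(phy, tips)
      sup <- supports[node - length(phy$tip.label)]
    }
    cand <- mono && (is.null(min_support) || (!is.na(sup) && sup >= min_support))
    data.frame(taxon = tx, tip_count = length(tips), monophyletic = mono,
               single_tip = length(tips) == 1L, support = sup,
               candidate = cand, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Node support labels on the 0-1 scale; percentages (any value > 1)
# auto-detected and rescaled.
parse_support <- function(phy) {
  if (is.null(phy$node.label)) return(rep(NA_real_, phy$Nnode))
  sup <- suppressWarnings(as.numeric(phy$node.label))
  if (any(sup > 1, na.rm = TRUE)) sup <- sup / 100
  sup
}
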