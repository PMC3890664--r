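#' Paths to packaged example data
#'
#' The package ships plain-text fixtures encoding the published data
#' tables of the *Liolaemus walkeri* species complex study system:
#'
#' * `walkeri_complex_table1.csv` — individual-level binary character
#'   matrix (17 characters, 184 adults of five taxa), reconstructed from
#'   the per-taxon/per-sex state summary; polymorphic cells are encoded
#'   with both states present. `walkeri_complex_characters.csv` carries
#'   the applicability flags (precloacal pores, melanistic belly and
#'   ringed ventral tail are scored on adult males only).
#' * `walkeri_complex_meristic.csv` / `walkeri_complex_morphometric.csv`
#'   — per taxon x character mean, SD and the sample size used at the
#'   tolerance-interval stage (which differs by one or a few individuals
#'   from the descriptive-table n for two taxa; the explicit `n` column
#'   is authoritative).
#' * `synthetic_haplotype_tree.nwk` + `synthetic_tree_assignments.csv` —
#'   a small constructed newick stand-in encoding the published ingroup
#'   topology (per-taxon haplotype clades with support labels); synthetic,
#'   not the inferred tree itself.
#'
#' @param file Fixture file name; omit to list available fixtures.
#' @return A file path (or a vector of file names).
#' @examples
#' delimitax_example()
#' read_continuous_summary(delimitax_example("walkeri_complex_meristic.csv"))
#' @export
delimitax_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "delimitax")))
  path <- system.file("extdata", file, package = "delimitax")
  if (path == "") stop("no packaged fixture named '", file, "'")
  path
}

#' Load all walkeri-complex fixtures at once
#'
#' @return List with `matrix` (a [character_matrix()]), `meristic` and
#'   `morphometric` (continuous summary data frames) and `tree`
#'   (a [taxon_tree()]).
#' @export
load_walkeri_fixtures <- function() {
  list(
    matrix = read_character_matrix(
      delimitax_example("walkeri_complex_table1.csv"),
      delimitax_example("walkeri_complex_characters.csv")),
    meristic = read_continuous_summary(
      delimitax_example("walkeri_complex_meristic.csv")),
    morphometric = read_continuous_summary(
      delimitax_example("walkeri_complex_morphometric.csv")),
    tree = read_taxon_tree(
      delimitax_example("synthetic_haplotype_tree.nwk"),
      delimitax_example("synthetic_tree_assignments.csv")))
}
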