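#' Construct a discrete character matrix
#'
#' Individuals x binary characters with taxon/sex/age metadata. States are
#' 0, 1 or `NA` (missing). Each character carries an applicability flag:
#' `"all"`, `"adults-only"` or `"adult-males-only"`; individuals outside a
#' character's applicability are treated as missing when states are
#' retrieved, so sex/age stratification happens at the data layer, not
#' inside the statistics.
#'
#' @param individuals Data frame with columns `id` (unique), `taxon`,
#'   `sex` (`male`/`female`/`unknown`), `age_class`
#'   (`adult`/`juvenile`/`unknown`).
#' @param states Integer matrix (rows = individuals, columns = characters)
#'   with values 0, 1 or `NA`; column names are character names.
#' @param applicability Named character vector (or data frame with columns
#'   `character`, `applicability`) mapping character names to flags;
#'   unnamed characters default to `"all"`.
#' @return Object of class `character_matrix`.
#' @export
character_matrix <- function(individuals, states, applicability = NULL) {
  req <- c("id", "taxon", "sex", "age_class")
  stopifnot(is.data.frame(individuals), all(req %in% names(individuals)))
  if (anyDuplicated(individuals$id))
    stop("duplicate individual id: ",
         individuals$id[duplicated(individuals$id)][1])
  if (nrow(individuals) == 0L) stop("empty character matrix (no individuals)")
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (nrow(states) != nrow(individuals))
    stop("states has ", nrow(states), " rows but there are ",
         nrow(individuals), " individuals")
  bad <- !(is.na(states) | states %in% c(0L, 1L))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid state at individual '%s', character '%s'",
                 individuals$id[w[1]], colnames(states)[w[2]]))
  }
  if (is.data.frame(applicability))
    applicability <- stats::setNames(applicability$applicability,
                                     applicability$character)
  app <- rep("all", ncol(states))
  names(app) <- colnames(states)
  if (!is.null(applicability)) {
    unknown <- setdiff(names(applicability), colnames(states))
    if (length(unknown))
      stop("applicability given for unknown character: ", unknown[1])
    ok <- c("all", "adults-only", "adult-males-only")
    if (!all(applicability %in% ok))
      stop("applicability flags must be one of: ", paste(ok, collapse = ", "))
    app[names(applicability)] <- applicability
  }
  structure(list(
    individuals = individuals[, req],
    characters = data.frame(name = colnames(states), applicability = app,
                            row.names = NULL, stringsAsFactors = FALSE),
    states = states), class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d individuals x %d characters, %d taxa\n",
              nrow(x$states), ncol(x$states),
              length(unique(x$individuals$taxon))))
  invisible(x)
}

# States for one character after the applicability filter; returns a data
# frame (taxon, state) aligned to individuals, NA where inapplicable.
applicable_states <- function(matrix, character) {
  i <- match(character, matrix$characters$name)
  app <- matrix$characters$applicability[i]
  st <- matrix$states[, i]
  ind <- matrix$individuals
  keep <- switch(app,
    "all" = rep(TRUE, nrow(ind)),
    "adults-only" = ind$age_class == "adult",
    "adult-males-only" = ind$age_class == "adult" & ind$sex == "male")
  st[!keep] <- NA_integer_
  data.frame(taxon = ind$taxon, state = st, stringsAsFactors = FALSE)
}

#' Subset a character matrix by individual metadata
#'
#' @param matrix A [character_matrix()].
#' @param sex,age_class Optional values to keep.
#' @return A [character_matrix()] restricted to the matching individuals.
#' @export
subset_matrix <- function(matrix, sex = NULL, age_class = NULL) {
  keep <- rep(TRUE, nrow(matrix$individuals))
  if (!is.null(sex)) keep <- keep & matrix$individuals$sex %in% sex
  if (!is.null(age_class))
    keep <- keep & matrix$individuals$age_class %in% age_class
  character_matrix(matrix$individuals[keep, , drop = FALSE],
                   matrix$states[keep, , drop = FALSE],
                   stats::setNames(matrix$characters$applicability,
                                   matrix$characters$name))
}

#' Read a discrete character matrix from CSV
#'
#' Expects columns `id`, `taxon`, `sex`, `age_class`, then one column per
#' character holding 0, 1 or missing (`NA`, any case, or empty). An
#' optional companion CSV (`character`, `applicability`) supplies
#' applicability flags.
#'
#' @param path CSV path.
#' @param applicability_path Optional companion CSV path.
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(path, applicability_path = NULL) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("id", "taxon", "sex", "age_class")
  if (!all(req %in% names(df)))
    stop("character matrix CSV must have columns: ",
         paste(req, collapse = ", "))
  if (nrow(df) == 0L) stop("character matrix CSV has no data rows")
  chars <- setdiff(names(df), req)
  if (length(chars) == 0L) stop("character matrix CSV has no character columns")
  states <- sapply(chars, function(ch) {
    v <- trimws(df[[ch]])
    v[toupper(v) == "NA" | v == ""] <- NA
    bad <- !is.na(v) & !v %in% c("0", "1")
    if (any(bad))
      stop(sprintf("malformed state '%s' at row %d, column '%s'",
                   v[bad][1], which(bad)[1], ch))
    as.integer(v)
  })
  if (length(chars) == 1L) states <- matrix(states, ncol = 1,
                                            dimnames = list(NULL, chars))
  app <- NULL
  if (!is.null(applicability_path)) {
    ac <- read.csv(applicability_path, stringsAsFactors = FALSE)
    app <- stats::setNames(ac$applicability, ac$character)
  }
  character_matrix(df[, req], states, app)
}

#' Write a character matrix to CSV
#'
#' Inverse of [read_character_matrix()]; missing states are written as
#' `NA`.
#'
#' @param matrix A [character_matrix()].
#' @param path Output CSV path.
#' @param applicability_path Optional path for the companion applicability
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(matrix, path, applicability_path = NULL) {
  df <- cbind(matrix$individuals, as.data.frame(matrix$states))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(applicability_path)) {
    app <- data.frame(character = matrix$characters$name,
                      applicability = matrix$characters$applicability)
    write.csv(app, applicability_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a continuous character summary table
#'
#' Columns `taxon`, `character`, `mean`, `sd`, `n`: one row per
#' taxon x character. The sample size n is always read from the explicit
#' column, never inferred.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_continuous_summary <- function(path) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("taxon", "character", "mean", "sd", "n")
  if (!all(req %in% names(df)))
    stop("continuous summary CSV must have columns: ",
         paste(req, collapse = ", "))
  validate_continuous_summary(df)
}

validate_continuous_summary <- function(df) {
  if (any(!is.finite(df$mean)) || any(!is.finite(df$sd)))
    stop("non-numeric mean/sd in continuous summary")
  if (any(df$sd < 0)) stop("sd < 0 in continuous summary (row ",
                           which(df$sd < 0)[1], ")")
  if (any(df$n < 2)) stop("n < 2 in continuous summary (row ",
                          which(df$n < 2)[1], ")")
  df$n <- as.integer(df$n)
  dup <- duplicated(df[, c("taxon", "character")])
  if (any(dup)) stop("duplicate taxon x character row in continuous summary")
  df
}

#' Write a continuous summary table to CSV
#' @param summaries Data frame as from [read_continuous_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_continuous_summary <- function(summaries, path) {
  write.csv(summaries[, c("taxon", "character", "mean", "sd", "n")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise raw continuous measurements per taxon and character
#'
#' Raw-measurement layout: columns `id`, `taxon`, optionally `sex`, then
#' one numeric column per character; missing values excluded from n.
#'
#' @param raw Data frame of raw measurements.
#' @return Summary data frame (taxon, character, mean, sd, n), rows with
#'   n >= 2 only.
#' @export
summarize_raw <- function(raw) {
  stopifnot(all(c("id", "taxon") %in% names(raw)))
  chars <- setdiff(names(raw), c("id", "taxon", "sex", "age_class"))
  out <- list()
  for (tx in unique(raw$taxon)) for (ch in chars) {
    v <- raw[[ch]][raw$taxon == tx]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    out[[length(out) + 1L]] <- data.frame(
      taxon = tx, character = ch, mean = mean(v), sd = sd(v),
      n = length(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
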