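#' Specify a synthetic taxon
#'
#' Defines the true generating parameters of one virtual taxon: Bernoulli
#' state-1 frequencies for binary characters, Normal(mu, sigma) continuous
#' characters (meristic characters are rounded to integers), a Gaussian
#' climatic niche per layer (optimum and breadth), and sample sizes.
#'
#' @param name Taxon label.
#' @param n_males,n_females Individuals per sex for the character matrix.
#' @param discrete Named numeric vector of state-1 frequencies in \[0, 1\].
#' @param continuous Named list, each element `c(mean, sd)`.
#' @param meristic Character vector naming which continuous characters are
#'   counts (rounded to nearest integer).
#' @param niche Named list, each element `c(optimum, breadth)` per climate
#'   layer; breadth > 0.
#' @param n_occurrences Occurrence records to sample.
#' @return Object of class `taxon_spec`.
#' @export
taxon_spec <- function(name, n_males = 15L, n_females = 15L,
                       discrete = NULL, continuous = NULL,
                       meristic = character(), niche = NULL,
                       n_occurrences = 30L) {
  if (!is.null(discrete))
    stopifnot(all(discrete >= 0 & discrete <= 1), !is.null(names(discrete)))
  if (!is.null(continuous))
    stopifnot(all(vapply(continuous, function(x) x[2] >= 0, logical(1))))
  if (!is.null(niche))
    stopifnot(all(vapply(niche, function(x) x[2] > 0, logical(1))))
  structure(list(name = name, n_males = as.integer(n_males),
                 n_females = as.integer(n_females), discrete = discrete,
                 continuous = continuous, meristic = meristic,
                 niche = niche, n_occurrences = as.integer(n_occurrences)),
            class = "taxon_spec")
}

#' Specify a synthetic climate world
#'
#' Layers are built as a linear gradient in a random direction plus a
#' sinusoidal term plus Gaussian noise, scaled to roughly \[0, 100\] —
#' smooth enough to exercise envelope models without a full spatial
#' autocorrelation model.
#'
#' @param ncols,nrows Grid dimensions.
#' @param n_layers Number of climate layers.
#' @param xll,yll,cellsize Grid placement (WGS84 degrees).
#' @param gradient_amp,sine_amp,noise_amp Component amplitudes.
#' @param nodata_frac Fraction of cells masked as nodata.
#' @return Object of class `world_spec`.
#' @export
world_spec <- function(ncols = 30L, nrows = 30L, n_layers = 2L,
                       xll = -75, yll = -15, cellsize = 0.05,
                       gradient_amp = 60, sine_amp = 20, noise_amp = 4,
                       nodata_frac = 0.02) {
  structure(list(ncols = as.integer(ncols), nrows = as.integer(nrows),
                 n_layers = as.integer(n_layers), xll = xll, yll = yll,
                 cellsize = cellsize, gradient_amp = gradient_amp,
                 sine_amp = sine_amp, noise_amp = noise_amp,
                 nodata_frac = nodata_frac), class = "world_spec")
}

#' Generate a synthetic climate stack
#'
#' @param world A [world_spec()].
#' @param seed Integer seed; output is reproducible given the seed.
#' @return A [climate_stack()].
#' @export
gen_world <- function(world = world_spec(), seed = 1L) {
  stopifnot(inherits(world, "world_spec"))
  set.seed(seed)
  nr <- world$nrows; nc <- world$ncols
  rr <- matrix(rep(seq_len(nr) / nr, nc), nr, nc)
  cc <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  layers <- lapply(seq_len(world$n_layers), function(l) {
    th <- runif(1, 0, 2 * pi)
    ph <- runif(1, 0, 2 * pi)
    f <- runif(1, 1, 3)
    v <- world$gradient_amp * (cos(th) * cc + sin(th) * rr) +
      world$sine_amp * sin(2 * pi * f * (cc + rr) / 2 + ph) +
      world$noise_amp * matrix(rnorm(nr * nc), nr, nc)
    v <- v - min(v)
    structure(list(values = v, ncols = nc, nrows = nr, xll = world$xll,
                   yll = world$yll, cellsize = world$cellsize,
                   nodata = -9999), class = "climate_layer")
  })
  names(layers) <- paste0("bio", seq_len(world$n_layers))
  if (world$nodata_frac > 0) {
    nna <- round(world$nodata_frac * nr * nc)
    if (nna > 0) {
      idx <- sample(nr * nc, nna)
      for (l in seq_along(layers)) layers[[l]]$values[idx] <- NA_real_
    }
  }
  climate_stack(layers)
}

# True per-cell suitability for a taxon's Gaussian niche: product over
# layers of exp(-(v - optimum)^2 / (2 breadth^2)).
true_suitability <- function(spec, stack) {
  stopifnot(!is.null(spec$niche))
  s <- matrix(1, stack$nrows, stack$ncols)
  for (nm in names(spec$niche)) {
    par <- spec$niche[[nm]]
    v <- stack$layers[[nm]]
    if (is.null(v)) stop("niche layer not in stack: ", nm)
    s <- s * exp(-(v - par[1])^2 / (2 * par[2]^2))
  }
  s[!stack$mask] <- NA_real_
  s
}

#' Sample occurrence records from a taxon's true niche
#'
#' Cells are drawn without replacement with probability proportional to
#' the true Gaussian suitability surface; coordinates are cell centers
#' (so deduplication is a no-op on synthetic data by construction).
#'
#' @param spec A [taxon_spec()] with a `niche`.
#' @param stack A [climate_stack()].
#' @param seed Integer seed.
#' @return An `occurrence_set`.
#' @export
gen_occurrences <- function(spec, stack, seed = 1L) {
  suit <- true_suitability(spec, stack)
  idx <- which(!is.na(suit) & suit > 0)
  if (spec$n_occurrences > length(idx))
    stop("requested ", spec$n_occurrences, " occurrences but only ",
         length(idx), " cells have positive suitability")
  set.seed(seed)
  pick <- sample(idx, spec$n_occurrences, prob = suit[idx])
  rc <- arrayInd(pick, dim(suit))
  xy <- cell_center(stack, rc[, 1], rc[, 2])
  occurrence_set(data.frame(taxon = spec$name, longitude = xy[, 1],
                            latitude = xy[, 2], stringsAsFactors = FALSE))
}

#' Generate discrete and continuous character data for a set of taxa
#'
#' Discrete states are independent Bernoulli draws at each taxon's true
#' state-1 frequency; continuous characters are Normal(mu, sigma) with
#' meristic characters rounded to the nearest integer.
#'
#' @param specs List of [taxon_spec()]s (>= 2).
#' @param seed Integer seed.
#' @param applicability Optional applicability flags for the discrete
#'   characters (see [character_matrix()]).
#' @return List with `matrix` (a [character_matrix()]), `raw` (raw
#'   continuous measurements data frame) and `summaries` (via
#'   [summarize_raw()]).
#' @export
gen_characters <- function(specs, seed = 1L, applicability = NULL) {
  stopifnot(length(specs) >= 2L)
  set.seed(seed)
  ind <- list(); st <- list(); raw <- list()
  for (sp in specs) {
    n <- sp$n_males + sp$n_females
    meta <- data.frame(
      id = sprintf("%s_%02d", sp$name, seq_len(n)), taxon = sp$name,
      sex = c(rep("male", sp$n_males), rep("female", sp$n_females)),
      age_class = "adult", stringsAsFactors = FALSE)
    ind[[sp$name]] <- meta
    if (!is.null(sp$discrete))
      st[[sp$name]] <- sapply(names(sp$discrete), function(ch)
        rbinom(n, 1L, sp$discrete[[ch]]))
    if (!is.null(sp$continuous)) {
      cont <- sapply(names(sp$continuous), function(ch) {
        v <- rnorm(n, sp$continuous[[ch]][1], sp$continuous[[ch]][2])
        if (ch %in% sp$meristic) round(v) else v
      })
      raw[[sp$name]] <- cbind(meta[, c("id", "taxon", "sex")],
                              as.data.frame(cont))
    }
  }
  individuals <- do.call(rbind, ind)
  rownames(individuals) <- NULL
  mat <- NULL
  if (length(st))
    mat <- character_matrix(individuals, do.call(rbind, st), applicability)
  rawdf <- if (length(raw)) do.call(rbind, raw) else NULL
  if (!is.null(rawdf)) rownames(rawdf) <- NULL
  list(matrix = mat, raw = rawdf,
       summaries = if (!is.null(rawdf)) summarize_raw(rawdf) else NULL)
}

#' Generate a gene tree with per-taxon clades and optional discordance
#'
#' Builds a ladder of balanced per-taxon clades (so every taxon is
#' exclusive at discordance 0); with probability `discordance` each tip is
#' regrafted into a random other taxon's clade, breaking exclusivity.
#' Branch lengths are arbitrary positive values.
#'
#' @param specs List of [taxon_spec()]s, or a named integer vector of tips
#'   per taxon.
#' @param discordance Per-tip regrafting probability in \[0, 1\].
#' @param seed Integer seed; the newick string is reproducible.
#' @param tips_per_taxon Tips per taxon when `specs` is a list of
#'   `taxon_spec`s.
#' @return A [taxon_tree()].
#' @export
gen_tree <- function(specs, discordance = 0, seed = 1L,
                     tips_per_taxon = 4L) {
  stopifnot(discordance >= 0, discordance <= 1)
  counts <- if (is.numeric(specs)) specs
    else stats::setNames(rep(as.integer(tips_per_taxon), length(specs)),
                         vapply(specs, `[[`, character(1), "name"))
  taxa <- names(counts)
  stopifnot(length(taxa) >= 2L)
  set.seed(seed)
  tipnames <- unlist(lapply(taxa, function(tx)
    sprintf("%s_h%d", tx, seq_len(counts[[tx]]))))
  home <- rep(taxa, counts)
  # regraft: move a discordant tip's label into another taxon's clade slot
  slot <- seq_along(tipnames)
  disc <- which(runif(length(tipnames)) < discordance)
  for (i in disc) {
    others <- which(home != home[i])
    if (length(others) == 0L) next
    j <- others[sample.int(length(others), 1L)]
    slot[c(i, j)] <- slot[c(j, i)]
    home[c(i, j)] <- home[c(j, i)]
  }
  placed <- character(length(tipnames))
  placed[slot] <- tipnames
  # balanced clade per slot block, then a ladder across taxa
  blocks <- split(placed, rep(taxa, counts))
  clade_nwk <- function(tips) {
    if (length(tips) == 1L) return(tips)
    mid <- ceiling(length(tips) / 2)
    sprintf("(%s,%s)", clade_nwk(tips[seq_len(mid)]),
            clade_nwk(tips[-seq_len(mid)]))
  }
  nwk <- clade_nwk_ladder(vapply(blocks[taxa], clade_nwk, character(1)))
  phy <- ape::read.tree(text = paste0(nwk, ";"))
  taxon_tree(phy, data.frame(tip = tipnames, taxon = rep(taxa, counts),
                             stringsAsFactors = FALSE))
}

clade_nwk_ladder <- function(clades) {
  out <- clades[1]
  for (i in seq_along(clades)[-1]) out <- sprintf("(%s,%s)", clades[i], out)
  out
}
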