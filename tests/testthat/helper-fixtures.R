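# Shared test builders: tiny in-code datasets, small worlds, oracles.

make_tiny_matrix <- function() {
  ind <- data.frame(
    id = sprintf("i%02d", 1:12),
    taxon = rep(c("A", "B"), each = 6),
    sex = rep(c("male", "male", "male", "female", "female", "female"), 2),
    age_class = c(rep("adult", 11), "juvenile"),
    stringsAsFactors = FALSE)
  states <- cbind(
    pores = c(rep(0L, 6), rep(1L, 6)),          # fixed A vs B
    marks = c(1L, 1L, 0L, 1L, 0L, 1L, rep(1L, 6)),  # polymorphic in A
    belly = rep(1L, 12))                         # monomorphic everywhere
  character_matrix(ind, states,
                   c(pores = "adult-males-only", marks = "all",
                     belly = "all"))
}

make_small_world <- function(seed = 42, ncols = 25, nrows = 25,
                             n_layers = 2) {
  gen_world(world_spec(ncols = ncols, nrows = nrows, n_layers = n_layers),
            seed = seed)
}

niche_spec <- function(name, opt, breadth = 8, n = 20) {
  taxon_spec(name, niche = list(bio1 = c(opt, breadth),
                                bio2 = c(40, 12)),
             n_occurrences = n)
}

# Brute-force monophyly oracle: a taxon is exclusive iff some clade's tip
# set equals the taxon's tip set (single tips are trivially exclusive).
brute_force_monophyly <- function(tree, taxon) {
  tips <- tree$assignments$tip[tree$assignments$taxon == taxon]
  if (length(tips) == 1L) return(TRUE)
  phy <- tree$phylo
  all_tips <- phy$tip.label
  if (length(tips) == length(all_tips)) return(TRUE)
  clades <- lapply((length(all_tips) + 1):(length(all_tips) + phy$Nnode),
                   function(nd) ape::extract.clade(phy, nd)$tip.label)
  any(vapply(clades, function(cl) setequal(cl, tips), logical(1)))
}

# Exhaustive binomial count-bound oracle by direct CDF enumeration.
enumerate_count_bound <- function(p, m, P, direction) {
  probs <- vapply(0:m, function(i) choose(m, i) * p^i * (1 - p)^(m - i),
                  numeric(1))
  cdf <- cumsum(probs)
  if (direction == "upper") {
    which(cdf >= P - 1e-12)[1] - 1L
  } else {
    tail_ge <- vapply(0:m, function(c)
      sum(probs[(c + 1):(m + 1)]) >= P - 1e-12, logical(1))
    max(which(tail_ge)) - 1L
  }
}
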