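#!/usr/bin/env Rscript
# Integration: combine tree exclusivity, discrete diagnosability,
# continuous gaps and niche comparisons into per-pair verdicts under the
# conservative rule (one corroborating line suffices when both taxa are
# exclusive candidates).
#
# With the packaged morphology and tree plus the synthetic-world niche
# evidence of driver 03, the three focal populations (Ancash, Ayacucho,
# Cusco) are each delimited from one another and from the two named
# species by at least one line of evidence.

suppressPackageStartupMessages(library(delimitax))
dir.create("results", showWarnings = FALSE)

seed <- 20131218L
fx <- load_walkeri_fixtures()

world <- gen_world(world_spec(ncols = 40, nrows = 40, n_layers = 3),
                   seed = seed)
specs <- list(
  Ancash   = taxon_spec("Ancash",
    niche = list(bio1 = c(35, 8), bio2 = c(55, 10), bio3 = c(50, 14)),
    n_occurrences = 22),
  Ayacucho = taxon_spec("Ayacucho",
    niche = list(bio1 = c(75, 7), bio2 = c(45, 10), bio3 = c(50, 14)),
    n_occurrences = 31),
  Cusco    = taxon_spec("Cusco",
    niche = list(bio1 = c(38, 8), bio2 = c(57, 10), bio3 = c(50, 14)),
    n_occurrences = 16),
  tacnae   = taxon_spec("tacnae",
    niche = list(bio1 = c(15, 6), bio2 = c(20, 8), bio3 = c(50, 14)),
    n_occurrences = 33),
  walkeri  = taxon_spec("walkeri",
    niche = list(bio1 = c(55, 8), bio2 = c(70, 9), bio3 = c(50, 14)),
    n_occurrences = 52))
occs <- lapply(seq_along(specs), function(i)
  gen_occurrences(specs[[i]], world, seed = seed + i))
names(occs) <- names(specs)

ev <- build_evidence(matrix = fx$matrix,
                     summaries = rbind(fx$meristic, fx$morphometric),
                     occs = occs, stack = world, tree = fx$tree,
                     decision = decision_config(), seed = seed)

render_report(ev, "results/evidence.tsv", "tsv")
render_report(ev, "results/evidence.md", "markdown")

cat("Per-pair verdicts:\n")
print(as.data.frame(ev)[, c("taxon_a", "taxon_b", "n_fixed_discrete",
                            "n_gaps", "schoener_D", "p_identity",
                            "verdict")], row.names = FALSE)
cat(sprintf("\n%d of %d pairs delimited; reports in results/evidence.{tsv,md}\n",
            sum(ev$verdict == "delimited"), nrow(ev)))
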