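suppressMessages(library(finemapSNV))
frac_private <- function(F, seed) {
    region <- RegionSpec("r", 2000L, founder_haplotypes = 200L, common_fraction = 1)
    pops <- list(PopulationSpec("A", 50L, 50L, divergence_F = F),
                 PopulationSpec("B", 50L, 50L, divergence_F = F))
    panel <- simulatePanel(region, pops, seed = seed, n_haplotypes = 2000L)
    fa <- colMeans(panel@haplotypes[["A"]]); fb <- colMeans(panel@haplotypes[["B"]])
    polyA <- fa > 0 & fa < 1; polyB <- fb > 0 & fb < 1
    sum(xor(polyA, polyB)) / sum(polyA | polyB)
}
for (F in c(0.01, 0.1)) cat("F=",F,":", round(sapply(1:4, function(s) frac_private(F,s)),3), "\n")
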