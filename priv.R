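suppressMessages(library(finemapSNV))
frac_private <- function(F, seed, rare_only=FALSE) {
    region <- RegionSpec("r", 2000L, founder_haplotypes = 200L, common_fraction = 0.128)
    pops <- list(PopulationSpec("A", 50L, 50L, divergence_F = F),
                 PopulationSpec("B", 50L, 50L, divergence_F = F))
    panel <- simulatePanel(region, pops, seed = seed)
    fa <- colMeans(panel@haplotypes[["A"]]); fb <- colMeans(panel@haplotypes[["B"]])
    polyA <- fa > 0 & fa < 1; polyB <- fb > 0 & fb < 1
    if (rare_only) { rare <- pmin((fa+fb)/2, 1-(fa+fb)/2) < 0.005
      polyA <- polyA & rare; polyB <- polyB & rare }
    sum(xor(polyA, polyB)) / sum(polyA | polyB)
}
for (F in c(0.01, 0.05, 0.1, 0.2)) {
  v <- sapply(1:5, function(s) frac_private(F, s))
  cat("F=",F," all:", round(mean(v),3), "\n")
}
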