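#!/usr/bin/env Rscript
# Sensitivity of the predicted effect to mean dominance and component
# effect for mammal-, Drosophila-, and bird-like genomes. Writes the
# tidy sweep table to results/sweep.csv and, when ggplot2 is installed,
# a line plot to results/sweep.pdf.

suppressPackageStartupMessages(library(unguardedX))

dir.create("results", showWarnings = FALSE)

grid <- sweep_scenarios(
  list("mammal_baseline", "drosophila_baseline", "bird_baseline"),
  h_bar = seq(0, 0.5, by = 0.01),
  alpha_hom = c(0.1, 0.3))
utils::write.csv(grid, "results/sweep.csv", row.names = FALSE)

at <- grid[grid$h_bar == 0.25 & grid$alpha == 0.3, ]
cat("Sweep written:", nrow(grid), "rows.\n")
cat("At h_bar = 0.25, alpha = 0.3 the curves pass through:\n")
print(data.frame(scenario = at$scenario, ratio = round(at$ratio, 3)),
      row.names = FALSE)
cat("\nReading: every curve decreases with mean dominance and reaches 1",
    "at additivity (h_bar = 0.5); bird-like Z chromosomes support a",
    "slightly larger effect than mammal-like X chromosomes at matched",
    "parameters because male-biased mutation loads the Z.\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(grid, aes(h_bar, pct_log, colour = scenario,
                        linetype = factor(alpha))) +
    geom_line() +
    labs(x = "mean dominance coefficient of deleterious mutations",
         y = "predicted sex difference, 100 * ln(ratio)",
         colour = "scenario", linetype = "component effect") +
    theme_minimal()
  ggsave("results/sweep.pdf", p, width = 7, height = 4.5)
  cat("Plot written to results/sweep.pdf\n")
}
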