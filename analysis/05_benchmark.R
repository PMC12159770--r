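#!/usr/bin/env Rscript

# Assemble the facility benchmark table: crude DOT/DASC per 1000 DP,
# method-1 O:E and method-2 P:E for both outcomes, with ranks per column.

library(abxbench)

stays <- read.csv("results/data/stays.csv")
eval <- subset(stays, period == "evaluation")

bm <- build_benchmark(
  eval,
  oe_dot = read.csv("results/method1_oe_dot.csv"),
  oe_dasc = read.csv("results/method1_oe_dasc.csv"),
  pe_dot = read.csv("results/method2_pe_dot.csv"),
  pe_dasc = read.csv("results/method2_pe_dasc.csv")
)
write.csv(bm, "results/benchmark_wide.csv", row.names = FALSE)
write.csv(benchmark_long(bm), "results/benchmark_long.csv", row.names = FALSE)
write.csv(attr(bm, "summary"), "results/benchmark_summary.csv",
  row.names = FALSE
)

smry <- attr(bm, "summary")
cat("Benchmark columns (median [IQR]):\n")
for (i in seq_len(nrow(smry))) {
  cat(sprintf(
    "  %-16s %8.2f [%.2f-%.2f]\n",
    smry$column[i], smry$median[i], smry$q25[i], smry$q75[i]
  ))
}
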