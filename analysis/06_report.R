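#!/usr/bin/env Rscript

# Stage 6: assemble the comparison summary.
#
# Collects the stage tables under results/ into a single markdown summary of
# the small-vs-large spot comparison: nominal and worst-case CTV metrics,
# pass counts, OAR worst-case EUD/NTCP deltas, and interplay D99 losses by
# repainting variant and start phase.

library(spotlab)

rd <- function(f) utils::read.csv(file.path("results", f))
rob_s <- rd("robustness_small.csv"); rob_l <- rd("robustness_large.csv")
rb_d <- rd("radiobio_delta.csv")
ip <- rd("interplay.csv")
pass <- vapply(c("robustness_small.json", "robustness_large.json"),
               function(f) jsonlite::read_json(file.path("results", f))$pass_count,
               numeric(1))

lines <- c(
  "# Small vs large spot comparison - summary", "",
  sprintf("- Robustness pass count (CTV D95 >= 6860 cGy(RBE)): small %d/12, large %d/12",
          pass[1], pass[2]),
  sprintf("- WCS CTV D95: small %.0f, large %.0f cGy(RBE)",
          rob_s$wcs[rob_s$metric == "ctv_D95"],
          rob_l$wcs[rob_l$metric == "ctv_D95"]),
  sprintf("- WCS HI (D99/D1): small %.3f, large %.3f",
          rob_s$wcs[rob_s$metric == "ctv_HI"],
          rob_l$wcs[rob_l$metric == "ctv_HI"]),
  "", "## Worst-case OAR deltas (large minus small)", "")
for (i in seq_len(nrow(rb_d)))
  lines <- c(lines, sprintf("- %s %s: %.1f (small %.2f, large %.2f)",
                            rb_d$organ[i], rb_d$quantity[i], rb_d$delta[i],
                            rb_d$small_wcs[i], rb_d$large_wcs[i]))
lines <- c(lines, "", "## Interplay CTV D99 loss vs static (cGy(RBE))", "")
for (i in seq_len(nrow(ip)))
  lines <- c(lines, sprintf("- %s %s start %s: loss %.0f (D99 %.0f, HI %.3f)",
                            ip$model[i], ip$variant[i], ip$start_phase[i],
                            ip$D99_loss[i], ip$D99[i], ip$HI[i]))

writeLines(lines, "results/summary.md")
cat(paste(lines, collapse = "\n"), "\n")
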