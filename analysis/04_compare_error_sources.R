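#!/usr/bin/env Rscript
# Compare the recovered registration-error samples against the
# interobserver-variation samples per organ with two-tailed
# independent-samples t-tests (alpha = 0.05, pooled variance), and render
# the mean +/- 1 SD bar chart per site.

suppressPackageStartupMessages(library(contourvar))

for (site in c("head_neck", "pelvis")) {
  rec <- tibble::as_tibble(read.csv(sprintf("results/%s_records.csv", site)))
  dec <- decompose_records(rec)
  comp <- compare_error_sources(dec, rec)
  out <- dplyr::select(comp, -dplyr::any_of("edef_records"))
  write.csv(out, sprintf("results/%s_comparisons.csv", site),
            row.names = FALSE)
  for (v in c("edef_less", "not_different", "edef_greater")) {
    message(sprintf("%s: %-13s %d of %d ROIs", site, v,
                    sum(comp$verdict == v), nrow(comp)))
  }
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- plot_comparison(comp, dec)
    ggplot2::ggsave(sprintf("results/%s_comparison.png", site), gg,
                    width = 8, height = 4.5, dpi = 150)
  }
}
message("Comparison tables and figures written under results/")
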