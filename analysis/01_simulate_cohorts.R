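#!/usr/bin/env Rscript
# Generate the two synthetic study cohorts (head-and-neck: 30 patients x
# 10 organs; male pelvis: 20 patients x 3 organs with focused second
# registration passes for bladder and rectum) and cache them for the later
# analysis stages. A small two-patient cohort is also written as a JSON
# directory tree to document the interchange format.

suppressPackageStartupMessages(library(contourvar))

seed <- 20160508L # study master seed used throughout the analysis
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)

message("Simulating head-and-neck cohort (30 patients, 10 ROIs)...")
hn <- preset_head_neck()
hn$noise$seed <- seed
hn_bundle <- simulate_cohort(hn$phantoms, hn$noise, hn$n_patients,
                             hn$n_recontour)
saveRDS(hn_bundle, "results/cache/head_neck_bundle.rds")

message("Simulating pelvis cohort (20 patients, 3 ROIs, 2nd-pass subset)...")
pe <- preset_pelvis()
pe$noise$seed <- seed + 1L
pe_bundle <- simulate_cohort(pe$phantoms, pe$noise, pe$n_patients,
                             pe$n_recontour, second_pass = pe$second_pass)
saveRDS(pe_bundle, "results/cache/pelvis_bundle.rds")

message("Writing a 2-patient demo cohort as a JSON directory tree...")
demo <- simulate_cohort(pe$phantoms[1], pe$noise, n_patients = 2,
                        n_recontour = 1)
write_cohort(demo, "results/demo_cohort")

message("Done. Cohort caches under results/cache/, demo tree under ",
        "results/demo_cohort/.")
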