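#!/usr/bin/env Rscript
# Step 1: generate the study cohort.
#
# 24 female runners (conditions at 3.8 and 4.9 m/s) and 13 male runners
# (3.8, 4.1, 5.4 m/s), each condition a 30 s paired recording of
# treadmill vertical GRF (1000 Hz) and sacral acceleration (500 Hz)
# with the default sensor noise model and a 1.337 s clock offset
# between devices; each subject's session bracketed by two
# countermovement jumps. Channel CSVs are large and go to scratch/;
# the small subject table goes to results/.

suppressPackageStartupMessages(library(gaitkinetics))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed")
  as.integer(args[2]) else 1L

cfg <- default_config(seed = seed)
message("simulating cohort with seed ", seed)
cohort <- simulate_cohort(24, 13, cfg)

out <- file.path("scratch", "simdata")
write_cohort(cohort, out)
dir.create("results", showWarnings = FALSE)
utils::write.csv(cohort$subjects, file.path("results", "subjects.csv"),
                 row.names = FALSE)

message(sprintf("wrote %d trials + %d CMJ pairs to %s",
                length(cohort$trials), length(cohort$cmj), out))
message(sprintf("cohort mass: %.1f +/- %.1f kg",
                mean(cohort$subjects$body_mass),
                sd(cohort$subjects$body_mass)))
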