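#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analyses:
# a crosslinking-MS run with three planted bait-prey crosslinks (+/-UV MS1
# feature lists, MS2 spectra, FASTA), a 20-model docked ensemble in which
# half the models carry the peptide in the planted pocket, and kinetic
# traces (exponential remodeling time courses at two H4-tail conditions,
# and a linear NADH-depletion ATPase trace).

suppressPackageStartupMessages(library(xlmap))
seed <- 1L

message("simulating crosslinking-MS run (seed ", seed, ")")
ms <- simulate_xl_ms(xlms_recipe(seed = seed), out_dir = "results/sim/xlms")
message("  planted ", nrow(ms$truth), " crosslinks; MS1 features: ",
        nrow(ms$ms1_plus), " (+UV), ", nrow(ms$ms1_minus), " (-UV)")

message("simulating docked ensemble")
ens <- simulate_ensemble(ensemble_recipe(seed = seed, n_models = 20,
                                         f_pocket = 0.5),
                         out_file = "results/sim/ensemble.pdb")
message("  ", sum(ens$truth$in_pocket), "/20 models in the planted pocket; ",
        length(ens$truth$pocket_residues), " pocket residues")
writeLines(as.character(ens$truth$pocket_residues),
           "results/sim/pocket_residues.txt")
writeLines(as.character(which(ens$truth$in_pocket)),
           "results/sim/models_in_pocket.txt")

message("simulating kinetic traces")
dir.create("results/sim/kinetics", recursive = TRUE, showWarnings = FALSE)
# wild-type H4 chromatin remodels fast, tail-less slowly (16-fold here)
sim <- simulate_kinetics(kinetics_recipe(seed = seed, k = 0.08,
                                         noise_sd = 0.03, replicates = 2),
                         out_file = "results/sim/kinetics/remodeling_wt.csv")
sim <- simulate_kinetics(kinetics_recipe(seed = seed + 1, k = 0.005,
                                         noise_sd = 0.03, replicates = 2),
                         out_file = "results/sim/kinetics/remodeling_tailless.csv")
sim <- simulate_kinetics(kinetics_recipe(seed = seed + 2, kind = "linear",
                                         slope = -2.5 * 6220 * 1e-6,
                                         noise_sd = 2e-4, n_points = 60),
                         out_file = "results/sim/kinetics/atpase_nadh.csv")
message("done; inputs under results/sim/")
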