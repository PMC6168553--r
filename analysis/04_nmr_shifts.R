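#!/usr/bin/env Rscript
# Solution-vs-solid-state chemical-shift perturbation mapping and
# residue-type signal accounting on synthetic shift tables.
#
# Plants interface-sized perturbations (>= 1.2 ppm summed over Ca/Cb) at
# five residues of a 72-residue construct, adds 0.05 ppm measurement noise
# to the solid-state table, and checks which residues the 1.2 ppm
# threshold flags; then reproduces the residue-type counting logic used to
# localise a disordered C-terminal segment.

suppressMessages(library(helifil))
dir.create("results", showWarnings = FALSE)

seq72 <- paste(rep(c("A", "Q", "L", "V", "T", "E", "S", "K"), 9),
               collapse = "")
planted <- list(`443` = c(1.1, 0.4), `457` = c(-1.3, 0.5),
                `471` = c(0.9, 0.6), `483` = c(1.6, -0.2),
                `497` = c(-0.8, 0.9))
tabs <- make_shift_tables(seq72, perturbed = planted, noise_sigma = 0.05,
                          seed = 4, first_resno = 441L)

pert <- state_perturbation(tabs$solution, tabs$solid, threshold = 1.2)
flagged <- pert$perturbation$resno[pert$perturbation$flag]
cat("planted >= 1.2 ppm at:", names(planted), "\n")
cat("flagged:", flagged, "\n")
write.table(pert$perturbation, "results/shift_perturbation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# secondary shifts of the solid state against the bundled random-coil table
rc <- read_random_coil_table()
ss <- secondary_shifts(tabs$solid, rc)
write.table(ss, "results/secondary_shifts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# residue-type signal accounting: ordered core assigned, tail unassigned
core <- c(rep(c("L", "T", "A"), 6), rep(c("L", "V", "A"), 3),
          rep("V", 2), "P")
tail_seq <- c(rep(c("L", "A"), 5), "V", "V", rep("P", 3))
construct <- c(core, tail_seq)
acc <- signal_accounting(seq_along(core), construct,
                         types = c("L", "T", "V", "P"))
print(acc)
write.table(acc, "results/signal_accounting.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/shift_perturbation.tsv, secondary_shifts.tsv, signal_accounting.tsv\n")
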