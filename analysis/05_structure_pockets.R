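#!/usr/bin/env Rscript
# Step 5: structure layer. (a) Kabsch/CA-RMSD sanity on toy helices: a
# rigid-transform copy superposes to RMSD 0, Gaussian noise gives a finite
# RMSD near its expectation. (b) The bundled in-text acyl-acceptor pocket
# residue lists are charge-profiled: both characterized spermidine
# acyltransferase pockets classify acidic, matching the amine-acceptor
# electrostatics; the charge-inverted list classifies basic
# (shikimate-type contrast). Writes the pocket report tables.

suppressPackageStartupMessages(library(bahdscope))
set.seed(20260905)

base <- make_toy_structure(120)
moved <- make_toy_structure(120, rigid_transform = TRUE)
noisy <- make_toy_structure(120, sigma = 0.5)
rmsd_rigid <- ca_rmsd_by_alignment(base, moved)$rmsd
rmsd_noisy <- ca_rmsd_by_alignment(base, noisy)$rmsd
message(sprintf("toy helix CA-RMSD: rigid copy %.2e A, sigma=0.5 noise %.3f A",
                rmsd_rigid, rmsd_noisy))

rows <- list()
for (enz in c("AtSHT", "AtSDT")) {
  prof <- bahd_pocket(enz)
  write_pocket_tsv(prof, sprintf("results/pocket_%s.tsv", enz))
  rows[[enz]] <- data.frame(enzyme = enz,
                            n_positions = nrow(prof$positions),
                            net_charge = prof$net_charge,
                            electro_class = prof$electro_class,
                            catalytic_his = bahd_catalytic_his(enz))
  message(sprintf(
    "%s pocket: %d residues, net %+.1f -> %s (catalytic His%d)",
    enz, nrow(prof$positions), prof$net_charge, prof$electro_class,
    bahd_catalytic_his(enz)))
}

# charge-inverted AtSDT pocket: the shikimate-type electrostatic contrast
inv <- bahd_pocket("AtSDT")$positions
swap <- c(D = "R", E = "K")
inv$resname <- ifelse(inv$resname %in% names(swap), swap[inv$resname],
                      inv$resname)
pc <- pocket_charge(inv)
rows[["inverted"]] <- data.frame(enzyme = "AtSDT_charge_inverted",
                                 n_positions = nrow(inv),
                                 net_charge = pc$net_charge,
                                 electro_class = pc$electro_class,
                                 catalytic_his = NA_integer_)
message(sprintf("charge-inverted AtSDT pocket: net %+.1f -> %s",
                pc$net_charge, pc$electro_class))

write.table(do.call(rbind, rows), "results/pocket_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/pocket_AtSHT.tsv, pocket_AtSDT.tsv, pocket_summary.tsv")
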