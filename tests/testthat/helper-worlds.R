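# One synthetic recovery world: a genome with annotated CDS, 300 sRNAs of
# which 30 carry a planted coding ORF (SD core, biased codons, omega = 0.2
# orthologs), analyzed end to end. Problem sizes follow the package's
# documented desk-scale study conditions.
run_recovery_world <- function(wseed, n_srna = 300, n_coding = 30) {
  sim <- simulate_genome(length = 200000, n_cds = 60, seed = wseed)
  world <- simulate_srnas(sim, n_srna = n_srna, n_coding = n_coding,
                          srna_len = 150, seed = wseed + 1)
  tree <- ape::read.tree(
    text = "((ref:0.2,sp2:0.2):0.1,(sp3:0.2,sp4:0.2):0.1);")
  prov <- simulated_dnds_provider(tree, "ref", world$truth$orf_id,
                                  omega_coding = 0.2, tol = 0.12,
                                  omega_bounds = c(0.002, 20),
                                  scale_bounds = c(0.02, 20),
                                  seed = (wseed * 17) %% 2^30)
  res <- analyze_srna_coding(world$genome, sim$features, world$srnas,
                             anti_sd = "UCACCUCCUUUCU",
                             dnds_provider = prov,
                             n_sets = 2, n_comp_sets = 10, n_bags = 25,
                             n_shuffles = 10, cv_folds = 5,
                             seed = wseed + 2)
  tot <- res$combined[res$combined$category == "total", ]
  list(c_corrected = tot$c_corrected, ci95 = tot$ci95,
       covered = abs(tot$c_corrected - n_coding) <= tot$ci95,
       fraction = res$fraction$fraction, analysis = res)
}
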