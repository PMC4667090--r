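# shared fixture builders (all generated in code, fixed seeds)

small_panel <- function(seed = 7, n_loci = 40, n_varieties = 12,
                        snp_rate = 1 / 600, ...) {
  cfg <- sim_config(n_loci = n_loci, n_varieties = n_varieties,
                    snp_rate = snp_rate, seed = seed, ...)
  simulate_tetraploid_panel(simulate_progenitors(cfg), cfg)
}

# two-group concordance: best matching of a 2-level clustering to truth
concordance2 <- function(cluster, truth) {
  t1 <- truth == truth[1]
  max(mean((cluster == cluster[1]) == t1), mean((cluster != cluster[1]) == t1))
}

table1_path <- function() {
  system.file("extdata", "table1_markers.tsv", package = "tetrasnp")
}
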