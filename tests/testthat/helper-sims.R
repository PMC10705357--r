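# Shared simulated datasets, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

get_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_isoseq(cfg)
  }
  .sim_cache[[key]]
}

sim_basic <- function() get_sim("basic", sim_config(seed = 11, n_genes = 12))

sim_apa_rich <- function() {
  get_sim("apa", sim_config(seed = 5, n_genes = 12,
                            reads_per_isoform = c(12L, 16L),
                            frac_fusion_reads = 0, frac_artifact_reads = 0,
                            apa_sites_per_gene = c(1L, 3L),
                            end_scatter_sd = 2))
}

sim_wide <- function() {
  get_sim("wide", sim_config(seed = 23, n_genes = 30,
                             reads_per_isoform = c(8L, 12L)))
}

run_basic <- function() {
  if (is.null(.sim_cache$run_basic)) {
    sim <- sim_basic()
    .sim_cache$run_basic <- run_pipeline(
      sim$reads, sim$alignments, sim$annotation,
      pe_evidence = sim$pe_support, evidence = sim$evidence)
  }
  .sim_cache$run_basic
}
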