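# Shared simulated fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, build(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# default study conditions at full library depths (counts level)
default_sim <- function() fixture("default", function() {
  cfg <- sim_config(n_genes = 300, seed = 1)
  prog <- build_program(cfg)
  cm <- sample_counts(prog, seed = 101)
  arch <- setNames(prog$genes$archetype, prog$genes$gene_id)
  list(cfg = cfg, prog = prog, cm = cm, arch = arch)
})

# read-level round-trip conditions: error-free reads, long transcripts so
# accidental fragment collisions are negligible, reduced depths
readlevel_sim <- function() fixture("readlevel", function() {
  cfg <- sim_config(n_genes = 80, seed = 2)
  prog <- build_program(cfg)
  ref <- generate_reference(80, c(800, 2000), seed = 2)
  depths <- round(DEFAULT_LIBRARY_DEPTHS / 100)
  cm <- sample_counts(prog, depths, seed = 102)
  pool <- emit_reads(cm, ref, error_rate = 0, dup_rate = 0.1, seed = 103)
  list(prog = prog, ref = ref, cm = cm, pool = pool, depths = depths)
})
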