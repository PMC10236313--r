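# Default-configuration fixture shared by the acceptance tests.
# Simulated once per session (in memory; the determinism check does
# its own on-disk runs).

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config()
      ann <- simulate_annotation(cfg)
      sig <- simulate_chip_and_rna(cfg, ann)
      cache <<- list(cfg = cfg, ann = ann, sig = sig)
    }
    cache
  }
})
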