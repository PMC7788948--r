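# The paper-scale simulation experiment (3 types x 150 cells x 8180
# genes, seeds 1..10) takes a few minutes, and two different acceptance
# properties read from it (clustering accuracy and the distance ratio).
# Run it once per test session and cache the result.
paper_scale_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_simulation_study(seeds = 1:10)
    cache
  }
})
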