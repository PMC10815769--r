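# Cached full-scale demo runs shared between the workflow tests and the
# end-to-end recovery checks (each takes ~45 s; computing them once keeps
# the suite quick).
.run_cache <- new.env(parent = emptyenv())

demo_run <- function(system = c("ZW", "XY")) {
  system <- match.arg(system)
  if (is.null(.run_cache[[system]]))
    .run_cache[[system]] <- run_workflow(run_config(system = system))
  .run_cache[[system]]
}
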