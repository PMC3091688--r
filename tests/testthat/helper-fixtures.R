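# Shared fixtures: small cluster configurations used across test files.

# compact cluster (2 functional alpha, 1 Bohr + 1 non-Bohr beta, no
# pseudogenes unless overridden) for fast end-to-end checks
small_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    n_alpha_functional = 2L, n_beta_bohr = 1L, n_beta_nonbohr = 1L,
    pseudogene_plan = data.frame(subunit = character(0), defect = character(0),
                                 stringsAsFactors = FALSE),
    intergenic_length_range = c(800L, 1500L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}
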