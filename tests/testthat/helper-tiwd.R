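# Shared fixtures: the two packaged data sets and a small deterministic
# synthetic sample generator.
metal <- tiwd_data("metal_fatigue")
cancer <- tiwd_data("head_neck_cancer")

synth_sample <- function(n, alpha, beta, seed = 1L) {
  set.seed(seed)
  rtiwd(n, alpha, beta)
}

# parameter grid used by several property tests
param_grid <- expand.grid(alpha = c(0.5, 1, 2), beta = c(0.5, 1, 3))
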