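# Shared fixtures: small, fast parameter sets built in code.

# Two-run design for cheap structural tests.
quick_spec <- function(n_runs = 2) design_spec(n_runs = n_runs)

# Reduced ROI sizes for simulation-heavy tests; effect structure unchanged.
quick_neural <- function(...) {
  neural_params(cortical_voxels = 48, hippo_voxels = 48, ...)
}

quick_subject <- function(seed = 1, gen = generative_params(),
                          neural = quick_neural(), n_runs = 6) {
  simulate_subject(design_spec(n_runs = n_runs), gen, neural, seed = seed)
}

# Independent oracle: Fisher z via stats::cor + atanh (with the same clamp).
oracle_fisher <- function(x, y) {
  atanh(min(max(stats::cor(x, y), -(1 - 1e-7)), 1 - 1e-7))
}

# Independent oracle: brute-force Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
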