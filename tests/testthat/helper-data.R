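# shared fixtures built in code

# one sample per fraction, unit depth and scale
design3 <- function() {
  data.frame(sample = c("in_1", "el_1", "sup_1"),
             fraction = c("input", "eluate", "supernatant"),
             replicate = "rep1", condition = "all",
             stringsAsFactors = FALSE)
}

unit_norm <- function(design, reference = "input") {
  scale <- c(input = 1, eluate = 1, supernatant = 1)
  scale <- scale[intersect(names(scale), unique(design$fraction))]
  normalization_set(stats::setNames(rep(1, nrow(design)), design$sample),
                    scale, reference = reference)
}

# small simulated dataset for quick tests
quick_sim <- function(n_genes = 100, seed = 1, ...) {
  simulate_dataset(sim_config(n_genes = n_genes, seed = seed, ...))
}

# geometric mean of the true depth factors of one fraction; because fitted
# depth factors are rescaled to geometric mean 1 within each fraction, the
# between-fraction component of the simulated depths is absorbed into the
# fitted fraction scale factors, so the comparable truth for x_f is
# x_f * gm(depth_f) / gm(depth_reference)
gm_depth <- function(sim, fraction) {
  s <- sim$design$sample[sim$design$fraction == fraction]
  exp(mean(log(sim$truth$norm$depth[s])))
}

effective_scale <- function(sim, fraction, reference = "input") {
  unname(sim$truth$norm$fraction_scale[[fraction]]) *
    gm_depth(sim, fraction) / gm_depth(sim, reference)
}
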