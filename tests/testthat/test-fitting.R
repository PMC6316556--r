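test_that("depth factors follow the median-of-ratios construction", {
  des <- data.frame(sample = c("a", "b"), fraction = "input",
                    replicate = c("r1", "r2"), condition = "all")
  base <- matrix(c(10L, 10L, 200L, 200L, 55L, 55L), ncol = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_equal(unname(estimate_depth_factors(base, des)), c(1, 1))

  doubled <- base
  doubled[, "b"] <- 2L * base[, "a"]
  expect_equal(unname(estimate_depth_factors(doubled, des)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  zero <- base; zero[] <- 0L
  expect_error(estimate_depth_factors(zero, des), "all-zero")
})

test_that("depth factors recover simulated per-sample depths", {
  set.seed(21)
  true_d <- c(0.5, 2.0)
  base <- exp(runif(1000, log(200), log(5000)))
  counts <- cbind(rnbinom(1000, mu = base * true_d[1], size = 50),
                  rnbinom(1000, mu = base * true_d[2], size = 50))
  dimnames(counts) <- list(sprintf("g%04d", 1:1000), c("a", "b"))
  des <- data.frame(sample = c("a", "b"), fraction = "input",
                    replicate = c("r1", "r2"), condition = "all")
  d <- estimate_depth_factors(counts, des)
  # geometric mean of (0.5, 2) is already 1, so factors match directly
  expect_equal(unname(d), true_d, tolerance = 0.05)
})

test_that("single-gene fits match the saturated closed form", {
  des <- design3()
  norm <- unit_norm(des)
  # e = 90, s = 10, i = 100: alpha-hat = e/(e+s) = 0.9
  r <- fit_gene(c(in_1 = 100, el_1 = 90, sup_1 = 10), norm, 1e8, des)
  expect_equal(r$alpha, 0.9, tolerance = 1e-4)
  expect_equal(exp(r$mu), 100, tolerance = 1e-4)
  # symmetric counts give log-odds zero
  r2 <- fit_gene(c(in_1 = 80, el_1 = 40, sup_1 = 40), norm, 1e8, des)
  expect_equal(r2$gamma, 0, tolerance = 1e-4)
  # all-zero gene is flagged, never a silent estimate
  r3 <- fit_gene(c(in_1 = 0, el_1 = 0, sup_1 = 0), norm, 100, des)
  expect_false(r3$converged)
  expect_equal(r3$flag, "all_zero")
})

test_that("the per-gene optimizer agrees with a brute-force grid", {
  sim <- quick_sim(n_genes = 10, seed = 31)
  des <- sim$design
  norm <- sim$truth$norm
  sf <- unname(norm$depth[des$sample] * norm$fraction_scale[des$fraction])
  theta <- sim$truth$theta
  is_el <- des$fraction == "eluate"
  is_sup <- des$fraction == "supernatant"
  # independent likelihood evaluation straight from the model formulas
  ll_at <- function(mu, gamma, y) {
    a <- 1 / (1 + exp(-gamma))
    part <- rep(1, length(sf)); part[is_el] <- a; part[is_sup] <- 1 - a
    sum(dnbinom(y, mu = sf * exp(mu) * part, size = theta, log = TRUE))
  }
  step <- 0.01
  for (g in 1:10) {
    y <- sim$counts[g, des$sample]
    r <- fit_gene(y, norm, theta, des)
    mus <- r$mu + seq(-0.5, 0.5, by = step)
    gams <- r$gamma + seq(-0.5, 0.5, by = step)
    grid <- outer(mus, gams, Vectorize(function(m, gm) ll_at(m, gm, y)))
    best <- arrayInd(which.max(grid), dim(grid))
    expect_lte(max(grid), r$loglik + 1e-8)
    expect_lt(abs(mus[best[1]] - r$mu), 2 * step)
    expect_lt(abs(gams[best[2]] - r$gamma), 2 * step)
  }
})

test_that("fraction scale factors are recovered and scale equivariant", {
  sim <- simulate_dataset(sim_config(n_genes = 500, seed = 41, theta = 100))
  fit <- suppressWarnings(
    fit_modlevel(sim$counts, sim$design,
                 options = fit_options(max_outer = 100)))
  expect_equal(fit$norm$fraction_scale[["eluate"]],
               effective_scale(sim, "eluate"), tolerance = 0.05)
  expect_equal(fit$norm$fraction_scale[["supernatant"]],
               effective_scale(sim, "supernatant"), tolerance = 0.05)

  # doubling all eluate counts doubles the refitted eluate factor
  doubled <- fit$counts
  el <- sim$design$sample[sim$design$fraction == "eluate"]
  doubled[, el] <- 2L * doubled[, el]
  refit <- fit_fraction_factors(doubled, fit$estimates, fit$theta,
                                sim$design, fit$norm)
  expect_equal(refit$fraction_scale[["eluate"]],
               2 * fit$norm$fraction_scale[["eluate"]], tolerance = 0.05)

  expect_error(fit_fraction_factors(fit$counts[1, , drop = FALSE],
                                    fit$estimates[1, ], fit$theta,
                                    sim$design, fit$norm),
               "two genes")
})

test_that("dispersion fitting recovers theta with other parameters fixed", {
  sim <- simulate_dataset(sim_config(n_genes = 1000, seed = 51, theta = 10))
  est <- data.frame(mu_hat = sim$truth$gene$mu,
                    gamma_hat = sim$truth$gene$gamma)
  r <- fit_dispersion(sim$counts, est, sim$truth$norm, sim$design)
  expect_gt(r$theta, 8)
  expect_lt(r$theta, 12)
  expect_false(r$at_bound)

  # Poisson data pushes theta to the upper bound
  simp <- simulate_dataset(sim_config(n_genes = 300, seed = 52, theta = 1e12))
  estp <- data.frame(mu_hat = simp$truth$gene$mu,
                     gamma_hat = simp$truth$gene$gamma)
  rp <- fit_dispersion(simp$counts, estp, simp$truth$norm, simp$design)
  expect_gt(rp$theta, 1e6)

  # invariant to permuting gene order
  perm <- sample(nrow(sim$counts))
  r2 <- fit_dispersion(sim$counts[perm, ], est[perm, ], sim$truth$norm,
                       sim$design)
  expect_equal(r2$theta, r$theta, tolerance = 1e-8)
})

test_that("estimates are invariant when a sample's counts and depth scale together", {
  sim <- quick_sim(n_genes = 80, seed = 61, depth_range = c(1, 1))
  fit1 <- fit_modlevel(sim$counts, sim$design,
                       fixed_norm = sim$truth$norm, fixed_theta = 100)
  scaled <- sim$counts
  s <- sim$design$sample[1]
  scaled[, s] <- 3L * scaled[, s]
  norm2 <- sim$truth$norm
  norm2$depth[s] <- 3
  fit2 <- fit_modlevel(scaled, sim$design, fixed_norm = norm2,
                       fixed_theta = 100)
  expect_equal(fit2$estimates$gamma_hat, fit1$estimates$gamma_hat,
               tolerance = 0.02)
  expect_equal(fit2$estimates$mu_hat, fit1$estimates$mu_hat,
               tolerance = 0.02)
})

test_that("spike-in mode holds the spike-derived factors fixed", {
  sim <- simulate_dataset(sim_config(
    n_genes = 60, seed = 71, n_spikeins = 20,
    fraction_scale = c(eluate = 1.4, supernatant = 1)))
  spikes <- sim$truth$spikes$spike_id
  fit <- suppressMessages(
    fit_modlevel(sim$counts, sim$design, spikeins = spikes))
  des <- fit$design
  gcounts <- sim$counts[, des$sample]
  direct <- spikein_fraction_factor(
    gcounts, des, spikes,
    depth = estimate_depth_factors(
      sim$counts[setdiff(rownames(sim$counts), spikes), des$sample], des))
  expect_identical(fit$norm$fraction_scale, direct$fraction_scale)
  expect_identical(fit$norm$reference, "supernatant")
  # spike rows are anchors, not estimated genes
  expect_false(any(spikes %in% fit$estimates$gene_id))
})

test_that("mode prerequisites are enforced", {
  sim <- quick_sim(n_genes = 20, seed = 81,
                   fractions = c("eluate", "supernatant"))
  expect_error(fit_modlevel(sim$counts, sim$design), "spike-in")
  des2 <- sim$design
  des2$condition <- rep(c("c1", "c2"), length.out = nrow(des2))
  expect_error(fit_modlevel(sim$counts, des2), "conditions")
})
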