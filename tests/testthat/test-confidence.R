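test_that("the profile equals the unconstrained maximum at the MLE", {
  sim <- quick_sim(n_genes = 10, seed = 91)
  fit <- fit_modlevel(sim$counts, sim$design, fixed_norm = sim$truth$norm,
                      fixed_theta = sim$truth$theta)
  for (g in 1:5) {
    gid <- fit$estimates$gene_id[g]
    prof <- profile_loglik(fit$counts[gid, ], fit$estimates$gamma_hat[g],
                           fit$norm, fit$theta, fit$design)
    expect_equal(prof, fit$estimates$loglik[g], tolerance = 1e-6)
    # profiling never exceeds the gene maximum away from the MLE
    away <- profile_loglik(fit$counts[gid, ],
                           fit$estimates$gamma_hat[g] + 1.5,
                           fit$norm, fit$theta, fit$design)
    expect_lt(away, prof)
  }
})

test_that("the profile is unimodal in the log-odds", {
  sim <- quick_sim(n_genes = 10, seed = 92)
  fit <- fit_modlevel(sim$counts, sim$design, fixed_norm = sim$truth$norm,
                      fixed_theta = sim$truth$theta)
  grid <- seq(-8, 8, length.out = 100)
  for (g in 1:10) {
    gid <- fit$estimates$gene_id[g]
    prof <- vapply(grid, function(gam) {
      profile_loglik(fit$counts[gid, ], gam, fit$norm, fit$theta,
                     fit$design)
    }, numeric(1))
    peak <- which.max(prof)
    expect_true(all(diff(prof[seq_len(peak)]) > -1e-8))
    expect_true(all(diff(prof[peak:length(prof)]) < 1e-8))
  }
})

test_that("symmetric counts give a profile symmetric about zero", {
  des <- design3()
  norm <- unit_norm(des)
  y <- c(in_1 = 120, el_1 = 60, sup_1 = 60)
  for (gam in c(0.5, 1.2, 3)) {
    expect_equal(profile_loglik(y, gam, norm, 50, des),
                 profile_loglik(y, -gam, norm, 50, des), tolerance = 1e-6)
  }
})

test_that("deep symmetric counts match the Wald half-width", {
  des <- design3()
  counts <- matrix(c(20000L, 10000L, 10000L, 18000L, 9000L, 9000L),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), des$sample))
  fit <- fit_modlevel(counts, des, fixed_norm = unit_norm(des),
                      fixed_theta = 1e8)
  ci <- ci_gene(fit, "g1", level = 0.95)
  expect_equal(ci$gamma_hat, 0, tolerance = 1e-3)
  # observed information for gamma at alpha = 1/2: (e + s) * 1/4
  wald_half <- qnorm(0.975) * sqrt(1 / (20000 * 0.25))
  expect_equal((ci$gamma_upper - ci$gamma_lower) / 2, wald_half,
               tolerance = 0.1 * wald_half)
  expect_equal(ci$gamma_upper, -ci$gamma_lower, tolerance = 1e-3)

  # the deviance at interior bounds sits exactly on the chi-square cutoff
  dev_at <- function(gam) {
    2 * (profile_loglik(counts["g1", ], ci$gamma_hat, fit$norm, fit$theta,
                        des) -
           profile_loglik(counts["g1", ], gam, fit$norm, fit$theta, des))
  }
  expect_lt(abs(dev_at(ci$gamma_upper) - qchisq(0.95, 1)), 1e-6)
  expect_lt(abs(dev_at(ci$gamma_lower) - qchisq(0.95, 1)), 1e-6)
})

test_that("intervals widen with the confidence level and shrink with depth", {
  des <- design3()
  counts <- matrix(c(300L, 200L, 100L, 3000L, 2000L, 1000L),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("lo", "hi"), des$sample))
  fit <- fit_modlevel(counts, des, fixed_norm = unit_norm(des),
                      fixed_theta = 1e6)
  w <- vapply(c(0.90, 0.95, 0.99), function(lv) {
    ci <- ci_gene(fit, "lo", level = lv)
    ci$gamma_upper - ci$gamma_lower
  }, numeric(1))
  expect_true(all(diff(w) > 0))
  w_lo <- ci_gene(fit, "lo")$gamma_upper - ci_gene(fit, "lo")$gamma_lower
  w_hi <- ci_gene(fit, "hi")$gamma_upper - ci_gene(fit, "hi")$gamma_lower
  expect_lt(w_hi, w_lo)
  expect_error(ci_gene(fit, "lo", level = 1.2), "level")
  expect_error(ci_gene(fit, "nope"), "not present")
})

test_that("a gene absent from the eluate gets a flagged one-sided interval", {
  des <- design3()
  counts <- matrix(c(500L, 0L, 480L), nrow = 1,
                   dimnames = list("g1", des$sample))
  fit <- fit_modlevel(counts, des, fixed_norm = unit_norm(des),
                      fixed_theta = 100)
  expect_equal(fit$estimates$flag[1], "gamma_at_bound")
  ci <- ci_gene(fit, "g1")
  expect_equal(ci$gamma_lower, -20)
  expect_lt(ci$gamma_upper, 0)
  expect_match(ci$flags, "lower_at_bound")
  expect_match(ci$flags, "one_sided")
})

test_that("proportion-scale bounds are the transformed log-odds bounds", {
  sim <- quick_sim(n_genes = 5, seed = 93)
  fit <- fit_modlevel(sim$counts, sim$design, fixed_norm = sim$truth$norm,
                      fixed_theta = sim$truth$theta)
  ci <- ci_all(fit, level = 0.9)
  expect_equal(ci$alpha_lower, inv_logit(ci$gamma_lower))
  expect_equal(ci$alpha_upper, inv_logit(ci$gamma_upper))
  expect_true(all(ci$gamma_lower <= ci$gamma_hat &
                    ci$gamma_hat <= ci$gamma_upper))
})
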