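# Maximum-likelihood fitting of the fraction model by block coordinate
# ascent: per-gene (mu, gamma), shared per-fraction scale factors, shared
# NB size parameter. Sequencing-depth factors are estimated once up front
# (median-of-ratios within fractions) and held fixed throughout.

#' Fitting options
#'
#' @param max_outer maximum number of outer block-coordinate iterations.
#' @param rel_tol relative tolerance on the total log-likelihood used to
#'   declare convergence of the outer loop.
#' @param theta_init starting value for the shared NB size parameter.
#' @param spike_min_count minimum mean spike-in count for a spike-in to
#'   contribute to the spike-in-derived fraction scale factor.
#' @return a list of class `fit_options`.
#' @export
fit_options <- function(max_outer = 50L, rel_tol = 1e-8, theta_init = 100,
                        spike_min_count = 100) {
  if (max_outer < 1) stop("`max_outer` must be >= 1", call. = FALSE)
  if (rel_tol <= 0) stop("`rel_tol` must be positive", call. = FALSE)
  if (theta_init <= 0) stop("`theta_init` must be positive", call. = FALSE)
  structure(list(max_outer = as.integer(max_outer), rel_tol = rel_tol,
                 theta_init = theta_init, spike_min_count = spike_min_count),
            class = "fit_options")
}

#' Sequencing-depth factors by median-of-ratios within fractions
#'
#' Samples of the same fraction share the same expected composition, so
#' depth factors are computed among them with the median-of-ratios
#' construction: the per-gene reference is the geometric mean across the
#' fraction's samples (genes with any zero count excluded from the
#' reference), and a sample's factor is the median ratio of its counts to
#' the reference. Factors are rescaled to geometric mean 1 within each
#' fraction, so fraction-to-fraction scale is left entirely to the fraction
#' scale factors.
#'
#' @param counts integer count matrix (genes x samples).
#' @param design sample design `data.frame`.
#' @return named positive vector of depth factors, one per design sample.
#' @export
estimate_depth_factors <- function(counts, design) {
  design <- .validate_design(design)
  missing <- setdiff(design$sample, colnames(counts))
  if (length(missing) > 0) {
    stop("design samples missing from count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  depth <- stats::setNames(rep(NA_real_, nrow(design)), design$sample)
  for (f in unique(design$fraction)) {
    smp <- design$sample[design$fraction == f]
    sub <- counts[, smp, drop = FALSE]
    if (all(sub == 0)) {
      stop(sprintf("fraction '%s' has all-zero counts", f), call. = FALSE)
    }
    if (length(smp) == 1) {
      depth[smp] <- 1
      next
    }
    pos <- rowSums(sub == 0) == 0
    if (!any(pos)) {
      stop(sprintf(
        "no gene has positive counts in every sample of fraction '%s'", f),
        call. = FALSE)
    }
    ref <- exp(rowMeans(log(sub[pos, , drop = FALSE])))
    fac <- apply(sub[pos, , drop = FALSE], 2, function(col) {
      stats::median(col / ref)
    })
    fac <- fac / exp(mean(log(fac)))
    depth[smp] <- fac
  }
  depth
}

# moment-based starting values; counts are depth- and scale-normalized so
# the eluate/supernatant means estimate alpha*e^mu and (1-alpha)*e^mu
.init_gene <- function(counts_g, design, sf) {
  cn <- counts_g / sf
  is_in <- design$fraction == "input"
  a <- mean(cn[design$fraction == "eluate"])
  b <- mean(cn[design$fraction == "supernatant"])
  m0 <- if (any(is_in)) mean(cn[is_in]) else a + b
  m0 <- max(m0, 0.5)
  mu0 <- min(max(log(m0), MU_MIN), MU_MAX)
  p <- if (a + b > 0) a / (a + b) else 0.5
  p <- min(max(p, 1e-6), 1 - 1e-6)
  c(mu0, stats::qlogis(p))
}

#' Maximum-likelihood estimate of (mu, gamma) for one gene
#'
#' Bounded quasi-Newton (L-BFGS-B with analytic gradient) maximization of
#' the NB log-likelihood over the box `mu` in `[log(0.1), log(1e9)]`,
#' `gamma` in `[-20, 20]`, with normalization and dispersion held fixed.
#' A gene with all-zero counts is returned flagged and non-converged; a
#' gene empty in one fraction lands on the gamma box bound and is flagged.
#'
#' @param counts_g per-sample counts for one gene (named by sample id, or
#'   ordered as the design rows).
#' @param norm a [normalization_set()].
#' @param disp positive scalar NB size parameter.
#' @param design sample design `data.frame`.
#' @param init optional `c(mu, gamma)` starting values (defaults to the
#'   moment-based heuristic: `mu0` close to the log mean input count,
#'   `gamma0` the logit of the eluate share).
#' @return list with `mu`, `gamma`, `alpha`, `loglik`, `converged`, `flag`.
#' @export
fit_gene <- function(counts_g, norm, disp, design, init = NULL) {
  design <- .validate_design(design)
  if (!is.null(names(counts_g))) {
    idx <- match(design$sample, names(counts_g))
    if (any(is.na(idx))) {
      stop("named `counts_g` missing design samples", call. = FALSE)
    }
    counts_g <- counts_g[idx]
  }
  if (length(counts_g) != nrow(design)) {
    stop("`counts_g` must have one value per design sample", call. = FALSE)
  }
  sf <- .sample_factors(design, norm)
  .fit_gene_core(as.numeric(counts_g), design, sf, disp, init)
}

.fit_gene_core <- function(counts_g, design, sf, disp, init = NULL) {
  if (all(counts_g == 0)) {
    mu <- MU_MIN; gamma <- 0
    ll <- .nb_ll(counts_g, .gene_means(mu, gamma, design, NULL, sf), disp)
    return(list(mu = mu, gamma = gamma, alpha = stats::plogis(gamma),
                loglik = ll, converged = FALSE, flag = "all_zero"))
  }
  if (is.null(init)) init <- .init_gene(counts_g, design, sf)
  is_el <- design$fraction == "eluate"
  is_sup <- design$fraction == "supernatant"

  negll <- function(p) {
    m <- .gene_means(p[1], p[2], design, NULL, sf)
    -.nb_ll(counts_g, m, disp)
  }
  grad <- function(p) {
    a <- stats::plogis(p[2])
    m <- .gene_means(p[1], p[2], design, NULL, sf)
    r <- counts_g / m - (counts_g + disp) / (m + disp)  # d loglik / d mean
    dg <- numeric(length(m))
    dg[is_el] <- (1 - a)
    dg[is_sup] <- -a
    -c(sum(r * m), sum(r * m * dg))
  }
  opt <- stats::optim(init, negll, grad, method = "L-BFGS-B",
                      lower = c(MU_MIN, GAMMA_MIN),
                      upper = c(MU_MAX, GAMMA_MAX),
                      control = list(maxit = 200, factr = 1e5))
  # ascent guard: never leave a gene worse than its starting point
  v0 <- negll(init)
  if (opt$value > v0) {
    opt$par <- init
    opt$value <- v0
  }
  flag <- ""
  if (opt$par[2] <= GAMMA_MIN + 1e-6 || opt$par[2] >= GAMMA_MAX - 1e-6) {
    flag <- "gamma_at_bound"
  }
  list(mu = opt$par[1], gamma = opt$par[2],
       alpha = stats::plogis(opt$par[2]),
       loglik = -opt$value,
       converged = opt$convergence == 0,
       flag = flag)
}

# unit-scale mean matrix: depth * fraction_mean, i.e. expected counts at
# fraction scale factors of 1 (genes x design rows)
.base_mean_matrix <- function(mu, gamma, design, depth) {
  a <- stats::plogis(gamma)
  part <- matrix(1, nrow = length(mu), ncol = nrow(design))
  part[, design$fraction == "eluate"] <- a
  part[, design$fraction == "supernatant"] <- 1 - a
  d <- as.numeric(depth[design$sample])
  exp(mu) * part * rep(d, each = length(mu))
}

.mean_matrix <- function(mu, gamma, design, norm) {
  B <- .base_mean_matrix(mu, gamma, design, norm$depth)
  x <- as.numeric(norm$fraction_scale[design$fraction])
  B * rep(x, each = length(mu))
}

#' Fit the shared per-fraction scale factors (spike-in-free mode)
#'
#' With all gene parameters and the dispersion held fixed, maximizes the
#' total log-likelihood over the eluate and supernatant scale factors on
#' the log scale (L-BFGS-B with analytic gradient). The input fraction is
#' pinned to 1 as the identifiability reference; sharing the two factors
#' across all genes is what makes the spike-in-free model identifiable.
#'
#' @param counts integer count matrix aligned with `estimates` rows and
#'   `design` samples.
#' @param estimates `data.frame` with columns `mu_hat`, `gamma_hat` (one
#'   row per gene of `counts`).
#' @param disp positive scalar NB size parameter.
#' @param design sample design `data.frame`.
#' @param norm current [normalization_set()] (supplies depth factors and
#'   starting scale values).
#' @return an updated `normalization_set`.
#' @export
fit_fraction_factors <- function(counts, estimates, disp, design, norm) {
  design <- .validate_design(design)
  if (!any(design$fraction == "input")) {
    stop("spike-in-free normalization requires input-fraction samples",
         call. = FALSE)
  }
  if (nrow(counts) < 2) {
    stop("at least two genes are required to fit fraction scale factors",
         call. = FALSE)
  }
  non_in <- design$fraction != "input"
  dsub <- design[non_in, , drop = FALSE]
  y <- counts[, design$sample[non_in], drop = FALSE]
  B <- .base_mean_matrix(estimates$mu_hat, estimates$gamma_hat, dsub,
                         norm$depth)
  fidx <- ifelse(dsub$fraction == "eluate", 1L, 2L)
  G <- nrow(B)

  negll <- function(z) {
    m <- B * rep(exp(z)[fidx], each = G)
    -.nb_ll(y, m, disp)
  }
  grad <- function(z) {
    m <- B * rep(exp(z)[fidx], each = G)
    r <- (y / m - (y + disp) / (m + disp)) * m
    cs <- colSums(r)
    -c(sum(cs[fidx == 1L]), sum(cs[fidx == 2L]))
  }
  z0 <- log(c(norm$fraction_scale[["eluate"]],
              norm$fraction_scale[["supernatant"]]))
  opt <- stats::optim(z0, negll, grad, method = "L-BFGS-B",
                      lower = log(1e-6), upper = log(1e6),
                      control = list(maxit = 200, factr = 1e5))
  if (opt$value > negll(z0)) opt$par <- z0
  normalization_set(
    depth = norm$depth,
    fraction_scale = c(input = 1, eluate = exp(opt$par[1]),
                       supernatant = exp(opt$par[2])),
    reference = "input")
}

#' Fit the shared NB size parameter
#'
#' One-dimensional bounded search on `log(theta)` over
#' `[log(1e-3), log(1e12)]` with all other parameters fixed. Boundary
#' solutions are allowed and flagged.
#'
#' @inheritParams fit_fraction_factors
#' @param norm a [normalization_set()].
#' @return list with `theta` and `at_bound` flag.
#' @export
fit_dispersion <- function(counts, estimates, norm, design) {
  design <- .validate_design(design)
  M <- .mean_matrix(estimates$mu_hat, estimates$gamma_hat, design, norm)
  y <- counts[, design$sample, drop = FALSE]
  f <- function(lt) -.nb_ll(y, M, exp(lt))
  opt <- stats::optimize(f, c(log(THETA_MIN), log(THETA_MAX)), tol = 1e-7)
  theta <- exp(opt$minimum)
  at_bound <- opt$minimum < log(THETA_MIN) + 0.01 ||
    opt$minimum > log(THETA_MAX) - 0.01
  list(theta = theta, at_bound = at_bound)
}

.total_loglik <- function(counts, estimates, norm, design, theta) {
  M <- .mean_matrix(estimates$mu_hat, estimates$gamma_hat, design, norm)
  .nb_ll(counts[, design$sample, drop = FALSE], M, theta)
}

#' Fit the fraction model to a count table
#'
#' Block-coordinate maximum likelihood: per-gene `(mu, gamma)` are fitted
#' with normalization and dispersion fixed, then (in the spike-in-free
#' mode) the shared eluate/supernatant scale factors, then the shared NB
#' size parameter, iterating until the relative change in total
#' log-likelihood drops below `rel_tol`. Each block maximizes the same
#' total log-likelihood, so the trace is non-decreasing.
#'
#' Two modes are supported. Without spike-ins, input, eluate and
#' supernatant samples are all required; fraction scale factors are
#' inferred from the data with the input pinned to 1. With `spikeins`
#' supplied, input samples are ignored, the supernatant is the reference
#' fraction, and the eluate scale is computed once from the spike-in counts
#' (see [spikein_fraction_factor()]) and held fixed — no factor refitting.
#'
#' Initialization follows the moment heuristics: `mu0` close to the log of
#' the gene's mean (depth-normalized) input count, `gamma0` the logit of
#' the eluate share of eluate + supernatant, scale factors 1 and
#' `theta0 = 100`.
#'
#' @param counts integer count matrix (genes x samples, spike-in rows
#'   included in spike-in mode).
#' @param design sample design `data.frame`.
#' @param spikeins optional character vector of spike-in row ids; supplying
#'   it selects the spike-in mode.
#' @param options a [fit_options()] list.
#' @param fixed_norm optional [normalization_set()] to hold fixed (skips
#'   depth estimation and factor fitting; used e.g. in simulation studies
#'   with known truth).
#' @param fixed_theta optional fixed NB size parameter (skips dispersion
#'   fitting).
#' @param condition if the design has several conditions, the one to fit
#'   (conditions are always fitted independently).
#' @return an object of class `modlevel_fit`: per-gene estimates,
#'   normalization set, dispersion, log-likelihood trace, and convergence
#'   status.
#' @export
fit_modlevel <- function(counts, design, spikeins = NULL,
                         options = fit_options(),
                         fixed_norm = NULL, fixed_theta = NULL,
                         condition = NULL) {
  design <- .validate_design(design)
  counts <- .validate_counts(as.matrix(counts))
  conds <- unique(design$condition)
  if (!is.null(condition)) {
    if (!condition %in% conds) {
      stop(sprintf("condition '%s' not present in design", condition),
           call. = FALSE)
    }
    design <- design[design$condition == condition, , drop = FALSE]
  } else if (length(conds) > 1) {
    stop("design has several conditions (", paste(conds, collapse = ", "),
         "); fit them independently via `condition = `", call. = FALSE)
  }
  missing <- setdiff(design$sample, colnames(counts))
  if (length(missing) > 0) {
    stop("design samples missing from count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  mode <- if (is.null(spikeins)) "no_spikeins" else "spikeins"
  fr <- unique(design$fraction)
  if (mode == "no_spikeins") {
    if (!all(FRACTIONS %in% fr)) {
      stop("spike-in-free mode requires input, eluate and supernatant ",
           "samples; without an input fraction, supply spike-ins instead",
           call. = FALSE)
    }
  } else {
    if (!all(c("eluate", "supernatant") %in% fr)) {
      stop("spike-in mode requires eluate and supernatant samples",
           call. = FALSE)
    }
    if ("input" %in% fr) {
      message("spike-in mode: ignoring ", sum(design$fraction == "input"),
              " input sample(s)")
      design <- design[design$fraction != "input", , drop = FALSE]
    }
    spikeins <- intersect(spikeins, rownames(counts))
    if (length(spikeins) < 2) {
      stop("spike-in mode needs at least two spike-in rows in the count table",
           call. = FALSE)
    }
  }

  gene_ids <- setdiff(rownames(counts), spikeins)
  gcounts <- counts[gene_ids, design$sample, drop = FALSE]

  # depth factors: estimated once from gene rows, then held fixed
  if (!is.null(fixed_norm)) {
    norm <- fixed_norm
  } else {
    depth <- estimate_depth_factors(gcounts, design)
    if (mode == "no_spikeins") {
      norm <- normalization_set(depth,
                                c(input = 1, eluate = 1, supernatant = 1),
                                reference = "input")
    } else {
      norm <- spikein_fraction_factor(counts[, design$sample, drop = FALSE],
                                      design, spikeins, depth = depth,
                                      min_count = options$spike_min_count)
    }
  }
  fit_factors <- mode == "no_spikeins" && is.null(fixed_norm)
  theta <- if (is.null(fixed_theta)) options$theta_init else fixed_theta
  fit_theta <- is.null(fixed_theta)

  G <- nrow(gcounts)
  if (G == 0) stop("no gene rows to fit", call. = FALSE)
  est <- data.frame(gene_id = gene_ids,
                    mu_hat = NA_real_, gamma_hat = NA_real_,
                    alpha_hat = NA_real_, loglik = NA_real_,
                    converged = NA, flag = "",
                    stringsAsFactors = FALSE)
  inits <- vector("list", G)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  theta_flag <- FALSE
  n_iter <- 0L

  for (it in seq_len(options$max_outer)) {
    n_iter <- it
    sf <- .sample_factors(design, norm)
    for (g in seq_len(G)) {
      r <- .fit_gene_core(gcounts[g, ], design, sf, theta, inits[[g]])
      est$mu_hat[g] <- r$mu
      est$gamma_hat[g] <- r$gamma
      est$alpha_hat[g] <- r$alpha
      est$loglik[g] <- r$loglik
      est$converged[g] <- r$converged
      est$flag[g] <- r$flag
      inits[[g]] <- c(r$mu, r$gamma)
    }
    if (fit_factors) {
      norm <- fit_fraction_factors(gcounts, est, theta, design, norm)
    }
    if (fit_theta) {
      dres <- fit_dispersion(gcounts, est, norm, design)
      theta <- dres$theta
      theta_flag <- dres$at_bound
    }
    ll <- .total_loglik(gcounts, est, norm, design, theta)
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - ll_prev) < options$rel_tol * (abs(ll_prev) + 1e-8)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  if (!converged && options$max_outer > 1) {
    warning("outer loop reached max_outer without meeting rel_tol",
            call. = FALSE)
  }
  est$alpha_hat <- stats::plogis(est$gamma_hat)

  structure(list(estimates = est, norm = norm, theta = theta,
                 theta_at_bound = theta_flag, trace = trace,
                 mode = mode, design = design, counts = gcounts,
                 spikeins = spikeins, options = options,
                 converged = converged, n_iter = n_iter),
            class = "modlevel_fit")
}

#' @export
print.modlevel_fit <- function(x, ...) {
  cat("Fraction-model fit (", x$mode, ")\n", sep = "")
  cat("  genes:", nrow(x$estimates),
      " samples:", nrow(x$design), "\n")
  cat("  theta:", format(x$theta, digits = 4),
      if (x$theta_at_bound) "(at bound)" else "", "\n")
  cat("  fraction scale:",
      paste(names(x$norm$fraction_scale),
            format(unname(x$norm$fraction_scale), digits = 4),
            sep = "=", collapse = ", "), "\n")
  cat("  log-likelihood:", format(utils::tail(x$trace, 1), digits = 8),
      "after", x$n_iter, "outer iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
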