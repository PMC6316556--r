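# Profile-likelihood confidence intervals for the gene-specific
# parameters, with normalization factors and the NB size parameter held
# fixed (their uncertainty is deliberately neglected).

#' Profile log-likelihood of one gene at a fixed log-odds
#'
#' Maximizes the gene's NB log-likelihood over the expression parameter
#' `mu` while holding `gamma`, the normalization set and the dispersion
#' fixed. By construction it never exceeds the unconstrained per-gene
#' maximum.
#'
#' @param counts_g per-sample counts for one gene (named by sample id, or
#'   ordered as the design rows).
#' @param gamma fixed log-odds value.
#' @param norm a [normalization_set()].
#' @param disp positive scalar NB size parameter.
#' @param design sample design `data.frame`.
#' @return scalar profile log-likelihood.
#' @export
profile_loglik <- function(counts_g, gamma, norm, disp, design) {
  design <- .validate_design(design)
  if (!is.null(names(counts_g))) {
    counts_g <- counts_g[design$sample]
  }
  sf <- .sample_factors(design, norm)
  .profile_ll(as.numeric(counts_g), gamma, design, sf, disp)
}

.profile_ll <- function(counts_g, gamma, design, sf, disp) {
  f <- function(mu) {
    .nb_ll(counts_g, .gene_means(mu, gamma, design, NULL, sf), disp)
  }
  opt <- stats::optimize(f, c(MU_MIN, MU_MAX), maximum = TRUE, tol = 1e-9)
  opt$objective
}

#' Profile-likelihood confidence interval for one gene's log-odds
#'
#' The interval at confidence `level` contains the `gamma` values whose
#' deviance `2 * (llmax - profile(gamma))` stays below the chi-square
#' (1 df) quantile. Bounds are located by root finding outward from the
#' point estimate; if the profile never reaches the cutoff before the
#' parameter box bound, that side is reported at the bound and flagged
#' one-sided. Proportion-scale bounds are the (monotone) inverse-logit
#' transforms of the `gamma` bounds.
#'
#' @param fit a `modlevel_fit` object.
#' @param gene gene id present in the fit.
#' @param level confidence level in (0, 1), default 0.95.
#' @return one-row `data.frame`: `gene_id`, `level`, `gamma_hat`,
#'   `gamma_lower`, `gamma_upper`, `alpha_lower`, `alpha_upper`, `flags`.
#' @export
ci_gene <- function(fit, gene, level = 0.95) {
  if (!inherits(fit, "modlevel_fit")) {
    stop("`fit` must be a modlevel_fit object", call. = FALSE)
  }
  if (level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  g <- match(gene, fit$estimates$gene_id)
  if (is.na(g)) {
    stop(sprintf("gene '%s' not present in fit", gene), call. = FALSE)
  }
  counts_g <- as.numeric(fit$counts[gene, fit$design$sample])
  sf <- .sample_factors(fit$design, fit$norm)
  gh <- fit$estimates$gamma_hat[g]
  flags <- character(0)
  if (!isTRUE(fit$estimates$converged[g])) flags <- c(flags, "not_converged")
  if (nzchar(fit$estimates$flag[g])) flags <- c(flags, fit$estimates$flag[g])

  llmax <- max(.profile_ll(counts_g, gh, fit$design, sf, fit$theta),
               fit$estimates$loglik[g])
  cutoff <- stats::qchisq(level, df = 1)
  dev_excess <- function(gam) {
    2 * (llmax - .profile_ll(counts_g, gam, fit$design, sf, fit$theta)) -
      cutoff
  }

  side <- function(bound) {
    if (abs(gh - bound) < 1e-9) return(list(val = bound, at_bound = TRUE))
    if (dev_excess(bound) < 0) return(list(val = bound, at_bound = TRUE))
    root <- stats::uniroot(dev_excess, lower = min(gh, bound),
                           upper = max(gh, bound), tol = 1e-9)
    list(val = root$root, at_bound = FALSE)
  }
  lo <- side(GAMMA_MIN)
  hi <- side(GAMMA_MAX)
  if (lo$at_bound) flags <- c(flags, "lower_at_bound")
  if (hi$at_bound) flags <- c(flags, "upper_at_bound")
  if (xor(lo$at_bound, hi$at_bound)) flags <- c(flags, "one_sided")

  data.frame(gene_id = gene, level = level, gamma_hat = gh,
             gamma_lower = lo$val, gamma_upper = hi$val,
             alpha_lower = stats::plogis(lo$val),
             alpha_upper = stats::plogis(hi$val),
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Profile-likelihood intervals for many genes
#'
#' @param fit a `modlevel_fit` object.
#' @param genes gene ids (default: all genes in the fit).
#' @param level confidence level.
#' @return `data.frame` with one row per gene (see [ci_gene()]).
#' @export
ci_all <- function(fit, genes = NULL, level = 0.95) {
  if (is.null(genes)) genes <- fit$estimates$gene_id
  do.call(rbind, lapply(genes, function(g) ci_gene(fit, g, level)))
}
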