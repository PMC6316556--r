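# Generative model for fraction-separated modification-level counts:
# expected relative abundances per fraction, logit/proportion maps,
# and the shared-dispersion negative-binomial log-likelihood.

# Parameter boxes used everywhere in fitting. The gamma box keeps alpha
# strictly inside (0, 1) (~2e-9 from each edge) so genes with zero counts
# in one fraction land on a finite, flagged boundary instead of +/-Inf.
MU_MIN <- log(0.1)
MU_MAX <- log(1e9)
GAMMA_MIN <- -20
GAMMA_MAX <- 20
THETA_MIN <- 1e-3
THETA_MAX <- 1e12

FRACTIONS <- c("input", "eluate", "supernatant")

#' Log-odds (logit) of a modification proportion
#'
#' The modification level of a gene can be expressed either as the
#' proportion `alpha` of modified molecules in the original RNA pool,
#' `alpha` in (0, 1), or as its log-odds `gamma = log(alpha / (1 - alpha))`.
#' Fitting is carried out on the unbounded log-odds scale; the proportion is
#' a derived, reported quantity (see [inv_logit()]).
#'
#' @param alpha numeric vector of proportions, strictly inside (0, 1).
#' @return numeric vector of log-odds.
#' @examples
#' logit(0.5)            # 0
#' inv_logit(logit(0.9)) # 0.9
#' @seealso [inv_logit()]
#' @export
logit <- function(alpha) {
  if (!is.numeric(alpha)) {
    stop("`alpha` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::qlogis(alpha)
}

#' Inverse logit (logistic) map from log-odds to proportion
#'
#' @param gamma numeric vector of log-odds.
#' @return numeric vector of proportions in (0, 1).
#' @export
inv_logit <- function(gamma) {
  if (!is.numeric(gamma)) {
    stop("`gamma` must be numeric", call. = FALSE)
  }
  stats::plogis(gamma)
}

#' Gene-specific model parameters
#'
#' Bundles the two gene-level parameters of the fraction model: `mu`, the
#' natural log of the expected input-fraction read count, and `gamma`, the
#' log-odds of modification. Values must lie inside the fitting boxes
#' (`mu` in `[log(0.1), log(1e9)]`, `gamma` in `[-20, 20]`).
#'
#' @param mu numeric, log expected input-fraction count.
#' @param gamma numeric, log-odds of modification (same length as `mu`).
#' @return an object of class `gene_params` (list with `mu`, `gamma`).
#' @export
gene_params <- function(mu, gamma) {
  if (!is.numeric(mu) || !is.numeric(gamma) || length(mu) != length(gamma)) {
    stop("`mu` and `gamma` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(mu)) || any(mu < MU_MIN) || any(mu > MU_MAX)) {
    stop(sprintf("`mu` must be finite and within [%.4f, %.4f]",
                 MU_MIN, MU_MAX), call. = FALSE)
  }
  if (any(!is.finite(gamma)) || any(gamma < GAMMA_MIN) ||
      any(gamma > GAMMA_MAX)) {
    stop(sprintf("`gamma` must be within [%g, %g]", GAMMA_MIN, GAMMA_MAX),
         call. = FALSE)
  }
  structure(list(mu = mu, gamma = gamma), class = "gene_params")
}

.as_gene_params <- function(params) {
  if (inherits(params, "gene_params")) return(params)
  if (is.list(params) && all(c("mu", "gamma") %in% names(params))) {
    return(gene_params(params$mu, params$gamma))
  }
  stop("`params` must be a gene_params object or a list with mu and gamma",
       call. = FALSE)
}

#' Expected relative abundance of a gene in one fraction
#'
#' The model for a high-efficiency separation without cross-contamination:
#' the input pool has expected abundance `exp(mu)`, of which a proportion
#' `alpha = inv_logit(gamma)` is pulled into the eluate and `1 - alpha`
#' remains in the supernatant:
#' \deqn{E[input] = e^{\mu},\quad
#'       E[eluate] = e^{\mu}\frac{e^{\gamma}}{1+e^{\gamma}},\quad
#'       E[supernatant] = \frac{e^{\mu}}{1+e^{\gamma}}.}
#' Eluate and supernatant means always add up to the input mean.
#'
#' @param params a [gene_params()] object (vectorized over genes).
#' @param fraction one of `"input"`, `"eluate"`, `"supernatant"`.
#' @return numeric vector of positive expected abundances.
#' @export
fraction_mean <- function(params, fraction) {
  params <- .as_gene_params(params)
  fraction <- match.arg(fraction, FRACTIONS)
  m <- exp(params$mu)
  switch(fraction,
         input = m,
         eluate = m * stats::plogis(params$gamma),
         supernatant = m * stats::plogis(-params$gamma))
}

#' Normalization factors for depth and fraction scale
#'
#' Holds per-sample sequencing-depth factors together with per-fraction
#' multiplicative scale factors. One fraction is pinned to 1 as the
#' identifiability reference: the input fraction in the spike-in-free mode,
#' the supernatant in the spike-in mode.
#'
#' @param depth named positive numeric vector, one entry per sample.
#' @param fraction_scale named positive numeric vector with names among
#'   `input`, `eluate`, `supernatant`.
#' @param reference fraction whose scale is required to equal 1.
#' @return an object of class `normalization_set`.
#' @export
normalization_set <- function(depth, fraction_scale,
                              reference = c("input", "supernatant")) {
  reference <- match.arg(reference)
  if (is.null(names(depth)) || any(!nzchar(names(depth)))) {
    stop("`depth` must be a named vector (names = sample ids)", call. = FALSE)
  }
  if (any(!is.finite(depth)) || any(depth <= 0)) {
    stop("all depth factors must be positive and finite", call. = FALSE)
  }
  if (is.null(names(fraction_scale)) ||
      !all(names(fraction_scale) %in% FRACTIONS)) {
    stop("`fraction_scale` names must be among input/eluate/supernatant",
         call. = FALSE)
  }
  if (any(!is.finite(fraction_scale)) || any(fraction_scale <= 0)) {
    stop("all fraction scale factors must be positive and finite",
         call. = FALSE)
  }
  if (!reference %in% names(fraction_scale)) {
    stop(sprintf("reference fraction '%s' missing from `fraction_scale`",
                 reference), call. = FALSE)
  }
  if (abs(fraction_scale[[reference]] - 1) > 1e-12) {
    stop(sprintf("reference fraction '%s' must have scale factor 1",
                 reference), call. = FALSE)
  }
  structure(list(depth = depth, fraction_scale = fraction_scale,
                 reference = reference),
            class = "normalization_set")
}

# depth * fraction-scale multiplier for every row of the design
.sample_factors <- function(design, norm) {
  d <- norm$depth[design$sample]
  if (any(is.na(d))) {
    stop("samples in design missing from normalization depth factors: ",
         paste(design$sample[is.na(d)], collapse = ", "), call. = FALSE)
  }
  x <- norm$fraction_scale[design$fraction]
  if (any(is.na(x))) {
    stop("fractions in design missing from normalization scale factors: ",
         paste(unique(design$fraction[is.na(x)]), collapse = ", "),
         call. = FALSE)
  }
  unname(d * x)
}

# per-sample expected counts of one gene, vectorized over design rows;
# `sf` (precomputed sample factors) avoids repeated name lookups in hot loops
.gene_means <- function(mu, gamma, design, norm,
                        sf = .sample_factors(design, norm)) {
  a <- stats::plogis(gamma)
  part <- rep(1, nrow(design))
  part[design$fraction == "eluate"] <- a
  part[design$fraction == "supernatant"] <- 1 - a
  sf * exp(mu) * part
}

#' Expected read count of a gene in one sample
#'
#' Composes the fraction mean with the sample's sequencing-depth factor and
#' the per-fraction scale factor:
#' `depth[sample] * fraction_scale[fraction] * fraction_mean(params, fraction)`.
#'
#' @param params a [gene_params()] object.
#' @param sample a sample id present in `design` and `norm`.
#' @param norm a [normalization_set()].
#' @param design a sample design `data.frame` (see [read_design()]).
#' @return positive expected read count.
#' @export
predicted_mean <- function(params, sample, norm, design) {
  i <- match(sample, design$sample)
  if (is.na(i)) {
    stop(sprintf("sample '%s' not present in design", sample), call. = FALSE)
  }
  if (!sample %in% names(norm$depth)) {
    stop(sprintf("sample '%s' has no depth factor", sample), call. = FALSE)
  }
  fraction <- design$fraction[i]
  norm$depth[[sample]] * norm$fraction_scale[[fraction]] *
    fraction_mean(params, fraction)
}

# unvalidated hot path
.nb_ll <- function(counts, means, size) {
  sum(stats::dnbinom(counts, mu = means, size = size, log = TRUE))
}

#' Negative-binomial log-likelihood with shared size parameter
#'
#' Sum of NB log-probabilities for observed counts given expected means and
#' a single size (overdispersion) parameter `theta`, in the size--mean
#' convention `Var = m + m^2 / theta`. Large `theta` approaches the Poisson
#' limit.
#'
#' @param counts non-negative integer vector.
#' @param means positive numeric vector, same length as `counts`.
#' @param size positive scalar NB size parameter.
#' @return scalar log-likelihood.
#' @export
nb_loglik <- function(counts, means, size) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  if (length(counts) != length(means)) {
    stop("`counts` and `means` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop("`means` must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(size) || length(size) != 1 || !is.finite(size) ||
      size <= 0) {
    stop("`size` must be a positive scalar", call. = FALSE)
  }
  .nb_ll(counts, means, size)
}
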