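# Synthetic fraction-separated count tables with known ground truth:
# NB-distributed counts with shared overdispersion, per-sample depth
# factors, per-fraction scale factors, gene-level modification
# proportions, and unmodified spike-ins added post-IP in equal amounts
# to eluate and supernatant.

#' Simulation configuration
#'
#' Defaults describe a desk-scale study emulating a fractionation
#' experiment: 500 genes whose expected input counts are log-uniform on
#' \[100, 10000\], modification proportions uniform on (0.02, 0.98)
#' (optionally Beta), shared NB size 100, per-sample depth factors
#' log-uniform on \[0.5, 2\], unit fraction scale factors and two
#' replicates per fraction. Spike-ins (off by default) are unmodified,
#' appear only in eluate and supernatant, and carry a mild lognormal
#' abundance perturbation (sd 0.1 on the log scale, mean-preserving)
#' emulating pipetting/composition variability on top of counting noise.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per fraction.
#' @param count_range range of expected input-fraction counts; `mu` is
#'   drawn log-uniformly over it.
#' @param alpha_range range of the uniform modification-proportion draw.
#' @param alpha_beta optional `c(shape1, shape2)` to draw proportions from
#'   a Beta distribution instead.
#' @param theta shared NB size parameter of the generator.
#' @param depth_range per-sample depth factors are drawn log-uniformly
#'   over this range.
#' @param fraction_scale named `c(eluate = , supernatant = )` scale
#'   factors (input is the unit reference).
#' @param n_spikeins number of spike-in rows (0 disables spike-ins).
#' @param spike_count_range range of expected spike-in counts
#'   (log-uniform).
#' @param spike_log_sd sd of the mean-preserving lognormal perturbation of
#'   spike-in abundances per sample.
#' @param fractions fractions to simulate.
#' @param condition condition label written to the design.
#' @param seed integer seed; fully determines the output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, n_replicates = 2L,
                       count_range = c(100, 10000),
                       alpha_range = c(0.02, 0.98),
                       alpha_beta = NULL,
                       theta = 100,
                       depth_range = c(0.5, 2),
                       fraction_scale = c(eluate = 1, supernatant = 1),
                       n_spikeins = 0L,
                       spike_count_range = c(100, 10000),
                       spike_log_sd = 0.1,
                       fractions = c("input", "eluate", "supernatant"),
                       condition = "sim1",
                       seed = NULL) {
  if (n_genes < 1) stop("`n_genes` must be >= 1", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (theta <= 0) stop("`theta` must be positive", call. = FALSE)
  if (any(count_range <= 0) || diff(count_range) < 0) {
    stop("`count_range` must be positive and non-decreasing", call. = FALSE)
  }
  if (any(alpha_range <= 0) || any(alpha_range >= 1)) {
    stop("`alpha_range` must lie inside (0, 1)", call. = FALSE)
  }
  if (!is.null(alpha_beta) &&
      (length(alpha_beta) != 2 || any(alpha_beta <= 0))) {
    stop("`alpha_beta` must be two positive shape parameters", call. = FALSE)
  }
  if (any(depth_range <= 0)) {
    stop("`depth_range` must be positive", call. = FALSE)
  }
  if (!all(c("eluate", "supernatant") %in% names(fraction_scale)) ||
      any(fraction_scale <= 0)) {
    stop("`fraction_scale` needs positive eluate and supernatant entries",
         call. = FALSE)
  }
  fractions <- match.arg(fractions, FRACTIONS, several.ok = TRUE)
  if (n_spikeins > 0 &&
      !all(c("eluate", "supernatant") %in% fractions)) {
    stop("spike-ins require eluate and supernatant fractions", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 count_range = count_range, alpha_range = alpha_range,
                 alpha_beta = alpha_beta, theta = theta,
                 depth_range = depth_range,
                 fraction_scale = fraction_scale,
                 n_spikeins = as.integer(n_spikeins),
                 spike_count_range = spike_count_range,
                 spike_log_sd = spike_log_sd,
                 fractions = fractions, condition = condition,
                 seed = seed),
            class = "sim_config")
}

#' Draw negative-binomial counts
#'
#' Thin wrapper around the size--mean NB sampler
#' (`Var = mean + mean^2 / size`); large `size` approaches Poisson
#' sampling.
#'
#' @param n number of draws.
#' @param mean positive expected count (recycled).
#' @param size positive NB size parameter.
#' @return integer vector of non-negative counts.
#' @export
sample_nb <- function(n, mean, size) {
  if (any(mean <= 0)) stop("`mean` must be positive", call. = FALSE)
  if (size <= 0) stop("`size` must be positive", call. = FALSE)
  stats::rnbinom(n, mu = mean, size = size)
}

#' Simulate a fraction-separated count table with known truth
#'
#' Generates, per gene and sample, `count ~ NB(mean = depth * scale *
#' fraction_mean(mu, gamma, fraction), size = theta)`. Spike-in rows are
#' unmodified and absent from the input fraction (zero counts there):
#' their expected depth-scaled abundance is equal in eluate and
#' supernatant, emulating equal-amount addition right after the IP, up to
#' the per-sample lognormal perturbation of `spike_log_sd`. The seed in
#' the configuration fully determines the output.
#'
#' @param config a [sim_config()].
#' @return list of class `modlevel_sim` with `counts` (integer matrix,
#'   spike rows last), `design` (`data.frame`), and `truth` (per-gene
#'   `mu`/`gamma`/`alpha`, the true [normalization_set()], `theta`, and
#'   spike-in abundances).
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must come from sim_config()", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_genes
  mu <- stats::runif(n, log(config$count_range[1]),
                     log(config$count_range[2]))
  alpha <- if (is.null(config$alpha_beta)) {
    stats::runif(n, config$alpha_range[1], config$alpha_range[2])
  } else {
    stats::rbeta(n, config$alpha_beta[1], config$alpha_beta[2])
  }
  alpha <- pmin(pmax(alpha, 1e-8), 1 - 1e-8)
  gamma <- stats::qlogis(alpha)
  gene_ids <- sprintf("gene_%04d", seq_len(n))

  design <- expand.grid(replicate = paste0("rep", seq_len(config$n_replicates)),
                        fraction = config$fractions,
                        stringsAsFactors = FALSE)
  design$sample <- paste(design$fraction, design$replicate, sep = "_")
  design$condition <- config$condition
  design <- design[, c("sample", "fraction", "replicate", "condition")]
  S <- nrow(design)

  depth <- stats::setNames(
    exp(stats::runif(S, log(config$depth_range[1]),
                     log(config$depth_range[2]))),
    design$sample)
  xs <- c(input = 1,
          eluate = unname(config$fraction_scale[["eluate"]]),
          supernatant = unname(config$fraction_scale[["supernatant"]]))
  x <- xs[design$fraction]

  part <- matrix(1, nrow = n, ncol = S)
  part[, design$fraction == "eluate"] <- alpha
  part[, design$fraction == "supernatant"] <- 1 - alpha
  M <- exp(mu) * part * rep(unname(depth) * unname(x), each = n)
  counts <- matrix(stats::rnbinom(n * S, mu = as.vector(M),
                                  size = config$theta),
                   nrow = n, ncol = S,
                   dimnames = list(gene_ids, design$sample))

  spike_truth <- NULL
  if (config$n_spikeins > 0) {
    ns <- config$n_spikeins
    spike_ids <- sprintf("SPIKE-%04d", seq_len(ns))
    ab <- exp(stats::runif(ns, log(config$spike_count_range[1]),
                           log(config$spike_count_range[2])))
    smat <- matrix(0L, nrow = ns, ncol = S,
                   dimnames = list(spike_ids, design$sample))
    post_ip <- design$fraction %in% c("eluate", "supernatant")
    for (j in which(post_ip)) {
      noise <- exp(stats::rnorm(ns, -config$spike_log_sd^2 / 2,
                                config$spike_log_sd))
      m <- ab * noise * unname(depth)[j] * unname(x)[j]
      smat[, j] <- stats::rnbinom(ns, mu = m, size = config$theta)
    }
    counts <- rbind(counts, smat)
    spike_truth <- data.frame(spike_id = spike_ids, abundance = ab,
                              stringsAsFactors = FALSE)
  }
  storage.mode(counts) <- "integer"

  truth <- list(
    gene = data.frame(gene_id = gene_ids, mu = mu, gamma = gamma,
                      alpha = alpha, stringsAsFactors = FALSE),
    norm = normalization_set(depth,
                             c(input = 1,
                               eluate = xs[["eluate"]],
                               supernatant = xs[["supernatant"]]),
                             reference = "input"),
    theta = config$theta,
    spikes = spike_truth)

  structure(list(counts = counts, design = design, truth = truth,
                 config = config),
            class = "modlevel_sim")
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `<prefix>_counts.tsv`, `<prefix>_design.tsv`,
#' `<prefix>_truth.tsv` and, when spike-ins are present,
#' `<prefix>_spikeins.txt` — the same formats the readers accept.
#'
#' @param sim a `modlevel_sim` object.
#' @param prefix output path prefix.
#' @return invisibly, the vector of written paths.
#' @export
write_sim <- function(sim, prefix) {
  if (!inherits(sim, "modlevel_sim")) {
    stop("`sim` must come from simulate_dataset()", call. = FALSE)
  }
  paths <- c(counts = paste0(prefix, "_counts.tsv"),
             design = paste0(prefix, "_design.tsv"),
             truth = paste0(prefix, "_truth.tsv"))
  write_counts(sim$counts, paths["counts"])
  write_design(sim$design, paths["design"])
  utils::write.table(sim$truth$gene, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$spikes)) {
    paths["spikeins"] <- paste0(prefix, "_spikeins.txt")
    writeLines(sim$truth$spikes$spike_id, paths["spikeins"])
  }
  invisible(paths)
}
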