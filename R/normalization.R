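# Spike-in-based normalization between the eluate and supernatant
# fractions, and the LAIC-seq ratio estimator used as a baseline.
# Unmodified spike-ins (e.g., ERCC mixes) added in equal amounts to both
# fractions after the IP anchor the cross-fraction scale.

#' Spike-in set
#'
#' @param ids character vector of spike-in row identifiers.
#' @param min_count minimum mean read count for a spike-in to qualify.
#' @return a list of class `spikein_set`.
#' @export
spikein_set <- function(ids, min_count = 100) {
  ids <- unique(as.character(ids))
  if (length(ids) == 0) stop("spike-in id list is empty", call. = FALSE)
  structure(list(ids = ids, min_count = min_count), class = "spikein_set")
}

.as_spikein_set <- function(spikes, min_count = 100) {
  if (inherits(spikes, "spikein_set")) return(spikes)
  spikein_set(spikes, min_count)
}

#' Eluate/supernatant scale factor from post-IP spike-ins
#'
#' Because equal amounts of unmodified spike-ins are added to both
#' fractions right after the IP, the ratio of their depth-normalized
#' counts measures the relative library scale of the two fractions
#' directly, with no fitting. The supernatant is the reference fraction
#' (scale 1) and the eluate scale is the geometric mean, over qualifying
#' spike-ins, of depth-normalized eluate over supernatant counts — the
#' multiplier that the model applies to eluate expected counts. The
#' geometric mean (rather than a total-count ratio) keeps one dominant
#' spike-in from driving the factor.
#'
#' @param counts count matrix containing the spike-in rows.
#' @param design sample design `data.frame` with eluate and supernatant
#'   samples.
#' @param spikes a [spikein_set()] or character vector of spike-in ids.
#' @param depth optional named per-sample depth factors (default: all 1).
#' @param min_count qualification threshold on the mean raw count across
#'   eluate and supernatant samples (used when `spikes` is a bare id
#'   vector).
#' @return a [normalization_set()] with `supernatant = 1` as reference.
#' @export
spikein_fraction_factor <- function(counts, design, spikes, depth = NULL,
                                    min_count = 100) {
  design <- .validate_design(design)
  spikes <- .as_spikein_set(spikes, min_count)
  el <- design$sample[design$fraction == "eluate"]
  sup <- design$sample[design$fraction == "supernatant"]
  if (length(el) == 0 || length(sup) == 0) {
    stop("spike-in normalization needs eluate and supernatant samples",
         call. = FALSE)
  }
  present <- intersect(spikes$ids, rownames(counts))
  if (length(present) < 2) {
    stop("fewer than two spike-in ids present in the count table",
         call. = FALSE)
  }
  if (is.null(depth)) {
    depth <- stats::setNames(rep(1, nrow(design)), design$sample)
  }
  sm <- counts[present, c(el, sup), drop = FALSE]
  qual <- rowMeans(sm) >= spikes$min_count
  e_norm <- rowMeans(sweep(counts[present, el, drop = FALSE], 2,
                           depth[el], "/"))
  s_norm <- rowMeans(sweep(counts[present, sup, drop = FALSE], 2,
                           depth[sup], "/"))
  keep <- qual & e_norm > 0 & s_norm > 0
  if (sum(keep) < 2) {
    stop(sprintf(
      "fewer than two spike-ins pass min_count = %g with nonzero counts",
      spikes$min_count), call. = FALSE)
  }
  x_el <- exp(mean(log(e_norm[keep] / s_norm[keep])))
  normalization_set(depth,
                    c(eluate = unname(x_el), supernatant = 1),
                    reference = "supernatant")
}

#' LAIC-seq cross-fraction intercept from spike-in counts
#'
#' Estimates the log2-scale intercept `R` relating supernatant to eluate
#' counts from spike-ins with at least `min_count` reads in both fractions.
#' The default dialect fixes the regression slope to 1, so `R` is the mean
#' log2 eluate/supernatant ratio and `2^R` has an exact scale-factor
#' interpretation; `dialect = "free_slope"` instead fits an ordinary
#' least-squares regression of log2 eluate on log2 supernatant counts and
#' reports its intercept.
#'
#' @param spike_eluate spike-in counts in the eluate sample.
#' @param spike_supernatant spike-in counts in the supernatant sample,
#'   aligned to the same spike-in ids.
#' @param min_count qualification threshold (counts below it, or zero, are
#'   excluded pairwise).
#' @param dialect `"slope1"` (default) or `"free_slope"`.
#' @return a list of class `laic_fit` with `R`, `slope`, `n_used`,
#'   `dialect`.
#' @export
laicseq_R <- function(spike_eluate, spike_supernatant, min_count = 100,
                      dialect = c("slope1", "free_slope")) {
  dialect <- match.arg(dialect)
  if (length(spike_eluate) != length(spike_supernatant)) {
    stop("spike-in count vectors must be aligned (equal length)",
         call. = FALSE)
  }
  keep <- spike_eluate >= min_count & spike_supernatant >= min_count &
    spike_eluate > 0 & spike_supernatant > 0
  if (sum(keep) < 2) {
    stop(sprintf("fewer than two spike-ins with at least %g counts in both fractions",
                 min_count), call. = FALSE)
  }
  le <- log2(spike_eluate[keep])
  ls <- log2(spike_supernatant[keep])
  if (dialect == "slope1") {
    R <- mean(le - ls)
    slope <- 1
  } else {
    cf <- stats::coef(stats::lm(le ~ ls))
    R <- unname(cf[1])
    slope <- unname(cf[2])
  }
  structure(list(R = R, slope = slope, n_used = sum(keep), dialect = dialect),
            class = "laic_fit")
}

#' LAIC-seq ratio estimate of the modification proportion
#'
#' The baseline ratio estimator: with eluate count `E`, supernatant count
#' `S` and cross-fraction intercept `R` (log2 scale, from spike-ins),
#' the modification level is `E / (E + S * 2^R)`. Invariant under joint
#' rescaling of `E` and `S`; genes with `E = S = 0` are reported `NA`.
#'
#' @param E eluate counts (vectorized).
#' @param S supernatant counts.
#' @param R log2-scale intercept (see [laicseq_R()]).
#' @return modification proportions in `[0, 1]` (or `NA`).
#' @export
laicseq_m6a <- function(E, S, R) {
  if (any(E < 0, na.rm = TRUE) || any(S < 0, na.rm = TRUE)) {
    stop("`E` and `S` must be non-negative", call. = FALSE)
  }
  out <- E / (E + S * 2^R)
  out[E == 0 & S == 0] <- NA_real_
  out
}

#' Per-gene LAIC-seq estimates for a whole count table
#'
#' For every replicate pair (one eluate and one supernatant sample with
#' matching replicate label within a condition), the intercept `R` is
#' fitted from the raw spike-in counts of that pair, and the ratio
#' estimator is applied to every gene of the pair. Gene-level summaries
#' average the per-pair proportions.
#'
#' @param counts count matrix containing gene and spike-in rows.
#' @param design sample design `data.frame`.
#' @param spikeins character vector (or [spikein_set()]) of spike-in ids.
#' @param min_count spike-in qualification threshold.
#' @param dialect regression dialect passed to [laicseq_R()].
#' @return list of class `laicseq_estimates` with elements `pairs`
#'   (per-pair `R` fits), `per_replicate` (genes x pairs matrix of
#'   proportions), and `gene` (`data.frame` with `gene_id`, `alpha_laic`).
#' @export
laicseq_estimate <- function(counts, design, spikeins, min_count = 100,
                             dialect = c("slope1", "free_slope")) {
  dialect <- match.arg(dialect)
  design <- .validate_design(design)
  spikes <- .as_spikein_set(spikeins, min_count)
  present <- intersect(spikes$ids, rownames(counts))
  if (length(present) < 2) {
    stop("fewer than two spike-in ids present in the count table",
         call. = FALSE)
  }
  gene_ids <- setdiff(rownames(counts), present)
  el <- design[design$fraction == "eluate", , drop = FALSE]
  sup <- design[design$fraction == "supernatant", , drop = FALSE]
  key_el <- paste(el$condition, el$replicate)
  key_sup <- paste(sup$condition, sup$replicate)
  keys <- intersect(key_el, key_sup)
  if (length(keys) == 0) {
    stop("no eluate/supernatant replicate pairs found in design",
         call. = FALSE)
  }
  pairs <- data.frame(condition = character(0), replicate = character(0),
                      eluate_sample = character(0),
                      supernatant_sample = character(0),
                      R = numeric(0), slope = numeric(0),
                      n_used = integer(0), stringsAsFactors = FALSE)
  amat <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(keys),
                 dimnames = list(gene_ids, keys))
  for (k in keys) {
    es <- el$sample[key_el == k][1]
    ss <- sup$sample[key_sup == k][1]
    fitR <- laicseq_R(counts[present, es], counts[present, ss],
                      min_count = spikes$min_count, dialect = dialect)
    amat[, k] <- laicseq_m6a(counts[gene_ids, es], counts[gene_ids, ss],
                             fitR$R)
    i <- which(key_el == k)[1]
    pairs <- rbind(pairs, data.frame(
      condition = el$condition[i], replicate = el$replicate[i],
      eluate_sample = es, supernatant_sample = ss,
      R = fitR$R, slope = fitR$slope, n_used = fitR$n_used,
      stringsAsFactors = FALSE))
  }
  gene <- data.frame(gene_id = gene_ids,
                     alpha_laic = rowMeans(amat, na.rm = TRUE),
                     stringsAsFactors = FALSE)
  gene$alpha_laic[is.nan(gene$alpha_laic)] <- NA_real_
  structure(list(pairs = pairs, per_replicate = amat, gene = gene,
                 dialect = dialect),
            class = "laicseq_estimates")
}
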