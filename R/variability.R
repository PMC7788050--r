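#' Count differentially methylated CpG sites between two groups
#'
#' A site is differentially methylated (a "DMR" in the single-CpG
#' sense) when its group-mean beta values differ by at least
#' `threshold` (boundary inclusive; default 0.3). Missing values are
#' excluded from the group means; a probe with no non-missing value in
#' either group is skipped and logged.
#'
#' @param betaA,betaB Beta sub-matrices for the two groups, same probe
#'   rows in the same order.
#' @param threshold Absolute beta-difference cut, default 0.3.
#' @return Integer count of differential sites.
#' @export
dmr_count <- function(betaA, betaB, threshold = 0.3) {
  if (!identical(rownames(betaA), rownames(betaB)))
    stopf("the two groups must share one probe set in the same order")
  mA <- rowMeans(betaA, na.rm = TRUE)
  mB <- rowMeans(betaB, na.rm = TRUE)
  skip <- !is.finite(mA) | !is.finite(mB)
  if (any(skip))
    message(sprintf("dmr_count: %d probe(s) all-missing in a group, skipped",
                    sum(skip)))
  sum(abs(mA - mB)[!skip] >= threshold)
}

## Shared container for subsample-resampling statistics.
new_resampling_result <- function(statistic, values, n_per_group, reps) {
  structure(list(statistic = statistic, n_per_group = n_per_group,
                 reps = reps, values = values, mean = mean(values),
                 sem = stats::sd(values) / sqrt(reps)),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("%s over %d resamples of %d samples/group: mean %.2f (SEM %.3f)\n",
              x$statistic, x$reps, x$n_per_group, x$mean, x$sem))
  invisible(x)
}

#' Resampled mean number of differential sites between two pools
#'
#' Repeatedly draws `n` samples without replacement from each pool,
#' counts differential sites between the two draws with [dmr_count()],
#' and reports the mean and SEM over replicates. This controls for the
#' unequal pool sizes when comparing, e.g., ESC and iPSC lines.
#'
#' @param beta Beta matrix.
#' @param groupA_samples,groupB_samples Column ids of the two pools
#'   (each at least `n`).
#' @param n Samples drawn per pool per replicate, default 15.
#' @param reps Replicates, default 100.
#' @param threshold Beta-difference cut, default 0.3.
#' @param seed Optional integer seed.
#' @return A `resampling_result` (per-rep `values`, `mean`, `sem`).
#' @export
resampled_dmr_mean <- function(beta, groupA_samples, groupB_samples,
                               n = 15, reps = 100, threshold = 0.3,
                               seed = NULL) {
  if (length(groupA_samples) < n || length(groupB_samples) < n)
    stopf("both pools must hold at least n = %d samples", n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  values <- vapply(seq_len(reps), function(i) {
    a <- sample(groupA_samples, n)
    b <- sample(groupB_samples, n)
    dmr_count(beta[, a, drop = FALSE], beta[, b, drop = FALSE],
              threshold = threshold)
  }, numeric(1))
  new_resampling_result("dmr_count", values, n, reps)
}

#' Resampled histogram of per-probe methylation SD
#'
#' Repeatedly draws `n` samples from a pool, computes each probe's
#' standard deviation of beta across the draw, and bins the SDs.
#' Reported are the mean count per bin (with SEM) across replicates and
#' the mean number of "high-SD" probes at `high_sd_threshold`. The last
#' bin is open-ended so per-replicate bin counts sum to the number of
#' probes with a defined SD.
#'
#' @param beta Beta matrix.
#' @param sample_pool Column ids to draw from (at least `n`).
#' @param n Samples per draw, default 15.
#' @param reps Replicates, default 100.
#' @param breaks Bin edges over SD; default `seq(0, 0.5, by = 0.05)`.
#' @param high_sd_threshold SD cut for the high-variability count,
#'   default 0.10.
#' @param seed Optional integer seed.
#' @return An `sd_histogram`: list with `bins` (data frame `bin_low`,
#'   `bin_high`, `mean_count`, `sem`), `high_sd_threshold`,
#'   `high_sd_mean_count`, `high_sd_sem`, `n_per_draw`, `reps`.
#' @export
sd_range_histogram <- function(beta, sample_pool, n = 15, reps = 100,
                               breaks = seq(0, 0.5, by = 0.05),
                               high_sd_threshold = 0.10, seed = NULL) {
  if (length(sample_pool) < n)
    stopf("sample pool must hold at least n = %d samples", n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  edges <- c(breaks, Inf)
  nb <- length(edges) - 1L
  counts <- matrix(0, reps, nb)
  high <- numeric(reps)
  for (i in seq_len(reps)) {
    sub <- beta[, sample(sample_pool, n), drop = FALSE]
    sds <- row_sds(sub)
    sds <- sds[!is.na(sds)]
    counts[i, ] <- tabulate(findInterval(sds, edges,
                                         rightmost.closed = FALSE), nb)
    high[i] <- sum(sds >= high_sd_threshold)
  }
  bins <- data.frame(
    bin_low = edges[-length(edges)], bin_high = edges[-1],
    mean_count = colMeans(counts),
    sem = apply(counts, 2, stats::sd) / sqrt(reps))
  structure(list(bins = bins, high_sd_threshold = high_sd_threshold,
                 high_sd_mean_count = mean(high),
                 high_sd_sem = stats::sd(high) / sqrt(reps),
                 n_per_draw = n, reps = reps),
            class = "sd_histogram")
}

#' @export
print.sd_histogram <- function(x, ...) {
  cat(sprintf(
    "SD histogram over %d resamples of %d samples; mean count at SD >= %g: %.1f (SEM %.2f)\n",
    x$reps, x$n_per_draw, x$high_sd_threshold, x$high_sd_mean_count,
    x$high_sd_sem))
  print(x$bins, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Resampled count of variably methylated sites within one cell type
#'
#' Repeatedly draws `n` samples of a single cell type and counts probes
#' whose beta range (max minus min across the draw) is at least
#' `range_threshold` — sites that fluctuate between lines of the same
#' type.
#'
#' @param beta Beta matrix.
#' @param samples_of_one_type Column ids of one cell type.
#' @param n Samples per draw, default 15.
#' @param reps Replicates, default 100.
#' @param range_threshold Beta-range cut, default 0.3.
#' @param seed Optional integer seed.
#' @return A `resampling_result`.
#' @export
within_type_variable_count <- function(beta, samples_of_one_type, n = 15,
                                       reps = 100, range_threshold = 0.3,
                                       seed = NULL) {
  if (length(samples_of_one_type) < n)
    stopf("pool must hold at least n = %d samples", n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  values <- vapply(seq_len(reps), function(i) {
    sub <- beta[, sample(samples_of_one_type, n), drop = FALSE]
    rng <- row_max(sub) - row_min(sub)
    sum(rng >= range_threshold, na.rm = TRUE)
  }, numeric(1))
  new_resampling_result("variable_site_count", values, n, reps)
}

#' Per-site, per-group methylation profiles
#'
#' Tabulates beta values at selected sites grouped by cell type,
#' derivation method or parental cell, with per-site per-group
#' summaries (n, min, max, mean, SD). Grouping by derivation method
#' partitions the iPSC lines by how they were reprogrammed.
#'
#' @param beta Beta matrix.
#' @param sites Probe ids to profile.
#' @param sheet Sample sheet covering the columns of `beta`.
#' @param grouping One of `"cell_type"`, `"derivation_method"`,
#'   `"parental_cell"`.
#' @return A `site_profile` list: `values` (long data frame `probe_id`,
#'   `sample_id`, `group`, `beta`) and `summary` (per probe x group).
#' @export
site_methylation_profile <- function(beta, sites, sheet,
                                     grouping = c("cell_type",
                                                  "derivation_method",
                                                  "parental_cell")) {
  grouping <- match.arg(grouping)
  miss <- setdiff(sites, rownames(beta))
  if (length(miss) > 0)
    stopf("site(s) absent from beta matrix: %s",
          paste(utils::head(miss, 3), collapse = ", "))
  if (!grouping %in% names(sheet))
    stopf("sheet lacks grouping column '%s'", grouping)
  grp <- stats::setNames(as.character(sheet[[grouping]]),
                         sheet$sample_id)[colnames(beta)]
  sub <- beta[sites, , drop = FALSE]
  values <- data.frame(
    probe_id = rep(sites, times = ncol(sub)),
    sample_id = rep(colnames(sub), each = length(sites)),
    group = rep(grp, each = length(sites)),
    beta = as.vector(sub), stringsAsFactors = FALSE)
  values <- values[!is.na(values$group), , drop = FALSE]
  summ <- do.call(rbind, lapply(split(values, list(values$probe_id,
                                                   values$group),
                                      drop = TRUE), function(d) {
    data.frame(probe_id = d$probe_id[1], group = d$group[1],
               n = sum(!is.na(d$beta)),
               min = suppressWarnings(min(d$beta, na.rm = TRUE)),
               max = suppressWarnings(max(d$beta, na.rm = TRUE)),
               mean = mean(d$beta, na.rm = TRUE),
               sd = stats::sd(d$beta[!is.na(d$beta)]),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$probe_id, summ$group), , drop = FALSE]
  structure(list(grouping = grouping, values = values, summary = summ),
            class = "site_profile")
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("Methylation profile of %d site(s) grouped by %s\n",
              length(unique(x$values$probe_id)), x$grouping))
  print(utils::head(x$summary, 12), row.names = FALSE, digits = 3)
  if (nrow(x$summary) > 12) cat(sprintf("  ... %d more rows\n",
                                        nrow(x$summary) - 12))
  invisible(x)
}
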