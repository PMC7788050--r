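#' Configuration for the synthetic methylome cohort
#'
#' Defines the study conditions the generator emulates: a 104-sample
#' cohort (27 ESC, 43 iPSC, 9 ECC, 25 somatic lines, one sample per
#' line), with probe archetypes planted among `n_probes` CpG sites:
#'
#' * `pluripotency_hypo` — unmethylated in pluripotent cells
#'   (ESC/iPSC/ECC), methylated in somatic cells, like promoters of
#'   pluripotency-associated genes;
#' * `somatic_hypo` — the reverse, like somatic-gene promoters;
#' * `class_marker_ECC` — methylated only in ECC lines;
#' * `ipsc_variable` — low methylation in ESC/ECC/somatic but a
#'   line-specific level drawn widely on `[0.05, 0.95]` in each iPSC
#'   line (stochastic, reprogramming-associated aberrant
#'   hypermethylation; these probes form the iPSC-positive signature);
#' * `ipsc_variable_hypo` — the mirrored flavour: methylated in
#'   ESC/ECC/somatic, line-specific wide levels in iPSC lines
#'   (incomplete erasure / aberrant hypomethylation);
#' * `esc_variable` — equal class means but inflated noise in ESC
#'   lines (the higher genome-wide background variability of ESCs);
#' * the remainder is neutral: a common bimodal-ish mean per probe,
#'   identical across classes.
#'
#' Beta noise is Beta-distributed with the archetype's class mean and a
#' per-class concentration, so variance shrinks near 0 and 1 as on
#' arrays. `n_maf_fail` and `n_detp_fail` neutral probes are spiked to
#' fail the MAF and detection-p filters.
#'
#' @param n_probes Number of probes, default 20000.
#' @param class_sizes Named cohort sizes, default
#'   `c(ESC = 27, iPSC = 43, ECC = 9, somatic = 25)`.
#' @param archetype_fractions Named fractions of probes per planted
#'   archetype (remainder neutral).
#' @param noise_concentration Per-class Beta concentration; ESC is
#'   lower (noisier) by default.
#' @param esc_variable_concentration ESC concentration at
#'   `esc_variable` probes (much noisier), default 5.
#' @param ipsc_variable_range Range of the per-line uniform draw for
#'   iPSC levels at `ipsc_variable` probes.
#' @param ipsc_variable_low_mean Mean of the non-iPSC classes at
#'   `ipsc_variable` probes, default 0.10.
#' @param n_maf_fail,n_detp_fail Numbers of filter-spike probes.
#' @param seed Default generator seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_probes = 20000,
                          class_sizes = c(ESC = 27, iPSC = 43, ECC = 9,
                                          somatic = 25),
                          archetype_fractions = c(pluripotency_hypo = 0.02,
                                                  somatic_hypo = 0.02,
                                                  ipsc_variable = 0.05,
                                                  ipsc_variable_hypo = 0.008,
                                                  esc_variable = 0.075,
                                                  class_marker_ECC = 0.012),
                          noise_concentration = c(ESC = 120, iPSC = 150,
                                                  ECC = 150, somatic = 150),
                          esc_variable_concentration = 10,
                          ipsc_variable_range = c(0.05, 0.95),
                          ipsc_variable_low_mean = 0.10,
                          n_maf_fail = 100, n_detp_fail = 80,
                          seed = 20200401) {
  if (!all(names(class_sizes) %in% .CELL_TYPES) ||
      length(class_sizes) != 4)
    stopf("class_sizes must name the four cell types")
  if (any(class_sizes < 5))
    stopf("class sizes below 5 break the resampling operations")
  if (sum(archetype_fractions) > 1)
    stopf("archetype fractions must sum to at most 1")
  n_arch <- floor(archetype_fractions * n_probes)
  if (n_maf_fail + n_detp_fail > n_probes - sum(n_arch))
    stopf("not enough neutral probes for the filter spikes")
  structure(list(n_probes = as.integer(n_probes),
                 class_sizes = class_sizes[.CELL_TYPES],
                 archetype_fractions = archetype_fractions,
                 noise_concentration = noise_concentration[.CELL_TYPES],
                 esc_variable_concentration = esc_variable_concentration,
                 ipsc_variable_range = ipsc_variable_range,
                 ipsc_variable_low_mean = ipsc_variable_low_mean,
                 n_maf_fail = as.integer(n_maf_fail),
                 n_detp_fail = as.integer(n_detp_fail),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## Archetype -> per-class target mean table; the iPSC means of the two
## line-variable archetypes are line-specific (the recorded truth mean
## is the centre of the draw).
archetype_means <- function(config) {
  lo <- config$ipsc_variable_low_mean
  hi <- 1 - lo
  centre <- mean(config$ipsc_variable_range)
  rbind(
    pluripotency_hypo  = c(ESC = 0.08, iPSC = 0.08, ECC = 0.08, somatic = 0.85),
    somatic_hypo       = c(ESC = 0.85, iPSC = 0.85, ECC = 0.85, somatic = 0.12),
    ipsc_variable      = c(ESC = lo, iPSC = centre, ECC = lo, somatic = lo),
    ipsc_variable_hypo = c(ESC = hi, iPSC = centre, ECC = hi, somatic = hi),
    esc_variable       = c(ESC = 0.30, iPSC = 0.30, ECC = 0.30, somatic = 0.30),
    class_marker_ECC   = c(ESC = 0.15, iPSC = 0.15, ECC = 0.90, somatic = 0.15)
  )
}

## Beta draw with mean m and concentration nu, clamped away from 0/1 so
## shapes stay positive.
rbeta_mc <- function(n, m, nu) {
  m <- pmin(pmax(m, 0.01), 0.99)
  stats::rbeta(n, m * nu, (1 - m) * nu)
}

#' Generate a synthetic methylome cohort with ground truth
#'
#' Draws a beta matrix, sample sheet (with stratified fold groups),
#' probe annotation, detection-p matrix and a per-probe truth table
#' from a [cohort_config()]. `ipsc_variable` probes are enriched near
#' transcription start sites and CpG islands in the annotation; spike
#' probes destined for removal by the MAF and detection-p filters are
#' flagged in the truth table.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to `config$seed`); a fixed seed
#'   reproduces the cohort bit-exactly.
#' @return A list `beta`, `sheet`, `annotation`, `detp`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  set.seed(as.integer(seed))
  p <- config$n_probes
  sizes <- config$class_sizes
  probe_ids <- sprintf("cg%08d", sample.int(99999999L, p))
  sample_ids <- unlist(lapply(.CELL_TYPES, function(ct)
    sprintf("%s_%02d", ct, seq_len(sizes[[ct]]))))
  ct_of <- rep(.CELL_TYPES, times = sizes)

  ## archetype layout
  n_arch <- floor(config$archetype_fractions * p)
  archetype <- rep("neutral", p)
  pos <- 1L
  for (a in names(n_arch)) {
    archetype[pos:(pos + n_arch[[a]] - 1L)] <- a
    pos <- pos + n_arch[[a]]
  }
  ## filter spikes among neutral probes
  neutral_idx <- which(archetype == "neutral")
  spike <- sample(neutral_idx, config$n_maf_fail + config$n_detp_fail)
  maf_fail_idx <- spike[seq_len(config$n_maf_fail)]
  detp_fail_idx <- spike[config$n_maf_fail + seq_len(config$n_detp_fail)]

  ## per-probe per-class target means
  am <- archetype_means(config)
  means <- matrix(NA_real_, p, 4, dimnames = list(NULL, .CELL_TYPES))
  for (a in rownames(am)) {
    idx <- archetype == a
    means[idx, ] <- matrix(am[a, .CELL_TYPES], sum(idx), 4, byrow = TRUE)
  }
  nm <- 0.02 + 0.96 * stats::rbeta(sum(archetype == "neutral"), 0.3, 0.3)
  means[archetype == "neutral", ] <- matrix(nm, sum(archetype == "neutral"), 4)

  beta <- matrix(NA_real_, p, length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (ct in .CELL_TYPES) {
    cols <- which(ct_of == ct)
    nu <- rep(config$noise_concentration[[ct]], p)
    if (ct == "ESC") nu[archetype == "esc_variable"] <-
        config$esc_variable_concentration
    m <- means[, ct]
    beta[, cols] <- rbeta_mc(p * length(cols), rep(m, length(cols)),
                             rep(nu, length(cols)))
  }
  ## line-specific iPSC levels at the two variable-in-iPSC archetypes
  iv <- which(archetype %in% c("ipsc_variable", "ipsc_variable_hypo"))
  if (length(iv) > 0) {
    ipsc_cols <- which(ct_of == "iPSC")
    line_means <- matrix(stats::runif(length(iv) * length(ipsc_cols),
                                      config$ipsc_variable_range[1],
                                      config$ipsc_variable_range[2]),
                         length(iv), length(ipsc_cols))
    nu_ipsc <- config$noise_concentration[["iPSC"]]
    beta[iv, ipsc_cols] <- rbeta_mc(length(line_means),
                                    as.vector(line_means), nu_ipsc)
  }

  ## sample sheet with stratified fold groups
  derivation <- ifelse(ct_of == "iPSC",
                       sample(c("Retro", "Sendai", "Episomal", "Lenti"),
                              length(ct_of), replace = TRUE,
                              prob = c(0.35, 0.3, 0.25, 0.1)),
                       "none")
  parental <- ifelse(ct_of == "iPSC",
                     sample(c("fibroblast", "PBMC"), length(ct_of),
                            replace = TRUE, prob = c(0.7, 0.3)),
                     NA_character_)
  sheet <- data.frame(sample_id = sample_ids, cell_type = ct_of,
                      fold_group = NA_character_,
                      derivation_method = derivation,
                      parental_cell = parental, stringsAsFactors = FALSE)
  sheet <- assign_fold_groups(sheet, seed = derive_seed(seed, 9L))

  ## annotation: ipsc_variable probes enriched near TSS/1stExon/Island
  gene_base_p <- c(TSS1500 = 0.13, TSS200 = 0.10, `5'UTR` = 0.12,
                   `1stExon` = 0.07, Body = 0.35, `3'UTR` = 0.04,
                   intergenic = 0.19)
  gene_iv_p <- c(TSS1500 = 0.25, TSS200 = 0.30, `5'UTR` = 0.08,
                 `1stExon` = 0.20, Body = 0.15, `3'UTR` = 0.02,
                 intergenic = 0.00)
  cgi_base_p <- c(Island = 0.31, N_Shore = 0.13, S_Shore = 0.11,
                  N_Shelf = 0.05, S_Shelf = 0.05, OpenSea = 0.35)
  cgi_iv_p <- c(Island = 0.70, N_Shore = 0.12, S_Shore = 0.08,
                N_Shelf = 0.02, S_Shelf = 0.02, OpenSea = 0.06)
  g1 <- character(p)
  is_iv <- archetype %in% c("ipsc_variable", "ipsc_variable_hypo")
  g1[!is_iv] <- sample(names(gene_base_p), sum(!is_iv), replace = TRUE,
                       prob = gene_base_p)
  g1[is_iv] <- sample(names(gene_iv_p), sum(is_iv), replace = TRUE,
                      prob = gene_iv_p)
  groups <- g1
  second <- stats::runif(p) < 0.15 & g1 != "intergenic"
  if (any(second)) {
    alt <- vapply(g1[second], function(g)
      sample(setdiff(setdiff(names(gene_base_p), "intergenic"), g), 1),
      character(1))
    groups[second] <- paste(g1[second], alt, sep = ";")
  }
  cgi <- character(p)
  cgi[!is_iv] <- sample(names(cgi_base_p), sum(!is_iv), replace = TRUE,
                        prob = cgi_base_p)
  cgi[is_iv] <- sample(names(cgi_iv_p), sum(is_iv), replace = TRUE,
                       prob = cgi_iv_p)
  chroms <- c(as.character(1:22), "X")
  chr_w <- c(22:1, 8) + 4
  maf <- rep(NA_real_, p)
  has_maf <- stats::runif(p) < 0.30
  maf[has_maf] <- stats::runif(sum(has_maf), 0, 0.049)
  maf[maf_fail_idx] <- stats::runif(length(maf_fail_idx), 0.05, 0.5)
  annotation <- data.frame(
    probe_id = probe_ids,
    chromosome = sample(chroms, p, replace = TRUE, prob = chr_w),
    gene_feature_groups = groups,
    cgi_relation = cgi,
    maf = maf, stringsAsFactors = FALSE)

  ## detection p values: clean background, spikes fail in one sample
  detp <- matrix(stats::runif(p * length(sample_ids), 0, 0.005),
                 p, length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  fail_col <- sample.int(length(sample_ids), length(detp_fail_idx),
                         replace = TRUE)
  detp[cbind(detp_fail_idx, fail_col)] <-
    stats::runif(length(detp_fail_idx), 0.05, 1)

  truth <- data.frame(
    probe_id = probe_ids, archetype = archetype,
    mean_ESC = means[, "ESC"], mean_iPSC = means[, "iPSC"],
    mean_ECC = means[, "ECC"], mean_somatic = means[, "somatic"],
    maf_fail = seq_len(p) %in% maf_fail_idx,
    detp_fail = seq_len(p) %in% detp_fail_idx,
    stringsAsFactors = FALSE)
  attr(truth, "config") <- config
  attr(truth, "seed") <- as.integer(seed)

  list(beta = beta, sheet = sheet, annotation = annotation, detp = detp,
       truth = truth)
}

#' Labeled prediction pairs reproducing the published confusion table
#'
#' A deterministic fixture of 104 (true, predicted) cell-type pairs
#' whose confusion matrix equals the published test-set counts
#' (25,2,0,0 / 3,40,0,0 / 0,0,8,1 / 0,0,0,25), for exercising the
#' evaluation module end to end.
#'
#' @return Data frame with columns `true` and `predicted`, 104 rows.
#' @export
generate_toy_confusion_cohort <- function() {
  counts <- matrix(c(25, 2, 0, 0,
                     3, 40, 0, 0,
                     0, 0, 8, 1,
                     0, 0, 0, 25), 4, 4, byrow = TRUE,
                   dimnames = list(.CELL_TYPES, .CELL_TYPES))
  rows <- list()
  for (i in .CELL_TYPES) for (j in .CELL_TYPES) {
    k <- counts[i, j]
    if (k > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        true = rep(i, k), predicted = rep(j, k), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
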