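## Small in-code fixtures shared across test files.

## A beta matrix with given dims and deterministic content.
make_beta <- function(p = 6, n = 4, seed = 1,
                      probes = sprintf("cg%08d", seq_len(p)),
                      samples = sprintf("s%02d", seq_len(n))) {
  set.seed(seed)
  matrix(round(runif(p * n), 6), p, n, dimnames = list(probes, samples))
}

## A minimal valid sample sheet for the given cell-type vector.
make_sheet <- function(cell_types, fold_groups = NULL,
                       sample_ids = sprintf("s%02d",
                                            seq_along(cell_types))) {
  sheet <- data.frame(
    sample_id = sample_ids,
    cell_type = cell_types,
    fold_group = if (is.null(fold_groups)) NA_character_ else fold_groups,
    derivation_method = ifelse(cell_types == "iPSC", "Retro", "none"),
    parental_cell = NA_character_,
    stringsAsFactors = FALSE)
  if (is.null(fold_groups)) sheet <- assign_fold_groups(sheet, seed = 7)
  sheet
}

## Annotation covering the given probes with constant categories.
make_annotation <- function(probes, maf = NA_real_,
                            gene = "Body", cgi = "OpenSea", chrom = "1") {
  data.frame(probe_id = probes, chromosome = chrom,
             gene_feature_groups = gene, cgi_relation = cgi,
             maf = maf, stringsAsFactors = FALSE)
}

## A small linearly separable two-class problem built from a known
## linear rule, so separability holds by construction.
make_separable_toy <- function(p = 5, n = 16, seed = 42) {
  set.seed(seed)
  w_true <- c(2, -2, 1.5, 0, 0)[seq_len(p)]
  x <- matrix(runif(p * n), p, n,
              dimnames = list(sprintf("cg%08d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  margin <- drop(crossprod(x, w_true)) - mean(crossprod(x, w_true))
  ## keep only samples clear of the boundary so a real margin exists
  keepers <- abs(margin) > 0.25
  x <- x[, keepers, drop = FALSE]
  y <- ifelse(margin[keepers] > 0, "ESC", "iPSC")
  list(x = x, y = y)
}

## Tiny synthetic cohort for fast pipeline-level tests.
tiny_cohort <- function(seed = 5, n_probes = 400) {
  cfg <- cohort_config(
    n_probes = n_probes,
    class_sizes = c(ESC = 8, iPSC = 12, ECC = 5, somatic = 7),
    n_maf_fail = 8, n_detp_fail = 6)
  generate_cohort(cfg, seed = seed)
}
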