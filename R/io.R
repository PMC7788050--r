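#' Read a GenomeStudio-style beta-value matrix
#'
#' Reads a tab-separated probe-by-sample table of methylation rates
#' (beta values). The first column must be named `TargetID` and hold
#' Illumina probe identifiers; remaining columns are samples. Missing
#' cells are written `NA` and preserved as `NA`.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix (probes x samples) with `TargetID` rownames
#'   and sample-id colnames; all non-missing values lie in `[0, 1]`.
#' @seealso [write_beta_matrix()], [filter_probes()]
#' @export
read_beta_matrix <- function(path) {
  read_probe_sample_matrix(path, what = "beta value")
}

#' Read a detection p-value matrix
#'
#' Same layout as the beta matrix ([read_beta_matrix()]): `TargetID`
#' first column, one column per sample, values in `[0, 1]`. High values
#' flag probe measurements indistinguishable from background.
#'
#' @inheritParams read_beta_matrix
#' @return Numeric matrix aligned like a beta matrix.
#' @export
read_detection_p <- function(path) {
  read_probe_sample_matrix(path, what = "detection p value")
}

read_probe_sample_matrix <- function(path, what) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA", colClasses = NA)
  if (ncol(df) < 2 || names(df)[1] != "TargetID")
    stopf("malformed header in %s: first column must be 'TargetID'", path)
  probes <- as.character(df[[1]])
  samples <- names(df)[-1]
  if (anyDuplicated(probes))
    stopf("duplicate TargetID in %s: %s", path,
          paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stopf("duplicate sample id in %s: %s", path,
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric %s cells in %s", what, path)
  dimnames(m) <- list(probes, samples)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("%s out of [0,1] at probe %s, sample %s (value %g)", what,
          probes[bad[1, 1]], samples[bad[1, 2]], m[bad[1, , drop = FALSE]])
  m
}

#' Write a beta matrix as tab-separated text
#'
#' Values are written with 17 significant digits so that a
#' write-then-read round trip reproduces the matrix bit-exactly.
#'
#' @param beta Numeric probes-x-samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta, range_check = FALSE)
  chr <- matrix(formatC(beta, digits = 17, format = "g"),
                nrow = nrow(beta))
  chr[is.na(beta)] <- "NA"
  out <- cbind(TargetID = rownames(beta), chr)
  colnames(out) <- c("TargetID", colnames(beta))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate a beta matrix
#'
#' Checks the container invariants: numeric matrix, unique probe and
#' sample ids, and (optionally) all non-missing values in `[0, 1]`.
#' Called by the readers; exported for use on matrices built in code.
#'
#' @param beta Matrix to validate.
#' @param range_check Check the `[0, 1]` value range (default `TRUE`).
#' @return `beta`, invisibly; errors describe the first violation.
#' @export
validate_beta_matrix <- function(beta, range_check = TRUE) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stopf("beta matrix must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stopf("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta))) stopf("duplicate probe ids")
  if (anyDuplicated(colnames(beta))) stopf("duplicate sample ids")
  if (range_check) {
    bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stopf("beta value out of [0,1] at probe %s, sample %s",
            rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]])
  }
  invisible(beta)
}

#' Restrict beta matrices to their common probe set
#'
#' Arrays of different designs (450K, EPIC) share only part of their
#' probe content; downstream analysis uses the intersection. Probes are
#' returned in lexicographic TargetID order for determinism.
#'
#' @param matrices A list of beta matrices (or a single matrix).
#' @return A list of matrices, each restricted to the shared, sorted
#'   probe set; sample columns untouched.
#' @export
intersect_common_probes <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(matrices) < 1) stopf("need at least one matrix")
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0) stopf("no probes common to all matrices")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Remove probes failing MAF or detection-p quality criteria
#'
#' A probe is eliminated when its interrogated sequence overlaps a
#' variant with minor allele frequency at or above `maf_threshold`, or
#' when its detection p value is at or above `detp_threshold` in any
#' sample (a probe must be reliable in every sample to be kept). Both
#' boundaries are inclusive. Probes without an annotation row are kept
#' on the MAF criterion (absence of evidence) and logged.
#'
#' @param beta Beta matrix.
#' @param annotation Probe annotation data frame ([read_annotation()]).
#' @param detp Detection p-value matrix aligned with `beta`.
#' @param maf_threshold MAF cut, default 0.05 (5%).
#' @param detp_threshold Detection-p cut, default 0.05.
#' @return The beta matrix restricted to surviving probes, in input
#'   order, with a `filter_log` attribute listing counts removed per
#'   criterion.
#' @export
filter_probes <- function(beta, annotation, detp,
                          maf_threshold = 0.05, detp_threshold = 0.05) {
  validate_beta_matrix(beta)
  probes <- rownames(beta)
  if (!is.null(detp)) {
    if (!identical(dim(detp), dim(beta)) ||
        !identical(rownames(detp), probes) ||
        !identical(colnames(detp), colnames(beta)))
      stopf("detection-p matrix is not aligned with the beta matrix")
  }
  maf <- annotation$maf[match(probes, annotation$probe_id)]
  n_unannotated <- sum(is.na(match(probes, annotation$probe_id)))
  maf_fail <- !is.na(maf) & maf >= maf_threshold
  detp_fail <- if (is.null(detp)) rep(FALSE, length(probes)) else
    rowSums(detp >= detp_threshold, na.rm = TRUE) > 0
  drop <- maf_fail | detp_fail
  log <- list(n_input = length(probes),
              n_maf_removed = sum(maf_fail),
              n_detp_removed = sum(detp_fail),
              n_removed = sum(drop),
              n_kept = sum(!drop),
              n_unannotated = n_unannotated)
  message(sprintf(
    "filter_probes: removed %d/%d probes (MAF >= %g: %d; detection p >= %g in any sample: %d; unannotated, kept on MAF: %d)",
    log$n_removed, log$n_input, maf_threshold, log$n_maf_removed,
    detp_threshold, log$n_detp_removed, n_unannotated))
  out <- beta[!drop, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

#' Read and validate a sample sheet
#'
#' Tab-separated with columns `sample_id`, `cell_type`, `fold_group`,
#' `derivation_method` and optionally `parental_cell`. Tokens are
#' case-sensitive: cell types in `ESC, iPSC, ECC, somatic`; fold groups
#' `A`-`D`; derivation methods `Retro, Sendai, Episomal, Lenti, none`
#' (non-iPSC lines carry `none`).
#'
#' @param path Path to the sheet.
#' @param require_folds Require every row to carry a fold group
#'   (default `TRUE`; set `FALSE` for sheets awaiting
#'   [assign_fold_groups()]).
#' @return A data frame, one row per sample.
#' @export
read_sample_sheet <- function(path, require_folds = TRUE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_sample_sheet(df, require_folds = require_folds)
}

#' Validate a sample sheet data frame
#'
#' @param sheet Data frame with the sample-sheet columns.
#' @param require_folds Require fold groups to be set.
#' @return The validated sheet, invisibly usable.
#' @export
validate_sample_sheet <- function(sheet, require_folds = TRUE) {
  needed <- c("sample_id", "cell_type", "fold_group", "derivation_method")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols) > 0)
    stopf("sample sheet lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stopf("duplicate sample_id in sheet")
  bad <- setdiff(unique(sheet$cell_type), .CELL_TYPES)
  if (length(bad) > 0)
    stopf("unknown cell_type token(s) %s; allowed: %s",
          paste(bad, collapse = ", "), paste(.CELL_TYPES, collapse = ", "))
  fg <- sheet$fold_group
  if (require_folds && anyNA(fg))
    stopf("fold_group missing for %d sample(s)", sum(is.na(fg)))
  bad <- setdiff(unique(fg[!is.na(fg)]), .FOLD_GROUPS)
  if (length(bad) > 0)
    stopf("unknown fold_group token(s) %s; allowed: %s",
          paste(bad, collapse = ", "), paste(.FOLD_GROUPS, collapse = ", "))
  dm <- sheet$derivation_method
  bad <- setdiff(unique(dm[!is.na(dm)]), .DERIVATION_METHODS)
  if (length(bad) > 0)
    stopf("unknown derivation_method token(s) %s; allowed: %s",
          paste(bad, collapse = ", "),
          paste(.DERIVATION_METHODS, collapse = ", "))
  nonipsc <- sheet$cell_type != "iPSC" & !is.na(dm) & dm != "none"
  if (any(nonipsc))
    stopf("non-iPSC sample(s) with a derivation method: %s",
          paste(sheet$sample_id[nonipsc], collapse = ", "))
  sheet
}

#' Write a sample sheet
#' @param sheet Sample-sheet data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a probe annotation table
#'
#' Tab-separated with columns `probe_id`, `chromosome`,
#' `gene_feature_groups` (semicolon-joined subset of TSS1500, TSS200,
#' 5'UTR, 1stExon, Body, 3'UTR, intergenic), `cgi_relation` (Island,
#' N_Shore, S_Shore, N_Shelf, S_Shelf, OpenSea) and `maf` (minor allele
#' frequency in `[0, 0.5]`, `NA` when unknown).
#'
#' @param path Path to the table.
#' @return A data frame, one row per probe.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_annotation(df)
}

#' Validate a probe annotation data frame
#' @param annotation Data frame with the annotation columns.
#' @return The validated annotation.
#' @export
validate_annotation <- function(annotation) {
  needed <- c("probe_id", "chromosome", "gene_feature_groups",
              "cgi_relation", "maf")
  missing_cols <- setdiff(needed, names(annotation))
  if (length(missing_cols) > 0)
    stopf("annotation lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (anyDuplicated(annotation$probe_id)) stopf("duplicate probe_id")
  groups <- strsplit(annotation$gene_feature_groups, ";", fixed = TRUE)
  if (any(lengths(groups) == 0) || anyNA(annotation$gene_feature_groups))
    stopf("gene_feature_groups must be non-empty (intergenic probes carry 'intergenic')")
  bad <- setdiff(unique(unlist(groups)), .GENE_FEATURES)
  if (length(bad) > 0)
    stopf("unknown gene feature group(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(annotation$cgi_relation), .CGI_RELATIONS)
  if (length(bad) > 0)
    stopf("unknown cgi_relation token(s): %s", paste(bad, collapse = ", "))
  maf <- annotation$maf
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5)))
    stopf("maf outside [0, 0.5]")
  annotation
}

#' Write a probe annotation table
#' @param annotation Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
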