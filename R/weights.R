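#' Combine ESC and iPSC determination weights into one table
#'
#' Determination weights across class models of one learned model are
#' directly comparable, so the ESC and iPSC weight lists are combined
#' into a single table for joint ranking.
#'
#' @param model An `arow_model`.
#' @param classes Which class models to combine (default ESC and iPSC).
#' @return A data frame with columns `class`, `probe_id`, `weight`, one
#'   row per (class, probe).
#' @export
extract_weight_table <- function(model, classes = c("ESC", "iPSC")) {
  stopifnot(inherits(model, "arow_model"))
  bad <- setdiff(classes, model$classes)
  if (length(bad) > 0)
    stopf("class(es) not in model: %s", paste(bad, collapse = ", "))
  do.call(rbind, lapply(classes, function(cl) {
    data.frame(class = cl, probe_id = model$probe_ids,
               weight = model$mu[, cl], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Select top-K positive and bottom-K negative high-weight sites
#'
#' Ranks the combined weight table jointly across its classes and cuts
#' the `K` largest weights (positive high-weight sites) and the `K`
#' smallest (negative high-weight sites). Ties at the cutoff are broken
#' deterministically by class order (ESC before iPSC) then lexicographic
#' probe id.
#'
#' @param table Weight table from [extract_weight_table()].
#' @param K Selection size per sign, default 2000.
#' @param series_id Optional series label carried on the result.
#' @return A `high_weight_selection`: list with `K`, `series_id`,
#'   `positive` and `negative` data frames (class, probe_id, weight).
#' @export
select_high_weight <- function(table, K = 2000, series_id = NA_integer_) {
  if (K > nrow(table))
    stopf("K = %d exceeds the %d entries in the weight table", K, nrow(table))
  class_rank <- match(table$class, .CELL_TYPES)
  pos_ord <- order(-table$weight, class_rank, table$probe_id)
  neg_ord <- order(table$weight, class_rank, table$probe_id)
  pos <- table[pos_ord[seq_len(K)], , drop = FALSE]
  neg <- table[neg_ord[seq_len(K)], , drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  structure(list(K = K, series_id = series_id,
                 positive = pos, negative = neg),
            class = "high_weight_selection")
}

#' @export
print.high_weight_selection <- function(x, ...) {
  cat(sprintf("High-weight selection (K = %d%s)\n", x$K,
              if (is.na(x$series_id)) "" else
                sprintf(", series %d", x$series_id)))
  print(per_class_counts(x))
  invisible(x)
}

#' Per-class counts of a high-weight selection
#'
#' How many of the positive and negative high-weight sites belong to
#' each class model; within each sign the counts sum to K.
#'
#' @param selection A `high_weight_selection`.
#' @return A 2-row matrix (`positive`, `negative`) with one column per
#'   class present in the selection's source table.
#' @export
per_class_counts <- function(selection) {
  classes <- unique(c(selection$positive$class, selection$negative$class))
  classes <- classes[order(match(classes, .CELL_TYPES))]
  cnt <- function(df) vapply(classes, function(cl) sum(df$class == cl),
                             integer(1))
  rbind(positive = cnt(selection$positive),
        negative = cnt(selection$negative))
}

#' Mean and SEM of per-class high-weight counts across fold series
#'
#' @param selections List of `high_weight_selection`s (one per series).
#' @return Data frame with `class`, `sign`, `mean`, `sem`, plus an
#'   attribute `ratio_ipsc_esc`: mean total (positive + negative)
#'   iPSC count over mean total ESC count.
#' @export
high_weight_count_summary <- function(selections) {
  mats <- lapply(selections, per_class_counts)
  classes <- colnames(mats[[1]])
  rows <- list()
  for (sgn in c("positive", "negative")) {
    for (cl in classes) {
      v <- vapply(mats, function(m) m[sgn, cl], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, sign = sgn, mean = mean(v),
        sem = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  totals <- vapply(classes, function(cl)
    mean(vapply(mats, function(m) sum(m[, cl]), numeric(1))), numeric(1))
  if (all(c("ESC", "iPSC") %in% classes) && totals[["ESC"]] > 0)
    attr(out, "ratio_ipsc_esc") <- totals[["iPSC"]] / totals[["ESC"]]
  out
}

#' Cross-fold common high-weight sites and the cross-class signature
#'
#' For each class and sign, the probes selected in all four fold
#' series; then the two cross-class intersections that define the
#' epigenetic signature: `esc_pos_ipsc_neg` (common ESC-positive AND
#' common iPSC-negative) and `ipsc_pos_esc_neg` (common iPSC-positive
#' AND common ESC-negative).
#'
#' @param selections List of four `high_weight_selection`s.
#' @return A `common_signature` list: `common` (nested list
#'   `[[class]][[sign]]` of probe vectors), `esc_pos_ipsc_neg`,
#'   `ipsc_pos_esc_neg`.
#' @export
common_sites <- function(selections) {
  if (length(selections) != 4)
    stopf("common_sites expects the four fold selections, got %d",
          length(selections))
  classes <- unique(selections[[1]]$positive$class)
  common <- list()
  for (cl in classes) {
    common[[cl]] <- list(
      positive = Reduce(intersect, lapply(selections, function(s)
        s$positive$probe_id[s$positive$class == cl])),
      negative = Reduce(intersect, lapply(selections, function(s)
        s$negative$probe_id[s$negative$class == cl])))
  }
  sig <- structure(list(common = common), class = "common_signature")
  if (all(c("ESC", "iPSC") %in% classes)) {
    sig$esc_pos_ipsc_neg <- sort(intersect(common$ESC$positive,
                                           common$iPSC$negative))
    sig$ipsc_pos_esc_neg <- sort(intersect(common$iPSC$positive,
                                           common$ESC$negative))
  }
  sig
}

#' @export
print.common_signature <- function(x, ...) {
  cat("Cross-fold common high-weight sites:\n")
  for (cl in names(x$common))
    cat(sprintf("  %s: %d positive, %d negative\n", cl,
                length(x$common[[cl]]$positive),
                length(x$common[[cl]]$negative)))
  if (!is.null(x$esc_pos_ipsc_neg))
    cat(sprintf("  ESC Pos-iPSC Neg: %d sites; iPSC Pos-ESC Neg: %d sites\n",
                length(x$esc_pos_ipsc_neg), length(x$ipsc_pos_esc_neg)))
  invisible(x)
}

#' Annotation category counts and proportions for a probe set
#'
#' Tallies a probe set over one annotation facet. For
#' `gene_feature`, a probe carrying several gene-feature groups
#' contributes once to each group, so counts may exceed the number of
#' sites; proportions are normalized by the total number of
#' contributions. `cgi_relation` and `chromosome` are single-valued.
#'
#' @param sites Character vector of probe ids.
#' @param annotation Probe annotation data frame.
#' @param facet One of `"gene_feature"`, `"cgi_relation"`,
#'   `"chromosome"`.
#' @return Data frame `category`, `count`, `proportion`; probes absent
#'   from the annotation are skipped with a warning.
#' @export
annotate_counts <- function(sites, annotation,
                            facet = c("gene_feature", "cgi_relation",
                                      "chromosome")) {
  facet <- match.arg(facet)
  idx <- match(sites, annotation$probe_id)
  if (anyNA(idx)) {
    warning(sprintf("%d site(s) missing from the annotation; skipped",
                    sum(is.na(idx))))
    idx <- idx[!is.na(idx)]
  }
  values <- switch(facet,
    gene_feature = unlist(strsplit(annotation$gene_feature_groups[idx],
                                   ";", fixed = TRUE)),
    cgi_relation = annotation$cgi_relation[idx],
    chromosome = annotation$chromosome[idx])
  tab <- table(values)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    proportion = as.integer(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$category), , drop = FALSE]
}
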