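#' The four cross-validation fold series
#'
#' Every cell line belongs to one of four groups A-D; the four learning
#' series use each group as the test set exactly once:
#' Series-1 trains on BCD and tests on A; Series-2 on CDA / B;
#' Series-3 on DAB / C; Series-4 on ABC / D.
#'
#' @param sheet Optional sample sheet; when given, each series is
#'   checked to have at least one test sample.
#' @return A list of four lists with `series_id`, `train_groups`,
#'   `test_group`.
#' @export
make_fold_series <- function(sheet = NULL) {
  series <- list(
    list(series_id = 1L, train_groups = c("B", "C", "D"), test_group = "A"),
    list(series_id = 2L, train_groups = c("C", "D", "A"), test_group = "B"),
    list(series_id = 3L, train_groups = c("D", "A", "B"), test_group = "C"),
    list(series_id = 4L, train_groups = c("A", "B", "C"), test_group = "D")
  )
  if (!is.null(sheet)) {
    validate_sample_sheet(sheet)
    for (s in series)
      if (!any(sheet$fold_group == s$test_group))
        stopf("fold group %s has no samples (series %d test set empty)",
              s$test_group, s$series_id)
  }
  series
}

#' Assign fold groups A-D to a sample sheet
#'
#' Stratified round-robin: within each cell type, samples are shuffled
#' and dealt to groups A, B, C, D in turn, so per-class group sizes
#' differ by at most one.
#'
#' @param sheet Sample sheet without (or with to-be-overwritten) fold
#'   groups.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return The sheet with `fold_group` filled in.
#' @export
assign_fold_groups <- function(sheet, seed = 1L) {
  validate_sample_sheet(sheet, require_folds = FALSE)
  set.seed(as.integer(seed))
  fg <- character(nrow(sheet))
  for (ct in unique(sheet$cell_type)) {
    idx <- which(sheet$cell_type == ct)
    idx <- idx[sample.int(length(idx))]
    fg[idx] <- rep_len(.FOLD_GROUPS, length(idx))
  }
  sheet$fold_group <- fg
  sheet
}

#' Sweep configuration
#'
#' The training protocol: for each of the four fold series and each
#' regularization weight, train for `epochs` epochs and record train and
#' test metrics every `checkpoint_every` epochs. Defaults follow the
#' study protocol: six regularization weights (0.10, 0.25, 0.50, 0.90,
#' 1.00, 1.10), 300 epochs, a checkpoint every 10 — hence 7,200 epochs
#' and 720 saved models sweep-wide.
#'
#' @param reg_weights Positive regularization weights to sweep.
#' @param epochs Epochs per (series, weight) cell; must be divisible by
#'   `checkpoint_every`.
#' @param checkpoint_every Checkpoint interval in epochs.
#' @param master_seed Master seed from which every cell's shuffling
#'   stream is derived deterministically.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(reg_weights = c(0.10, 0.25, 0.50, 0.90, 1.00, 1.10),
                         epochs = 300L, checkpoint_every = 10L,
                         master_seed = 1L) {
  if (length(reg_weights) == 0 || any(reg_weights <= 0))
    stopf("reg_weights must be non-empty and positive")
  epochs <- as.integer(epochs)
  checkpoint_every <- as.integer(checkpoint_every)
  if (epochs %% checkpoint_every != 0)
    stopf("epochs (%d) must be divisible by checkpoint_every (%d)",
          epochs, checkpoint_every)
  structure(list(reg_weights = reg_weights, epochs = epochs,
                 checkpoint_every = checkpoint_every,
                 master_seed = as.integer(master_seed)),
            class = "sweep_config")
}

#' Run the cross-validation regularization sweep
#'
#' For every (fold series, regularization weight) cell a fresh model is
#' trained with per-epoch shuffling; at every checkpoint epoch the model
#' is saved and evaluated on both its training and its test split.
#' Each cell's epoch-`e` shuffle uses the deterministic seed
#' `derived(master_seed, series, weight index) + e`, so any cell is
#' reproducible in isolation. Test samples are never presented during
#' training of their series.
#'
#' @param beta Filtered, validated beta matrix (probes x all samples).
#' @param sheet Sample sheet with fold groups covering the columns of
#'   `beta`.
#' @param config A [sweep_config()].
#' @param checkpoint_dir Directory for checkpoint files (created).
#' @return A data frame of checkpoint records: `series_id`, `r`,
#'   `epoch`, train/test macro metrics, and `checkpoint` (file path).
#'   Attributes: `epochs_total` (total epochs trained), `checkpoint_dir`,
#'   `config`.
#' @export
run_sweep <- function(beta, sheet, config = sweep_config(),
                      checkpoint_dir = tempfile("methylarow_ckpt_")) {
  validate_beta_matrix(beta)
  validate_sample_sheet(sheet)
  miss <- setdiff(colnames(beta), sheet$sample_id)
  if (length(miss) > 0)
    stopf("samples missing from sheet: %s", paste(miss, collapse = ", "))
  dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  series <- make_fold_series(sheet)
  labels <- stats::setNames(sheet$cell_type, sheet$sample_id)
  groups <- stats::setNames(sheet$fold_group, sheet$sample_id)[colnames(beta)]
  rows <- list()
  epochs_total <- 0L
  for (s in series) {
    train_cols <- colnames(beta)[groups %in% s$train_groups]
    test_cols <- colnames(beta)[groups == s$test_group]
    if (length(test_cols) == 0)
      stopf("series %d has no test samples", s$series_id)
    beta_train <- beta[, train_cols, drop = FALSE]
    for (ri in seq_along(config$reg_weights)) {
      r <- config$reg_weights[ri]
      cell_seed <- derive_seed(config$master_seed, s$series_id, ri)
      model <- init_model(rownames(beta), r = r)
      model$seed <- cell_seed
      for (e in seq_len(config$epochs)) {
        model <- train_epoch(model, beta_train, labels[train_cols],
                             seed = cell_seed + e)
        epochs_total <- epochs_total + 1L
        if (e %% config$checkpoint_every == 0) {
          ck <- file.path(checkpoint_dir,
                          sprintf("series%d_r%03d_epoch%04d.rds",
                                  s$series_id, ri, e))
          save_checkpoint(model, ck)
          tr <- evaluate_split(model, beta, train_cols, labels)
          te <- evaluate_split(model, beta, test_cols, labels)
          rows[[length(rows) + 1L]] <- data.frame(
            series_id = s$series_id, r = r, epoch = e,
            train_precision_macro = tr$precision_macro,
            train_recall_macro = tr$recall_macro,
            train_f_macro = tr$f_macro, train_accuracy = tr$accuracy,
            test_precision_macro = te$precision_macro,
            test_recall_macro = te$recall_macro,
            test_f_macro = te$f_macro, test_accuracy = te$accuracy,
            checkpoint = ck, stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  attr(records, "epochs_total") <- epochs_total
  attr(records, "checkpoint_dir") <- checkpoint_dir
  attr(records, "config") <- config
  records
}

## Macro metrics of a model on one set of columns of beta.
evaluate_split <- function(model, beta, cols, labels) {
  pred <- predict(model, beta[, cols, drop = FALSE])
  suppressWarnings(
    macro_metrics(confusion(labels[cols], pred, classes = model$classes)))
}

#' Select the optimal (epoch, regularization weight) combination
#'
#' For every (epoch, r) pair, the test macro F-scores of the four fold
#' series are averaged; the pair with the highest average wins. Ties are
#' broken by higher average training macro F-score, then smaller epoch,
#' then smaller r.
#'
#' @param records Checkpoint records from [run_sweep()].
#' @return A list `epoch`, `r`, `test_f_macro_mean`, `train_f_macro_mean`.
#' @export
select_optimal <- function(records) {
  agg <- stats::aggregate(
    cbind(test_f_macro, train_f_macro) ~ epoch + r,
    data = records, FUN = mean)
  ord <- order(-agg$test_f_macro, -agg$train_f_macro, agg$epoch, agg$r)
  best <- agg[ord[1], ]
  list(epoch = best$epoch, r = best$r,
       test_f_macro_mean = best$test_f_macro,
       train_f_macro_mean = best$train_f_macro)
}

#' Pooled ("mixed") confusion matrix at a sweep cell
#'
#' Loads the four series' checkpoints at the chosen epoch and
#' regularization weight, predicts each series' held-out test samples
#' with its own model, and pools the predictions into one confusion
#' matrix; every cohort sample contributes exactly once, so row sums
#' equal the cohort class sizes.
#'
#' @param records Checkpoint records from [run_sweep()].
#' @param beta The beta matrix the sweep ran on.
#' @param sheet The sample sheet with fold groups.
#' @param epoch,r The selected combination (e.g. from
#'   [select_optimal()]).
#' @return A `confusion_matrix`.
#' @export
pooled_confusion <- function(records, beta, sheet, epoch, r) {
  sel <- records[records$epoch == epoch & records$r == r, ]
  if (nrow(sel) != 4)
    stopf("expected 4 series records at epoch %d, r %g; found %d",
          epoch, r, nrow(sel))
  labels <- stats::setNames(sheet$cell_type, sheet$sample_id)
  groups <- stats::setNames(sheet$fold_group, sheet$sample_id)
  series <- make_fold_series()
  true_all <- pred_all <- character(0)
  for (s in series) {
    row <- sel[sel$series_id == s$series_id, ]
    model <- load_checkpoint(row$checkpoint)
    test_cols <- intersect(colnames(beta),
                           sheet$sample_id[groups == s$test_group])
    pred <- predict(model, beta[, test_cols, drop = FALSE])
    true_all <- c(true_all, labels[test_cols])
    pred_all <- c(pred_all, pred)
  }
  confusion(true_all, pred_all)
}

#' Load the four fold models at a sweep cell
#'
#' @inheritParams pooled_confusion
#' @return A list of four `arow_model`s indexed by series id.
#' @export
models_at <- function(records, epoch, r) {
  sel <- records[records$epoch == epoch & records$r == r, ]
  sel <- sel[order(sel$series_id), ]
  if (nrow(sel) != 4)
    stopf("expected 4 series records at epoch %d, r %g; found %d",
          epoch, r, nrow(sel))
  lapply(seq_len(4), function(i) load_checkpoint(sel$checkpoint[i]))
}
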