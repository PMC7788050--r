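#' Fit a one-vs-others AROW classifier on a beta matrix
#'
#' Adaptive Regularization of Weight vectors (AROW) is an online linear
#' learner that keeps, per feature, a mean weight (the "determination
#' weight" of a CpG site) and a positive confidence that shrinks as
#' evidence accumulates. Multiclass discrimination uses one binary AROW
#' model per cell type against the rest; a sample's class is the model
#' with the largest linear score (no intercept: the score is purely the
#' sum of methylation rate times determination weight).
#'
#' Each training epoch presents every sample exactly once in a freshly
#' shuffled order; for every sample all four class models receive a
#' binary update (target +1 for the sample's own class, -1 otherwise).
#' Missing beta values contribute 0 to scores and updates.
#'
#' @param x Numeric probes-x-samples beta matrix with dimnames.
#' @param y Cell-type label per sample (character or factor), in the
#'   class vocabulary `ESC, iPSC, ECC, somatic`.
#' @param r Positive AROW regularization weight; larger values damp each
#'   update. Default 1.0.
#' @param epochs Number of training epochs, default 1.
#' @param seed Optional integer; epoch `e` shuffles with seed
#'   `seed + e` so runs are exactly reproducible.
#' @param classes Class order (fixed default `ESC, iPSC, ECC, somatic`).
#' @return An object of class `arow_model` with components `mu`
#'   (probes x classes determination weights), `sigma` (probes x classes
#'   confidences), `r`, `classes`, `probe_ids`, `epoch_count`, `seed`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(40), 10, 4,
#'             dimnames = list(sprintf("cg%08d", 1:10), paste0("s", 1:4)))
#' fit <- arow(x, c("ESC", "iPSC", "ECC", "somatic"), r = 1, epochs = 5,
#'             seed = 1)
#' predict(fit, x)
#' @export
arow <- function(x, y, r = 1, epochs = 1, seed = NULL,
                 classes = cell_type_classes()) {
  model <- init_model(rownames(x), classes = classes, r = r)
  model$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  y <- as.character(y)
  for (e in seq_len(epochs)) {
    s <- if (is.null(seed)) NULL else seed + e
    model <- train_epoch(model, x, y, seed = s)
  }
  model$call <- match.call()
  model
}

#' Initialize a multiclass AROW model
#'
#' Fresh state per AROW convention: all determination weights zero, all
#' confidences one.
#'
#' @param probe_ids Ordered feature (TargetID) vector.
#' @param classes Ordered class labels.
#' @param r Positive regularization weight.
#' @return An `arow_model` with `epoch_count = 0`.
#' @export
init_model <- function(probe_ids, classes = cell_type_classes(), r = 1) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    stopf("regularization weight r must be a single positive number")
  probe_ids <- as.character(probe_ids)
  if (anyDuplicated(probe_ids)) stopf("duplicate probe ids")
  p <- length(probe_ids)
  k <- length(classes)
  structure(list(
    classes = classes,
    probe_ids = probe_ids,
    r = r,
    epoch_count = 0L,
    seed = NA_integer_,
    mu = matrix(0, p, k, dimnames = list(probe_ids, classes)),
    sigma = matrix(1, p, k, dimnames = list(probe_ids, classes))
  ), class = "arow_model")
}

#' Single binary AROW update
#'
#' One online step for a binary state `list(mu, sigma, r)` on example
#' `(x, y)`, `y` in `{+1, -1}`. With margin `m = y * (mu . x)`: if
#' `m >= 1` the state is unchanged; otherwise with
#' `beta = 1 / (sum_j sigma_j x_j^2 + r)` and
#' `alpha = max(0, 1 - m) * beta`,
#' `mu_j <- mu_j + alpha * y * sigma_j * x_j` and
#' `sigma_j <- sigma_j - beta * (sigma_j * x_j)^2`.
#' Confidences stay positive and never increase.
#'
#' @param state List with numeric vectors `mu`, `sigma` (same length)
#'   and scalar `r > 0`.
#' @param x Feature vector, same length as `state$mu`.
#' @param y Label, `+1` or `-1`.
#' @return The updated state list.
#' @export
arow_update_binary <- function(state, x, y) {
  mu <- state$mu; sigma <- state$sigma; r <- state$r
  if (length(x) != length(mu))
    stopf("feature vector length %d does not match state length %d",
          length(x), length(mu))
  if (!y %in% c(1, -1)) stopf("y must be +1 or -1")
  m <- y * sum(mu * x)
  if (m >= 1) return(state)
  sx <- sigma * x
  bet <- 1 / (sum(sx * x) + r)
  alpha <- max(0, 1 - m) * bet
  state$mu <- mu + alpha * y * sx
  state$sigma <- sigma - bet * sx * sx
  state
}

#' Per-class linear decision scores for one sample
#'
#' The score of class `c` is the integrated quantity
#' `sum_j mu[c, j] * x_j` — methylation rate times determination
#' weight, summed over CpG sites; no bias term.
#'
#' @param model An `arow_model`.
#' @param x Beta vector for one sample. If named, it is aligned to the
#'   model's probes (an error names any missing probe); if unnamed it
#'   must already be in model probe order. `NA` contributes 0.
#' @return Named numeric vector of per-class scores.
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "arow_model"))
  if (!is.null(names(x))) {
    miss <- setdiff(model$probe_ids, names(x))
    if (length(miss) > 0)
      stopf("sample lacks %d model probe(s), e.g. %s", length(miss),
            paste(utils::head(miss, 3), collapse = ", "))
    x <- x[model$probe_ids]
  } else if (length(x) != length(model$probe_ids)) {
    stopf("unnamed beta vector length %d does not match %d model probes",
          length(x), length(model$probe_ids))
  }
  x[is.na(x)] <- 0
  drop(crossprod(model$mu, x))
}

#' Predict cell types from a fitted AROW model
#'
#' @param object An `arow_model`.
#' @param newdata Beta matrix (probes x samples) or a single named beta
#'   vector. Rows are aligned to the model probes by name.
#' @param type `"class"` (default) for labels, `"score"` for the
#'   classes-x-samples score matrix.
#' @param ... Unused.
#' @return Character vector of predicted classes (ties broken by the
#'   fixed class order), or the score matrix.
#' @export
predict.arow_model <- function(object, newdata, type = c("class", "score"),
                               ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  miss <- setdiff(object$probe_ids, rownames(newdata))
  if (length(miss) > 0)
    stopf("newdata lacks %d model probe(s), e.g. %s", length(miss),
          paste(utils::head(miss, 3), collapse = ", "))
  xm <- newdata[object$probe_ids, , drop = FALSE]
  xm[is.na(xm)] <- 0
  scores <- crossprod(object$mu, xm)           # classes x samples
  rownames(scores) <- object$classes
  if (type == "score") return(scores)
  ## ties broken by class order: first maximum
  idx <- apply(scores, 2, which.max)
  stats::setNames(object$classes[idx], colnames(xm))
}

#' Train one epoch of the one-vs-others AROW model
#'
#' Visits every training sample exactly once in a shuffled order; for
#' each sample, each class state is updated with target +1 if the
#' sample belongs to that class, else -1. Missing beta values are
#' treated as 0 in scores and updates.
#'
#' @param model An `arow_model`.
#' @param beta Beta matrix restricted to the training samples.
#' @param labels Cell type per training sample: a named character
#'   vector (names = sample ids) or unnamed in column order.
#' @param seed Optional integer seed for the shuffle; identical seeds
#'   give identical epochs.
#' @return The updated model with `epoch_count` incremented.
#' @export
train_epoch <- function(model, beta, labels, seed = NULL) {
  stopifnot(inherits(model, "arow_model"))
  n <- ncol(beta)
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(beta), names(labels))
    if (length(miss) > 0)
      stopf("unlabeled training sample(s): %s", paste(miss, collapse = ", "))
    labels <- labels[colnames(beta)]
  } else if (length(labels) != n) {
    stopf("labels length %d does not match %d samples", length(labels), n)
  }
  bad <- setdiff(unique(as.character(labels)), model$classes)
  if (length(bad) > 0)
    stopf("label(s) outside model classes: %s", paste(bad, collapse = ", "))
  if (!identical(rownames(beta), model$probe_ids)) {
    miss <- setdiff(model$probe_ids, rownames(beta))
    if (length(miss) > 0)
      stopf("training matrix lacks %d model probe(s)", length(miss))
    beta <- beta[model$probe_ids, , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(as.integer(seed %% (.Machine$integer.max - 1L)))
  ord <- sample.int(n)
  n_missing <- sum(colSums(is.na(beta)) > 0)
  if (n_missing > 0)
    message(sprintf("train_epoch: %d sample(s) with missing beta treated as 0",
                    n_missing))
  mu <- model$mu; sigma <- model$sigma; r <- model$r
  p <- nrow(mu)
  ymat <- outer(model$classes, as.character(labels),
                function(cl, lb) ifelse(cl == lb, 1, -1))  # k x n
  for (i in ord) {
    x <- beta[, i]
    x[is.na(x)] <- 0
    yv <- ymat[, i]
    m <- yv * colSums(mu * x)
    viol <- m < 1
    if (any(viol)) {
      sx <- sigma * x
      xsx <- colSums(sx * x)
      bet <- ifelse(viol, 1 / (xsx + r), 0)
      alpha <- (1 - m) * bet            # zero where bet is zero
      mu <- mu + sx * rep(alpha * yv, each = p)
      sigma <- sigma - (sx * sx) * rep(bet, each = p)
    }
  }
  model$mu <- mu
  model$sigma <- sigma
  model$epoch_count <- model$epoch_count + 1L
  model
}

#' Save / load an AROW model checkpoint
#'
#' The checkpoint is a versioned container holding the per-class
#' determination weights and confidences, the regularization weight,
#' epoch count, seed and the probe list; save-then-load reproduces the
#' model bit-exactly.
#'
#' @param model An `arow_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the
#'   restored `arow_model` (truncated or foreign files raise an error).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "arow_model"))
  payload <- list(format = "methylarow-checkpoint", version = 1L,
                  classes = model$classes, probe_ids = model$probe_ids,
                  r = model$r, epoch_count = model$epoch_count,
                  seed = model$seed, mu = model$mu, sigma = model$sigma)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stopf("cannot read checkpoint %s: %s", path, conditionMessage(e)))
  if (!is.list(payload) ||
      !identical(payload$format, "methylarow-checkpoint"))
    stopf("%s is not a methylarow checkpoint", path)
  structure(list(classes = payload$classes, probe_ids = payload$probe_ids,
                 r = payload$r, epoch_count = payload$epoch_count,
                 seed = payload$seed, mu = payload$mu,
                 sigma = payload$sigma),
            class = "arow_model")
}

#' @export
print.arow_model <- function(x, ...) {
  cat(sprintf(
    "One-vs-others AROW model: %d classes (%s), %d CpG features\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    length(x$probe_ids)))
  cat(sprintf("  regularization weight r = %g, epochs trained = %d\n",
              x$r, x$epoch_count))
  invisible(x)
}

#' @export
summary.arow_model <- function(object, ...) {
  w <- object$mu
  out <- data.frame(
    class = object$classes,
    n_nonzero = colSums(w != 0),
    min_weight = apply(w, 2, min),
    max_weight = apply(w, 2, max),
    mean_confidence = colMeans(object$sigma),
    row.names = NULL
  )
  structure(list(model = object, weights = out),
            class = "summary.arow_model")
}

#' @export
print.summary.arow_model <- function(x, ...) {
  print(x$model)
  cat("Determination-weight summary per class model:\n")
  print(x$weights, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract determination weights from a fitted model
#'
#' @param object An `arow_model`.
#' @param ... Unused.
#' @return The probes-x-classes matrix of determination weights.
#' @export
coef.arow_model <- function(object, ...) object$mu
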