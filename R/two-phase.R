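# Two-phase analysis layer: feature assembly, predictive model with
# best-epoch selection, permutation attributions, directionality scoring,
# direction-prediction evaluation and the per-stage correlation shift.

#' Assemble a per-gene feature table
#'
#' In `initial` mode the features are the (mucosa) baseline values; in
#' `differential` mode they are per-gene log2 fold changes of a later stage
#' against mucosa, with a pseudo-count of 1 added to connectivity and
#' methylation columns (and to any column containing zeros) before the
#' ratio. Binary indicator columns (e.g. TF binding) are carried through
#' unchanged in both modes. Every numeric feature is duplicated as its rank
#' transform (ascending, average ties), doubling the column count.
#'
#' @param mode "initial" or "differential".
#' @param mucosa data.frame of per-gene raw feature values (rownames = gene
#'   ids).
#' @param stage data.frame of the same features in the later stage
#'   (differential mode only).
#' @param target Optional numeric target (log2 expression fold change),
#'   aligned with `mucosa` rows.
#' @param pseudo_cols Regular expression selecting columns that receive the
#'   pseudo-count unconditionally.
#' @param pseudo Pseudo-count.
#' @return Object of class `feature_table`: list(x = numeric matrix with
#'   raw + rank columns, target, gene_ids, raw_names, mode).
#' @export
build_features <- function(mode = c("initial", "differential"), mucosa,
                           stage = NULL, target = NULL,
                           pseudo_cols = "connect|meth", pseudo = 1) {
  mode <- match.arg(mode)
  gene_ids <- rownames(mucosa) %||% as.character(seq_len(nrow(mucosa)))
  mucosa <- as.data.frame(mucosa)
  num <- vapply(mucosa, is.numeric, TRUE)
  mucosa <- mucosa[num]
  is_binary <- vapply(mucosa, function(v) all(v %in% c(0, 1)), TRUE)

  if (mode == "initial") {
    raw <- mucosa
  } else {
    if (is.null(stage)) stop("differential mode requires a stage table")
    stage <- as.data.frame(stage)
    common <- intersect(gene_ids, rownames(stage) %||% gene_ids)
    if (length(common) < length(gene_ids)) {
      message(sprintf("%d gene id(s) missing from the stage table; dropped",
                      length(gene_ids) - length(common)))
      idx <- match(common, gene_ids)
      mucosa <- mucosa[idx, , drop = FALSE]
      if (!is.null(target)) target <- target[idx]
      gene_ids <- common
    }
    stage <- stage[match(gene_ids, rownames(stage) %||% gene_ids), ,
                   drop = FALSE]
    raw <- mucosa
    for (j in names(mucosa)) {
      if (is_binary[[j]]) next
      ps <- if (grepl(pseudo_cols, j, ignore.case = TRUE) ||
                any(mucosa[[j]] <= 0, na.rm = TRUE) ||
                any(stage[[j]] <= 0, na.rm = TRUE)) pseudo else 0
      raw[[j]] <- log2((stage[[j]] + ps) / (mucosa[[j]] + ps))
    }
  }
  x <- as.matrix(raw)
  rk <- apply(x, 2, rank, ties.method = "average")
  colnames(rk) <- paste0("rank.", colnames(x))
  x <- cbind(x, rk)
  rownames(x) <- gene_ids
  structure(list(x = x, target = target, gene_ids = gene_ids,
                 raw_names = colnames(raw), mode = mode),
            class = "feature_table")
}

#' Fit the two-phase predictive model
#'
#' Holds out `test_n` randomly selected genes, trains a feed-forward
#' regressor (three hidden layers, 20% dropout by default) on the rest for
#' up to `epochs` epochs, and returns the model at the epoch with the lowest
#' held-out mean squared error, together with the held-out predictions. The
#' split, initialization and minibatch order are all governed by `seed`, so
#' identical seeds give identical splits and selected epochs.
#'
#' @param features A [build_features()] table, or a numeric matrix/data
#'   frame of predictors.
#' @param target Numeric target; defaults to the feature table's target.
#' @param test_n Number of held-out test genes.
#' @param epochs Maximum training epochs.
#' @param hidden Hidden layer widths. The reference architecture is
#'   `c(2048, 512, 128)`; smaller widths are appropriate for desk-scale
#'   experiments.
#' @param dropout Dropout rate applied after each hidden layer.
#' @param batch Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed.
#' @return Object of class `two_phase_model`.
#' @export
two_phase_fit <- function(features, target = NULL, test_n = 2800,
                          epochs = 50, hidden = c(2048, 512, 128),
                          dropout = 0.2, batch = 128, lr = 1e-3, seed = 1) {
  if (inherits(features, "feature_table")) {
    x <- features$x
    target <- target %||% features$target
  } else {
    x <- as.matrix(features)
  }
  if (is.null(target)) stop("a target vector is required")
  if (nrow(x) != length(target)) stop("features and target length mismatch")
  if (nrow(x) <= test_n) stop("need more genes than test_n")
  keep <- is.finite(target) & !apply(x, 1, function(r) any(!is.finite(r)))
  x <- x[keep, , drop = FALSE]
  target <- target[keep]

  fit <- with_seed(seed, {
    test_idx <- sort(sample.int(nrow(x), test_n))
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    m <- mlp_fit(x[train_idx, , drop = FALSE], target[train_idx],
                 x[test_idx, , drop = FALSE], target[test_idx],
                 hidden = hidden, dropout = dropout, epochs = epochs,
                 batch = batch, lr = lr)
    list(m = m, test_idx = test_idx, train_idx = train_idx)
  })
  pred <- mlp_predict(fit$m, x[fit$test_idx, , drop = FALSE])
  obs <- target[fit$test_idx]
  if (!all(is.finite(pred))) stop("non-finite predictions; training diverged")
  structure(list(
    mlp = fit$m, x = x, target = target,
    test_idx = fit$test_idx, train_idx = fit$train_idx,
    predictions = pred, observed = obs,
    r = stats::cor(pred, obs),
    mse = mean((pred - obs)^2),
    selected_epoch = fit$m$best_epoch,
    seed = seed, call = match.call()
  ), class = "two_phase_model")
}

#' @export
print.two_phase_model <- function(x, ...) {
  cat("Two-phase dysregulation model\n")
  cat(sprintf("  features: %d  genes: %d (%d held out)\n",
              ncol(x$x), nrow(x$x), length(x$test_idx)))
  cat(sprintf("  hidden layers: %s  dropout: %.2f\n",
              paste(x$mlp$hidden, collapse = "-"), x$mlp$dropout))
  cat(sprintf("  selected epoch: %d of %d\n", x$selected_epoch,
              length(x$mlp$history)))
  cat(sprintf("  held-out r = %.3f, MSE = %.4f\n", x$r, x$mse))
  invisible(x)
}

#' @export
summary.two_phase_model <- function(object, ...) {
  print(object)
  cat("\nHeld-out MSE by epoch (first 10):\n")
  print(round(utils::head(object$mlp$history, 10), 4))
  invisible(object)
}

#' @export
predict.two_phase_model <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
  else if (inherits(newdata, "feature_table")) newdata$x
  else as.matrix(newdata)
  mlp_predict(object$mlp, x)
}

#' @export
fitted.two_phase_model <- function(object, ...) {
  mlp_predict(object$mlp, object$x)
}

#' @export
residuals.two_phase_model <- function(object, ...) {
  object$target - fitted(object)
}

#' @export
plot.two_phase_model <- function(x, ...) {
  graphics::plot(x$observed, x$predictions,
                 xlab = "observed log2 fold change",
                 ylab = "predicted log2 fold change",
                 main = sprintf("held-out r = %.2f", x$r), pch = 16,
                 col = grDevices::rgb(0, 0, 0, 0.3), ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}

#' Permutation-based feature attributions
#'
#' Per gene and feature, the attribution is the model prediction minus its
#' mean under random permutations of that feature column (i.e. the effect of
#' the gene's own feature value relative to the feature being marginalized).
#' Summaries follow the attribution convention: importance is the mean
#' absolute attribution across genes, directionality the plain mean.
#'
#' @param model A `two_phase_model`.
#' @param rows Which rows to attribute over: "test" (default) or "all".
#' @param n_perm Number of permutation repetitions.
#' @param seed Integer seed.
#' @return data.frame (feature, importance, direction, association), ordered
#'   as the model columns. `direction` is the plain mean attribution;
#'   `association` is the correlation between a feature's values and its
#'   per-gene attributions, whose sign is a robust readout of the direction
#'   of effect (mean attributions are near zero for purely additive
#'   effects). The per-gene attribution matrix is attached as attribute
#'   `attributions`.
#' @export
feature_importance <- function(model, rows = c("test", "all"), n_perm = 5,
                               seed = 1) {
  rows <- match.arg(rows)
  x <- if (rows == "test") model$x[model$test_idx, , drop = FALSE] else model$x
  base <- mlp_predict(model$mlp, x)
  phi <- matrix(0, nrow(x), ncol(x),
                dimnames = list(rownames(x), colnames(x)))
  with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      acc <- numeric(nrow(x))
      for (r in seq_len(n_perm)) {
        xp <- x
        xp[, j] <- x[sample.int(nrow(x)), j]
        acc <- acc + mlp_predict(model$mlp, xp)
      }
      phi[, j] <- base - acc / n_perm
    }
  })
  assoc <- vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) == 0 || stats::sd(phi[, j]) == 0) return(0)
    stats::cor(x[, j], phi[, j])
  }, numeric(1))
  out <- data.frame(feature = colnames(x),
                    importance = colMeans(abs(phi)),
                    direction = colMeans(phi),
                    association = assoc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "attributions") <- phi
  out
}

#' Exact Shapley attributions for small models (oracle)
#'
#' Brute-force Shapley values over all feature subsets, with a reference
#' value function: features outside the coalition are set to `baseline`
#' (column means by default). Exponential in the number of features; guarded
#' to at most 12. Used as an independent check of attribution signs for toy
#' models.
#'
#' @param predict_fun Function mapping a numeric matrix to predictions.
#' @param x Numeric matrix of instances to explain.
#' @param baseline Baseline feature vector (defaults to column means of x).
#' @return Matrix of Shapley values (instances x features).
#' @export
shapley_exact <- function(predict_fun, x, baseline = colMeans(x)) {
  m <- ncol(x)
  if (m > 12) stop("exact Shapley is limited to 12 features")
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  vals <- apply(subsets, 1, function(s) {
    xs <- x
    for (j in which(!s)) xs[, j] <- baseline[j]
    predict_fun(xs)
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  phi <- matrix(0, nrow(x), m, dimnames = list(rownames(x), colnames(x)))
  fact <- factorial(0:m)
  smat <- as.matrix(subsets)
  sizes <- rowSums(smat)
  for (j in seq_len(m)) {
    without <- which(!smat[, j])
    for (k in without) {
      s <- sizes[k]
      # index of the subset S union {j}
      with_j <- k + 2^(j - 1)
      w <- fact[s + 1] * fact[m - s] / fact[m + 1]
      phi[, j] <- phi[, j] + w * (vals[, with_j] - vals[, k])
    }
  }
  phi
}

#' Differential expression calls on replicated TPM matrices
#'
#' Per gene: Welch t-test on log2(TPM + 1) between condition and reference
#' samples, BH adjustment across genes, and a call of +1/-1 when the
#' adjusted q-value is below `fdr` AND the (pseudo-counted) fold change
#' exceeds `fold` (or its reciprocal); 0 otherwise.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param group Character vector per column, "ref" or "cond".
#' @param fold Fold-change threshold (> 1).
#' @param fdr BH q-value threshold.
#' @return Integer vector of calls in {-1, 0, 1} per gene; fold changes and
#'   q-values as attributes.
#' @export
de_calls <- function(tpm, group, fold = 1.3, fdr = 0.1) {
  ref <- tpm[, group == "ref", drop = FALSE]
  cond <- tpm[, group == "cond", drop = FALSE]
  lr <- log2(ref + 1); lc <- log2(cond + 1)
  n <- nrow(tpm)
  p <- vapply(seq_len(n), function(i) {
    a <- lr[i, ]; b <- lc[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    tryCatch(stats::t.test(b, a)$p.value, error = function(e) 1)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  fc <- (rowMeans(cond) + 1) / (rowMeans(ref) + 1)
  call <- integer(n)
  call[q < fdr & fc > fold] <- 1L
  call[q < fdr & fc < 1 / fold] <- -1L
  attr(call, "fc") <- fc
  attr(call, "q") <- q
  call
}

#' Directionality score of dysregulation calls
#'
#' Arithmetic mean of per-cancer-type calls coded -1 (down), 0 (unchanged),
#' +1 (up); one score in [-1, 1] per gene.
#'
#' @param calls Genes x types matrix (or data.frame) of coded calls.
#' @return Numeric vector of scores.
#' @export
directionality_score <- function(calls) {
  calls <- as.matrix(calls)
  if (!ncol(calls)) stop("at least one call column required")
  rowMeans(calls)
}

#' Evaluate direction predictions against multi-cohort calls
#'
#' ROC analysis of up- versus downregulated (gene, type) observations using
#' the predicted fold change as the score, plus prediction accuracy
#' stratified by bins of the absolute directionality score (accuracy =
#' agreement of sign(prediction) with the consensus direction among genes
#' with a nonzero score).
#'
#' @param pred_fc Predicted fold changes (per gene).
#' @param calls Genes x types matrix of -1/0/+1 calls.
#' @param bins Breaks for |directionality| stratification.
#' @return list(auc, accuracy = data.frame(bin, n, accuracy),
#'   directionality).
#' @export
direction_prediction_eval <- function(pred_fc, calls,
                                      bins = c(0, 0.25, 0.5, 0.75, 1)) {
  calls <- as.matrix(calls)
  obs <- as.vector(calls)
  score <- rep(pred_fc, ncol(calls))
  nz <- obs != 0
  if (!any(nz)) stop("no nonzero observed calls")
  roc <- pROC::roc(response = factor(obs[nz] > 0, levels = c(FALSE, TRUE)),
                   predictor = score[nz], quiet = TRUE, direction = "<")
  auc <- as.numeric(pROC::auc(roc))

  d <- directionality_score(calls)
  sel <- d != 0
  agree <- sign(pred_fc[sel]) == sign(d[sel])
  grp <- cut(abs(d[sel]), breaks = bins, include.lowest = TRUE)
  acc <- tapply(agree, grp, mean)
  nb <- tapply(agree, grp, length)
  list(auc = auc,
       accuracy = data.frame(bin = names(acc), n = as.integer(nb),
                             accuracy = as.numeric(acc)),
       directionality = d)
}

#' Per-stage correlation between connectivity and expression
#'
#' Spearman correlation between per-gene connectivity and expression among
#' active genes (TPM > `tpm_min`) for each stage, and the shift of each
#' stage's correlation relative to the first (baseline) stage. Under the
#' two-phase rule, global connectivity loss moves genes out of the saturated
#' regime and increases this correlation.
#'
#' @param conn Genes x stages connectivity matrix.
#' @param expr Genes x stages expression (TPM) matrix, same order.
#' @param tpm_min Activity threshold.
#' @return list(rho = named per-stage Spearman rho, delta = rho - rho of the
#'   first stage, n_active).
#' @export
correlation_shift <- function(conn, expr, tpm_min = 0.5) {
  conn <- as.matrix(conn); expr <- as.matrix(expr)
  stopifnot(all(dim(conn) == dim(expr)))
  stages <- colnames(conn) %||% paste0("stage", seq_len(ncol(conn)))
  rho <- vapply(seq_len(ncol(conn)), function(k) {
    act <- expr[, k] > tpm_min
    stats::cor(conn[act, k], expr[act, k], method = "spearman")
  }, numeric(1))
  names(rho) <- stages
  n_act <- colSums(expr > tpm_min)
  list(rho = rho, delta = rho - rho[1], n_active = n_act)
}

#' Permutation p-value for a held-out correlation
#'
#' Tests whether the correlation between held-out predictions and
#' observations exceeds chance by permuting the pairing `n_perm` times.
#'
#' @param pred,obs Numeric vectors.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return list(r, p).
#' @export
correlation_permutation_test <- function(pred, obs, n_perm = 999, seed = 1) {
  r <- stats::cor(pred, obs)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      stats::cor(pred, obs[sample.int(length(obs))]), numeric(1))
    list(r = r, p = (1 + sum(null >= r)) / (n_perm + 1))
  })
}
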