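#' Balanced subsample of cells by cluster
#'
#' Clusters larger than `n_per` are sampled without replacement down to
#' `n_per`; smaller clusters are kept whole. Deterministic given `seed`.
#'
#' @param labels named per-cell cluster labels.
#' @param n_per cells kept per cluster (default 300).
#' @param seed RNG seed.
#' @return character vector of selected cell names.
#' @export
balanced_subsample <- function(labels, n_per = 300L, seed = 0L) {
  .stopifnot_named(labels, "labels")
  with_seed(seed, unlist(lapply(sort(unique(labels)), function(cl) {
    cells <- names(labels)[labels == cl]
    if (length(cells) > n_per) sample(cells, n_per) else cells
  }), use.names = FALSE))
}

#' Train a one-vs-all L1-regularized lineage signature
#'
#' Fits a LASSO regression of the binary fate indicator (1 for
#' `target_class`, 0 otherwise) on log-normalized expression, over a
#' geometric grid of 100 penalties spanning three decades down from
#' `lambda_max = max |X'(y - mean(y))| / n`, choosing the penalty that
#' minimizes the cross-validated mean squared error (folds stratified by
#' class). Features are used as-is (no standardization) and an intercept is
#' fitted. The nonzero-weight genes form the fate's molecular signature.
#'
#' @param lognorm genes x cells log-normalized matrix (typically restricted
#'   to a [balanced_subsample()] of cells and [gene_filter()] genes).
#' @param labels named per-cell class labels covering the columns.
#' @param target_class positive class.
#' @param cv_folds folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param lambda optional fixed penalty; skips cross-validation.
#' @param thresh coordinate-descent convergence threshold.
#' @return list of class `signature_model`: `target_class`, `intercept`,
#'   `weights` (named, nonzero only), `lambda`, `cv_folds`, `seed`,
#'   `selected_genes`.
#' @export
train_signature <- function(lognorm, labels, target_class, cv_folds = 5L,
                            seed = 0L, lambda = NULL, thresh = 1e-8) {
  labels <- labels[colnames(lognorm)]
  y <- as.numeric(labels == target_class)
  if (all(y == 1) || all(y == 0)) {
    stop("labels contain a single class; cannot train one-vs-all model")
  }
  X <- Matrix::t(lognorm)
  n <- nrow(X)

  lmax <- max(abs(as.numeric(Matrix::t(X) %*% (y - mean(y)))) / n)
  grid <- exp(seq(log(lmax), log(lmax) - 3 * log(10), length.out = 100))

  if (is.null(lambda)) {
    foldid <- integer(n)
    foldid[y == 1] <- with_seed(seed, sample(rep_len(seq_len(cv_folds), sum(y == 1))))
    foldid[y == 0] <- with_seed(seed + 1L, sample(rep_len(seq_len(cv_folds), sum(y == 0))))
    cv <- glmnet::cv.glmnet(X, y, family = "gaussian", lambda = grid,
                            foldid = foldid, standardize = FALSE,
                            thresh = thresh)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    grid <- sort(unique(c(grid, lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = grid,
                          standardize = FALSE, thresh = thresh)
  }
  # coef() emits a spurious interpolation warning when the requested penalty
  # coincides with a grid point; the refit itself is exact
  beta <- withCallingHandlers(
    as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y,
                           standardize = FALSE, thresh = thresh)),
    warning = function(w) {
      if (grepl("collapsing to unique", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  names(beta) <- c("(Intercept)", colnames(X))
  w <- beta[-1]
  w <- w[abs(w) > 1e-10]
  structure(
    list(target_class = target_class, intercept = unname(beta[1]),
         weights = w, lambda = lambda, cv_folds = cv_folds, seed = seed,
         selected_genes = names(w)),
    class = "signature_model"
  )
}

#' Score cells with a trained signature
#'
#' Linear score `intercept + sum_g weight_g * value_gc`; genes absent from
#' the matrix contribute 0, with a warning.
#'
#' @param model a [train_signature()] model.
#' @param lognorm genes x cells log-normalized matrix.
#' @return named numeric vector of per-cell scores.
#' @export
score_cells <- function(model, lognorm) {
  stopifnot(inherits(model, "signature_model"))
  genes <- intersect(names(model$weights), rownames(lognorm))
  if (length(genes) < length(model$weights)) {
    warning(length(model$weights) - length(genes),
            " model gene(s) absent from the matrix; scored as 0")
  }
  score <- rep(model$intercept, ncol(lognorm))
  names(score) <- colnames(lognorm)
  if (length(genes) > 0) {
    score <- score + as.numeric(model$weights[genes] %*%
                                  lognorm[genes, , drop = FALSE])
  }
  score
}

#' Summarize scores by population, stage and sex
#'
#' Group means and standard errors of per-cell scores, ordered by stage.
#'
#' @param scores named per-cell scores.
#' @param cell_meta data.frame with rownames (or a `barcode` column)
#'   matching the score names and the grouping columns.
#' @param groupby grouping columns (default population, stage, sex).
#' @return data.frame with the group keys, `mean_score`, `se`, `n`.
#' @export
summarize_scores <- function(scores, cell_meta,
                             groupby = c("population", "stage", "sex")) {
  cm <- as.data.frame(cell_meta)
  if (!is.null(cm$barcode)) rownames(cm) <- cm$barcode
  cm <- cm[names(scores), groupby, drop = FALSE]
  if (anyNA(cm)) stop("incomplete metadata for scored cells")
  key <- interaction(cm, drop = TRUE, sep = "\r")
  agg <- lapply(split(unname(scores), key), function(v) {
    c(mean_score = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  keys <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(keys, do.call(rbind, agg), stringsAsFactors = FALSE)
  names(out)[seq_along(groupby)] <- groupby
  out$n <- as.integer(out$n)
  if ("stage" %in% groupby) {
    out <- out[order(out$stage, decreasing = FALSE), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
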