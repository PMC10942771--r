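#' Parameters for hurdle differential expression
#'
#' @param lfc_threshold minimum |logFC| for selection (strict; default 0.25).
#' @param alpha BH-adjusted p-value cutoff (strict; default 0.05).
#' @param min_pct genes detected in less than this fraction of both groups
#'   are skipped (default 0.1).
#' @param include_cdr include a per-cell detection-rate covariate in both
#'   model parts (default FALSE).
#' @return list of class `de_params`.
#' @export
de_params <- function(lfc_threshold = 0.25, alpha = 0.05, min_pct = 0.1,
                      include_cdr = FALSE) {
  stopifnot(lfc_threshold > 0, alpha > 0)
  structure(list(lfc_threshold = lfc_threshold, alpha = alpha,
                 min_pct = min_pct, include_cdr = include_cdr),
            class = "de_params")
}

#' Two-part (hurdle) differential expression test
#'
#' Models log-normalized expression in two parts: a detection component
#' (logistic regression of `value > 0` on group membership) and a continuous
#' component (Gaussian linear model of the value on group, over detected
#' cells only, with pooled maximum-likelihood variance). The per-gene test
#' statistic is the sum of the two components' likelihood-ratio statistics,
#' with degrees of freedom summed accordingly, referred to a chi-square
#' distribution. The fold change is reported on the back-transformed scale:
#' `logFC = ln(mean(exp(value_A) - 1) + 1) - ln(mean(exp(value_B) - 1) + 1)`
#' with means over all cells of each group. P-values are BH-adjusted over the
#' tested genes. Genes detected in less than `min_pct` of both groups are
#' reported untested. Degenerate continuous fits (zero residual variance) are
#' floored and flagged, as are detection tables with an empty margin
#' (separation).
#'
#' @param lognorm genes x cells log-normalized matrix.
#' @param group_a,group_b disjoint cell sets (names or indices).
#' @param params a [de_params()].
#' @return data.frame of class `de_result`: `gene`, `logFC`, `p_value`,
#'   `adj_p`, `pct_a`, `pct_b`, `direction`, `tested`, `flagged`.
#' @export
hurdle_test <- function(lognorm, group_a, group_b, params = de_params()) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  xa <- lognorm[, group_a, drop = FALSE]
  xb <- lognorm[, group_b, drop = FALSE]
  if (length(intersect(colnames(xa), colnames(xb))) > 0) {
    stop("groups must be disjoint")
  }
  if (params$include_cdr) {
    return(.hurdle_cdr(xa, xb, params))
  }
  na <- ncol(xa); nb <- ncol(xb)
  det_a <- Matrix::rowSums(xa > 0)
  det_b <- Matrix::rowSums(xb > 0)
  pct_a <- det_a / na
  pct_b <- det_b / nb
  tested <- (pct_a >= params$min_pct | pct_b >= params$min_pct) &
    (det_a + det_b) > 0

  # Detection part: likelihood-ratio (G) statistic of the 2x2 table
  # (detected x group); closed form since the only covariate is binary.
  a <- det_a; b <- na - det_a; c <- det_b; d <- nb - det_b
  n_tot <- na + nb
  row1 <- a + c; row0 <- b + d
  G <- .xlogxy(a, na * row1 / n_tot) + .xlogxy(b, na * row0 / n_tot) +
    .xlogxy(c, nb * row1 / n_tot) + .xlogxy(d, nb * row0 / n_tot)
  G <- 2 * G
  df_disc <- as.numeric(row1 > 0 & row0 > 0)
  G[df_disc == 0] <- 0

  # Continuous part over detected cells (zeros contribute nothing to the
  # sums, and detected values are strictly positive).
  sa <- Matrix::rowSums(xa); sb <- Matrix::rowSums(xb)
  qa <- Matrix::rowSums(xa^2); qb <- Matrix::rowSums(xb^2)
  rss1 <- pmax(0, qa - ifelse(det_a > 0, sa^2 / det_a, 0)) +
    pmax(0, qb - ifelse(det_b > 0, sb^2 / det_b, 0))
  n_det <- det_a + det_b
  rss0 <- pmax(0, (qa + qb) - ifelse(n_det > 0, (sa + sb)^2 / n_det, 0))
  cont_ok <- det_a >= 1 & det_b >= 1 & n_det >= 3
  degenerate <- cont_ok & rss1 <= .Machine$double.eps * pmax(1, rss0)
  rss1_f <- pmax(rss1, .Machine$double.eps * pmax(1, rss0))
  lr_cont <- ifelse(cont_ok & rss0 > 0, n_det * log(rss0 / rss1_f), 0)
  lr_cont <- pmax(lr_cont, 0)
  df_cont <- as.numeric(cont_ok & rss0 > 0)

  stat <- G + lr_cont
  df <- df_disc + df_cont
  p <- ifelse(df > 0, stats::pchisq(stat, df, lower.tail = FALSE), 1)

  mean_a <- Matrix::rowSums(expm1(xa)) / na
  mean_b <- Matrix::rowSums(expm1(xb)) / nb
  logfc <- log(mean_a + 1) - log(mean_b + 1)

  adj <- rep(NA_real_, length(p))
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")

  out <- data.frame(
    gene = rownames(lognorm),
    logFC = logfc,
    p_value = ifelse(tested, p, NA_real_),
    adj_p = adj,
    pct_a = pct_a,
    pct_b = pct_b,
    direction = ifelse(logfc > 0, "up", ifelse(logfc < 0, "down", "none")),
    tested = tested,
    flagged = tested & (degenerate | df_disc == 0 | a == 0 | b == 0 | c == 0 | d == 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", class(out))
  out
}

# Per-gene glm fits with a cellular-detection-rate covariate; slower path.
.hurdle_cdr <- function(xa, xb, params) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  na <- ncol(xa); nb <- ncol(xb)
  grp <- c(rep(1, na), rep(0, nb))
  x <- cbind(xa, xb)
  cdr <- colMeans(x > 0)
  det <- x > 0
  pct_a <- rowMeans(det[, seq_len(na), drop = FALSE])
  pct_b <- rowMeans(det[, na + seq_len(nb), drop = FALSE])
  tested <- (pct_a >= params$min_pct | pct_b >= params$min_pct) &
    rowSums(det) > 0

  stat <- df <- numeric(nrow(x)); flag <- logical(nrow(x))
  for (g in which(tested)) {
    y_det <- as.numeric(det[g, ])
    lr <- 0; dfg <- 0
    if (length(unique(y_det)) > 1) {
      f1 <- suppressWarnings(stats::glm(y_det ~ grp + cdr, family = stats::binomial()))
      f0 <- suppressWarnings(stats::glm(y_det ~ cdr, family = stats::binomial()))
      lr <- lr + max(0, f0$deviance - f1$deviance)
      dfg <- dfg + 1
      flag[g] <- flag[g] || !f1$converged
    }
    on_cells <- which(y_det == 1)
    if (length(unique(grp[on_cells])) > 1 && length(on_cells) >= 3) {
      yv <- x[g, on_cells]
      f1 <- stats::lm(yv ~ grp[on_cells] + cdr[on_cells])
      f0 <- stats::lm(yv ~ cdr[on_cells])
      rss1 <- sum(stats::resid(f1)^2); rss0 <- sum(stats::resid(f0)^2)
      if (rss1 > 0 && rss0 > 0) {
        lr <- lr + length(on_cells) * log(rss0 / rss1)
        dfg <- dfg + 1
      } else {
        flag[g] <- TRUE
      }
    }
    stat[g] <- lr; df[g] <- dfg
  }
  p <- ifelse(tested & df > 0, stats::pchisq(stat, df, lower.tail = FALSE), NA_real_)
  mean_a <- rowMeans(expm1(xa)); mean_b <- rowMeans(expm1(xb))
  logfc <- log(mean_a + 1) - log(mean_b + 1)
  adj <- rep(NA_real_, length(p))
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(
    gene = rownames(x), logFC = logfc, p_value = p, adj_p = adj,
    pct_a = pct_a, pct_b = pct_b,
    direction = ifelse(logfc > 0, "up", ifelse(logfc < 0, "down", "none")),
    tested = tested, flagged = flag, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", class(out))
  out
}

#' Select differentially expressed genes
#'
#' Applies the strict selection thresholds: `logFC > lfc_threshold` (up) or
#' `logFC < -lfc_threshold` (down), with `adj_p < alpha`.
#'
#' @param result a [hurdle_test()] result.
#' @param params a [de_params()].
#' @param direction "up", "down" or "both".
#' @return list with `up`, `down` and `selected` gene vectors (per
#'   `direction`).
#' @export
select_degs <- function(result, params = de_params(),
                        direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  ok <- result$tested & !is.na(result$adj_p) & result$adj_p < params$alpha
  up <- result$gene[ok & result$logFC > params$lfc_threshold]
  down <- result$gene[ok & result$logFC < -params$lfc_threshold]
  selected <- switch(direction, up = up, down = down, both = c(up, down))
  list(up = up, down = down, selected = selected)
}
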