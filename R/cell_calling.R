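#' Ranked-barcode UMI profile
#'
#' Computes per-barcode UMI totals and orders them for the classic ranked
#' barcode (log-log) plot that droplet cell calling works from. Zero-total
#' barcodes are excluded; ties in total are broken by barcode lexicographic
#' order.
#'
#' @param counts genes x barcodes count matrix (dense or sparse) with
#'   barcode column names.
#' @return list of class `ranked_profile` with `barcodes`, `totals`
#'   (non-increasing), `log_rank` and `log_total` (log10).
#' @export
rank_profile <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (all(totals == 0)) stop("all-zero matrix: no barcodes with counts")
  keep <- totals > 0
  totals <- totals[keep]
  bc <- colnames(counts)[keep]
  if (is.null(bc)) bc <- as.character(which(keep))
  ord <- order(-totals, bc)
  structure(
    list(
      barcodes = bc[ord],
      totals = totals[ord],
      log_rank = log10(seq_along(ord)),
      log_total = log10(totals[ord])
    ),
    class = "ranked_profile"
  )
}

#' Knee and inflection points of a ranked-barcode profile
#'
#' Landmarks of the log10(total) vs log10(rank) curve restricted to distinct
#' totals (each total represented at the smallest rank attaining it). The
#' inflection is the total at the bottom of the steepest drop (most negative
#' first difference of the raw distinct-totals curve, following the
#' established ranked-barcode convention); the knee is the total at the most
#' negative signed curvature `y'' / (1 + y'^2)^(3/2)`, searched only at ranks
#' at or before the inflection rank, with derivatives taken as central finite
#' differences on a smoothing spline fit evaluated over a uniform grid in
#' log-rank.
#'
#' @param profile a [rank_profile()].
#' @param n_grid evaluation grid size.
#' @return list with `knee_total`, `inflection_total`, `low_confidence`
#'   (TRUE when the curvature signal is negligible, e.g. a straight log-log
#'   profile), and the evaluation grid (`grid_log_rank`, `grid_log_total`).
#' @export
knee_inflection <- function(profile, n_grid = 512L) {
  stopifnot(inherits(profile, "ranked_profile"))
  dup <- duplicated(profile$totals)
  x <- profile$log_rank[!dup]
  y <- profile$log_total[!dup]
  if (length(x) < 3) stop("degenerate profile: fewer than 3 distinct totals")

  # inflection: lower end of the steepest raw segment
  d1raw <- diff(y) / diff(x)
  i_inf_raw <- which.min(d1raw) + 1L
  inflection_total <- 10^y[i_inf_raw]
  x_inf <- x[i_inf_raw]

  xg <- seq(min(x), max(x), length.out = n_grid)
  yg <- if (length(x) >= 4) {
    fit <- stats::smooth.spline(x, y)
    stats::predict(fit, xg)$y
  } else {
    stats::approx(x, y, xout = xg)$y
  }

  h <- xg[2] - xg[1]
  n <- length(xg)
  d1 <- c(NA, (yg[3:n] - yg[1:(n - 2)]) / (2 * h), NA)
  d2 <- c(NA, (yg[3:n] - 2 * yg[2:(n - 1)] + yg[1:(n - 2)]) / h^2, NA)
  curv <- d2 / (1 + d1^2)^1.5

  interior <- 2:(n - 1)
  knee_cand <- interior[xg[interior] <= x_inf]
  if (length(knee_cand) == 0) knee_cand <- interior
  i_knee <- knee_cand[which.min(curv[knee_cand])]
  knee_total <- max(10^yg[i_knee], inflection_total)

  curv_span <- diff(range(curv[interior], na.rm = TRUE))
  list(
    knee_total = knee_total,
    inflection_total = inflection_total,
    low_confidence = curv_span < 1e-3,
    grid_log_rank = xg,
    grid_log_total = yg
  )
}

#' Density-minimum UMI threshold between knee and inflection
#'
#' Calls cells at a UMI threshold placed at a local minimum of the
#' standardized kernel density of log10 barcode totals. The density is a
#' Gaussian KDE on a uniform grid with Silverman's bandwidth, rescaled to a
#' maximum of 1 (standardization does not move its minima). Candidate minima
#' must fall between the inflection and knee totals; if several qualify the
#' deepest is taken (ties resolved toward the larger total), and if none
#' qualify the local minimum nearest (in log10 distance) to that interval is
#' used and flagged as a fallback. Barcodes with totals greater than or equal
#' to the threshold are called cells.
#'
#' @param profile a [rank_profile()].
#' @param knee_total,inflection_total landmarks from [knee_inflection()].
#' @param n_grid KDE grid size.
#' @return list of class `cell_call` with `threshold_total`, `used_fallback`,
#'   `called_barcodes`, and the density grid (`grid_log_total`, `density`,
#'   `minima_idx`).
#' @export
density_threshold <- function(profile, knee_total, inflection_total,
                              n_grid = 512L) {
  stopifnot(inherits(profile, "ranked_profile"),
            knee_total >= inflection_total)
  lt <- profile$log_total
  d <- stats::density(lt, bw = "nrd0", n = n_grid, from = min(lt), to = max(lt))
  dens <- d$y / max(d$y)
  grid <- d$x

  mins <- .local_minima(dens)
  if (length(mins) == 0) stop("unimodal density: cannot call cells")

  lo <- log10(inflection_total)
  hi <- log10(knee_total)
  in_window <- mins[grid[mins] >= lo & grid[mins] <= hi]
  if (length(in_window) > 0) {
    best <- in_window[dens[in_window] == min(dens[in_window])]
    pick <- best[which.max(grid[best])]  # tie -> larger total
    used_fallback <- FALSE
  } else {
    dist_to_window <- pmax(0, pmax(lo - grid[mins], grid[mins] - hi))
    pick <- mins[which.min(dist_to_window)]
    used_fallback <- TRUE
  }

  threshold <- 10^grid[pick]
  called <- profile$barcodes[profile$totals >= threshold]
  structure(
    list(
      threshold_total = threshold,
      used_fallback = used_fallback,
      called_barcodes = called,
      grid_log_total = grid,
      density = dens,
      minima_idx = mins
    ),
    class = "cell_call"
  )
}

# Strict interior local minima: sign change of first differences.
.local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] < y[3:n]) + 1L
}

#' Call cells from a raw droplet count matrix
#'
#' Convenience wrapper chaining [rank_profile()], [knee_inflection()] and
#' [density_threshold()].
#'
#' @param counts genes x barcodes count matrix.
#' @param n_grid grid size for both the landmark and density curves.
#' @return a `cell_call` (see [density_threshold()]) with the profile and
#'   landmarks attached as `profile`, `knee_total`, `inflection_total`.
#' @export
call_cells <- function(counts, n_grid = 512L) {
  prof <- rank_profile(counts)
  ki <- knee_inflection(prof, n_grid = n_grid)
  res <- density_threshold(prof, ki$knee_total, ki$inflection_total,
                           n_grid = n_grid)
  res$profile <- prof
  res$knee_total <- ki$knee_total
  res$inflection_total <- ki$inflection_total
  res
}
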