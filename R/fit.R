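#' Fit guide-level expression shifts for one or more sorting screens
#'
#' The central estimator. For every guide in every experiment it finds the
#' maximum-likelihood mean expression shift \code{mu_hat} (in SD units of the
#' overall, quantile-normalised expression distribution) implied by the
#' guide's read counts across sorting bins, then re-centres the estimates
#' against the negative-control guides to produce per-guide Z-scores:
#' \code{z_score = mu_hat - centre(mu_hat of controls)}. By construction the
#' controls' mean Z is exactly zero (with \code{center = "mean"}).
#'
#' The model: cells carrying a guide express Normal(\code{mu}, 1) in
#' standard-normal sorting space; the expected fraction of a bin's reads
#' belonging to the guide is its unsorted-library fraction scaled by its
#' relative bin occupancy; observed counts are negative-binomial draws with
#' size equal to the bin's total reads. A depth-scaled pseudocount
#' (\code{pseudocount} per million reads of bin coverage) regularises poorly
#' covered guides toward no effect.
#'
#' @param counts data frame with columns \code{guide_id},
#'   \code{is_negative_control} (logical or 0/1), one numeric count column
#'   per bin (named as in \code{bins$bin_id}), \code{unsorted}, and
#'   optionally \code{experiment_id}, \code{chrom}, \code{pos},
#'   \code{element_label} plus any extra annotation columns (carried
#'   through).
#' @param bins a \code{\link{sorting_bins}} data frame; must cover every
#'   experiment present in \code{counts}.
#' @param pseudocount pseudocounts per million reads of bin coverage
#'   (default 10).
#' @param mu_limits search bounds for the shift, SD units (default
#'   \code{c(-5, 5)}; far beyond any realistic FACS shift).
#' @param tol optimiser convergence tolerance (default \code{1e-4}).
#' @param center how to centre against negative controls: \code{"mean"}
#'   (default) or the outlier-robust \code{"median"}.
#'
#' @return An object of class \code{"sortshift"}: a list with
#'   \item{guides}{data frame of per-guide results: annotations,
#'     \code{mu_hat}, \code{z_score}, \code{ll_ratio},
#'     \code{unquantifiable}.}
#'   \item{bins}{the bin definitions used.}
#'   \item{counts}{the input counts (with derived totals attached as
#'     attributes per experiment).}
#'   \item{params}{fitting parameters.}
#' Supports \code{print}, \code{summary}, \code{coef}, \code{predict},
#' \code{residuals}, \code{simulate} and \code{plot} methods.
#' @examples
#' sim <- simulate_screen(screen_config(n_elements = 4, n_controls = 20,
#'                                      effects = c(0.5, 1)), seed = 1)
#' fit <- sortshift(sim$counts, sim$bins)
#' head(coef(fit))
#' @seealso \code{\link{element_stats}} for aggregating guides into elements.
#' @export
sortshift <- function(counts, bins, pseudocount = 10, mu_limits = c(-5, 5),
                      tol = 1e-4, center = c("mean", "median")) {
  center <- match.arg(center)
  counts <- validate_counts(counts, bins)
  experiments <- unique(counts$experiment_id)

  res <- lapply(experiments, function(ex) {
    cts <- counts[counts$experiment_id == ex, , drop = FALSE]
    b <- bins_for(bins, ex)
    if (nrow(b) == 0)
      stop("no bin definitions for experiment ", ex)
    fit_one_experiment(cts, b, pseudocount, mu_limits, tol, center)
  })
  guides <- do.call(rbind, res)
  rownames(guides) <- NULL

  structure(list(guides = guides, bins = bins, counts = counts,
                 params = list(pseudocount = pseudocount,
                               mu_limits = mu_limits, tol = tol,
                               center = center),
                 call = match.call()),
            class = "sortshift")
}

# one experiment: counts rows for that experiment, bins rows for it
fit_one_experiment <- function(cts, b, pseudocount, mu_limits, tol, center) {
  bin_ids <- b$bin_id
  cmat <- as.matrix(cts[, bin_ids, drop = FALSE])
  R_b <- colSums(cmat)
  R_0 <- sum(cts$unsorted)
  if (R_0 <= 0) stop("unsorted library has zero total reads in experiment ",
                     cts$experiment_id[1])
  lib_frac <- cts$unsorted / R_0
  pseudo <- pseudocount * R_b / 1e6

  n <- nrow(cts)
  mu_hat <- numeric(n); ll_ratio <- numeric(n); unq <- logical(n)
  for (i in seq_len(n)) {
    if (lib_frac[i] <= 0) { unq[i] <- TRUE; next }
    k <- cmat[i, ] + pseudo
    f <- function(m) guide_loglik(m, k, R_b, lib_frac[i], b)
    opt <- stats::optimize(f, interval = mu_limits, maximum = TRUE, tol = tol)
    ll0 <- f(0)
    if (is.finite(opt$objective) && opt$objective > ll0) {
      mu_hat[i] <- opt$maximum
      ll_ratio[i] <- opt$objective - ll0
    }
  }

  ctrl <- as.logical(cts$is_negative_control) & !unq
  if (!any(ctrl))
    stop("screen analysis requires negative control guides; none found in ",
         "experiment ", cts$experiment_id[1])
  z <- guide_z_scores(mu_hat, ctrl, center)
  z[unq] <- NA_real_

  keep <- intersect(c("guide_id", "experiment_id", "is_negative_control",
                      "chrom", "pos", "element_label"), names(cts))
  out <- cts[, keep, drop = FALSE]
  out$mu_hat <- mu_hat
  out$z_score <- z
  out$ll_ratio <- ll_ratio
  out$unquantifiable <- unq
  out
}

# shared input validation; normalises experiment_id and control flag
validate_counts <- function(counts, bins) {
  if (!is.data.frame(counts)) stop("counts must be a data frame")
  required <- c("guide_id", "is_negative_control", "unsorted")
  miss <- setdiff(required, names(counts))
  if (length(miss))
    stop("counts is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"experiment_id" %in% names(counts))
    counts$experiment_id <- if (length(unique(bins$experiment_id)) == 1)
      bins$experiment_id[1] else
        stop("counts lacks experiment_id but bins define several experiments")
  counts$is_negative_control <- parse_flag(counts$is_negative_control)

  for (ex in unique(counts$experiment_id)) {
    bin_ids <- bins$bin_id[bins$experiment_id == ex]
    if (length(bin_ids) == 0 && length(unique(bins$experiment_id)) == 1)
      bin_ids <- bins$bin_id
    miss <- setdiff(bin_ids, names(counts))
    if (length(miss))
      stop("counts is missing bin column(s) for experiment ", ex, ": ",
           paste(miss, collapse = ", "))
    sub <- counts[counts$experiment_id == ex, ]
    if (anyDuplicated(sub$guide_id))
      stop("duplicate guide_id within experiment ", ex, ": ",
           sub$guide_id[duplicated(sub$guide_id)][1])
    cm <- as.matrix(sub[, c(bin_ids, "unsorted")])
    if (!is.numeric(cm) || any(is.na(cm)) || any(cm < 0))
      stop("negative or non-numeric read counts in experiment ", ex)
  }
  counts
}

#' Centre guide shifts against negative controls
#'
#' Converts raw maximum-likelihood shifts into Z-scores by subtracting the
#' centre (mean by default) of the negative-control shifts, so controls
#' average exactly zero. Targeting guides with real effects can drag the
#' overall distribution; anchoring on controls removes that drift.
#'
#' @param mu_hat numeric vector of fitted shifts for one experiment.
#' @param is_control logical vector marking the negative-control guides.
#' @param center \code{"mean"} (default; controls then average exactly 0) or
#'   \code{"median"}.
#' @return numeric vector of Z-scores.
#' @export
guide_z_scores <- function(mu_hat, is_control, center = c("mean", "median")) {
  center <- match.arg(center)
  is_control <- as.logical(is_control)
  if (!any(is_control))
    stop("screen analysis requires negative control guides")
  centre_fun <- if (center == "mean") mean else stats::median
  mu_hat - centre_fun(mu_hat[is_control])
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' @export
print.sortshift <- function(x, ...) {
  g <- x$guides
  cat("Sorting-screen guide fit\n")
  cat(sprintf("  experiments: %s\n",
              paste(unique(g$experiment_id), collapse = ", ")))
  cat(sprintf("  guides: %d (%d negative controls, %d unquantifiable)\n",
              nrow(g), sum(g$is_negative_control), sum(g$unquantifiable)))
  cat(sprintf("  bins per experiment: %d\n",
              length(unique(x$bins$bin_id))))
  cat(sprintf("  mu_hat range: [%.3f, %.3f] SD\n",
              min(g$mu_hat), max(g$mu_hat)))
  invisible(x)
}

#' @export
summary.sortshift <- function(object, ...) {
  g <- object$guides
  per_ex <- do.call(rbind, lapply(split(g, g$experiment_id), function(d) {
    ctrl <- d$is_negative_control & !d$unquantifiable
    data.frame(experiment_id = d$experiment_id[1],
               n_guides = nrow(d),
               n_controls = sum(d$is_negative_control),
               n_unquantifiable = sum(d$unquantifiable),
               control_mu_centre = mean(d$mu_hat[ctrl]),
               control_z_sd = stats::sd(d$z_score[ctrl]),
               max_abs_z = max(abs(d$z_score), na.rm = TRUE))
  }))
  rownames(per_ex) <- NULL
  out <- list(experiments = per_ex, params = object$params)
  class(out) <- "summary.sortshift"
  out
}

#' @export
print.summary.sortshift <- function(x, ...) {
  cat("Sorting-screen guide fit summary\n\n")
  print(x$experiments, row.names = FALSE, digits = 4)
  cat(sprintf("\npseudocount %g per million; mu in [%g, %g]; tol %g; %s-centred\n",
              x$params$pseudocount, x$params$mu_limits[1],
              x$params$mu_limits[2], x$params$tol, x$params$center))
  invisible(x)
}

#' Extract fitted guide shifts
#'
#' @param object a \code{\link{sortshift}} fit.
#' @param type \code{"mu"} for the raw MLE shifts or \code{"z"} for
#'   control-centred Z-scores.
#' @param ... unused.
#' @return named numeric vector (single experiment) or a guides-by-
#'   experiments matrix.
#' @export
coef.sortshift <- function(object, type = c("mu", "z"), ...) {
  type <- match.arg(type)
  g <- object$guides
  val <- if (type == "mu") g$mu_hat else g$z_score
  exs <- unique(g$experiment_id)
  if (length(exs) == 1) return(stats::setNames(val, g$guide_id))
  ids <- unique(g$guide_id)
  m <- matrix(NA_real_, length(ids), length(exs),
              dimnames = list(ids, exs))
  m[cbind(match(g$guide_id, ids), match(g$experiment_id, exs))] <- val
  m
}

#' Expected per-bin read fractions or counts at the fitted shifts
#'
#' @param object a \code{\link{sortshift}} fit.
#' @param type \code{"fraction"} returns the expected fraction of each bin's
#'   reads belonging to each guide at its fitted \code{mu_hat};
#'   \code{"count"} scales by the NB mean, \code{R_b p/(1-p)}.
#' @param ... unused.
#' @return data frame with guide_id, experiment_id and one column per bin.
#' @export
predict.sortshift <- function(object, type = c("fraction", "count"), ...) {
  type <- match.arg(type)
  g <- object$guides
  counts <- object$counts
  out <- lapply(unique(g$experiment_id), function(ex) {
    b <- bins_for(object$bins, ex)
    cts <- counts[counts$experiment_id == ex, ]
    gg <- g[g$experiment_id == ex, ]
    R_b <- colSums(as.matrix(cts[, b$bin_id, drop = FALSE]))
    lf <- cts$unsorted / sum(cts$unsorted)
    p <- t(vapply(seq_len(nrow(gg)), function(i)
      expected_read_fraction(lf[i], b, gg$mu_hat[i]), numeric(nrow(b))))
    colnames(p) <- b$bin_id
    if (type == "count") p <- sweep(p / (1 - p), 2, R_b, `*`)
    cbind(gg[, c("guide_id", "experiment_id")], as.data.frame(p))
  })
  do.call(rbind, out)
}

#' Pearson residuals of observed bin counts under the fitted model
#'
#' Observed minus expected counts scaled by the negative-binomial standard
#' deviation \code{sqrt(n p / (1-p)^2)}; large absolute values flag guides
#' whose read distribution the single-shift model cannot explain.
#'
#' @param object a \code{\link{sortshift}} fit.
#' @param ... unused.
#' @return data frame with guide_id, experiment_id and one residual column
#'   per bin.
#' @export
residuals.sortshift <- function(object, ...) {
  g <- object$guides
  counts <- object$counts
  out <- lapply(unique(g$experiment_id), function(ex) {
    b <- bins_for(object$bins, ex)
    cts <- counts[counts$experiment_id == ex, ]
    gg <- g[g$experiment_id == ex, ]
    obs <- as.matrix(cts[, b$bin_id, drop = FALSE])
    R_b <- colSums(obs)
    lf <- cts$unsorted / sum(cts$unsorted)
    res <- matrix(NA_real_, nrow(gg), nrow(b),
                  dimnames = list(NULL, b$bin_id))
    for (i in seq_len(nrow(gg))) {
      if (lf[i] <= 0) next
      p <- expected_read_fraction(lf[i], b, gg$mu_hat[i])
      mu <- R_b * p / (1 - p)
      res[i, ] <- (obs[i, ] - mu) / sqrt(mu / (1 - p))
    }
    cbind(gg[, c("guide_id", "experiment_id")], as.data.frame(res))
  })
  do.call(rbind, out)
}

#' Simulate new count tables from a fitted screen
#'
#' Draws fresh negative-binomial read counts for every guide at its fitted
#' \code{mu_hat}, keeping the observed bin totals and library composition —
#' a parametric bootstrap of the read-sampling stage.
#'
#' @param object a \code{\link{sortshift}} fit.
#' @param nsim number of replicate tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of count data frames in the input format.
#' @export
simulate.sortshift <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  g <- object$guides
  counts <- object$counts
  replicate(nsim, {
    out <- counts
    for (ex in unique(g$experiment_id)) {
      b <- bins_for(object$bins, ex)
      sel <- counts$experiment_id == ex
      cts <- counts[sel, ]
      gg <- g[g$experiment_id == ex, ]
      R_b <- colSums(as.matrix(cts[, b$bin_id, drop = FALSE]))
      lf <- cts$unsorted / sum(cts$unsorted)
      for (j in seq_len(nrow(b))) {
        p <- vapply(seq_len(nrow(gg)), function(i)
          expected_read_fraction(lf[i], b[j, , drop = FALSE],
                                 gg$mu_hat[i]), numeric(1))
        out[sel, b$bin_id[j]] <- stats::rnbinom(nrow(gg), size = R_b[j],
                                                prob = 1 - pmin(p, 1 - 1e-12))
      }
    }
    out
  }, simplify = FALSE)
}

#' Plot fitted guide Z-scores
#'
#' With genomic positions available, plots Z against position (controls in
#' grey); otherwise overlays the Z-score densities of targeting and control
#' guides.
#'
#' @param x a \code{\link{sortshift}} fit.
#' @param experiment which experiment to plot (default: first).
#' @param ... passed to the underlying plot call.
#' @export
plot.sortshift <- function(x, experiment = NULL, ...) {
  g <- x$guides
  if (is.null(experiment)) experiment <- g$experiment_id[1]
  g <- g[g$experiment_id == experiment & !g$unquantifiable, ]
  if ("pos" %in% names(g) && any(!is.na(g$pos) & !g$is_negative_control)) {
    tg <- g[!g$is_negative_control & !is.na(g$pos), ]
    graphics::plot(tg$pos, tg$z_score, pch = 16, cex = 0.5,
                   xlab = "position (bp)", ylab = "guide Z-score",
                   main = experiment, ...)
    graphics::abline(h = 0, col = "grey60", lty = 2)
  } else {
    dt <- stats::density(g$z_score[!g$is_negative_control])
    dc <- stats::density(g$z_score[g$is_negative_control])
    graphics::plot(dt, col = "firebrick", xlab = "guide Z-score",
                   main = experiment,
                   ylim = range(0, dt$y, dc$y), ...)
    graphics::lines(dc, col = "grey40")
    graphics::legend("topright", c("targeting", "negative control"),
                     col = c("firebrick", "grey40"), lty = 1, bty = "n")
  }
  invisible(x)
}

# bins rows for one experiment, tolerating a single shared layout
bins_for <- function(bins, ex) {
  b <- bins[bins$experiment_id == ex, , drop = FALSE]
  if (nrow(b) == 0 && length(unique(bins$experiment_id)) == 1) b <- bins
  b
}
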