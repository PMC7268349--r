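#' Stouffer combination of guide Z-scores
#'
#' @param z numeric vector of Z-scores (no NAs).
#' @return \code{sum(z) / sqrt(length(z))}.
#' @examples
#' stouffer_combine(c(2, 2, 2, 2))  # 4
#' @export
stouffer_combine <- function(z) {
  if (length(z) == 0) stop("cannot Stouffer-combine an empty set of Z-scores")
  if (any(is.na(z))) stop("NA Z-scores in Stouffer combination")
  sum(z) / sqrt(length(z))
}

#' Resampled negative-control null for Stouffer Z-scores
#'
#' Raw Stouffer Z-scores of real screens are over-dispersed relative to
#' Normal(0, 1): guide-level noise is not exactly unit variance and depends
#' on coverage. The empirical null is built by replicating each
#' negative-control Z-score \code{resample_factor} times into a pool,
#' repeatedly drawing \code{k} scores without replacement, Stouffer-combining
#' each draw, and recording the standard deviation — separately for every
#' guides-per-element count \code{k} in use. Dividing an element's Stouffer Z
#' by the matching null SD yields a statistic that is standard normal under
#' no effect.
#'
#' @param control_z Z-scores of the negative-control guides (one
#'   experiment).
#' @param k_values integer vector of guides-per-element counts needed.
#' @param resample_factor copies of each control in the pool (default 10).
#' @param n_draws null draws per \code{k} (default 10000).
#' @param seed optional integer seed for the draws.
#' @return a list of class \code{"control_null"} with elements \code{sd}
#'   (named numeric vector, one SD per \code{k}), \code{resample_factor},
#'   \code{n_draws} and \code{n_controls}.
#' @export
build_null_model <- function(control_z, k_values, resample_factor = 10,
                             n_draws = 10000, seed = NULL) {
  control_z <- control_z[!is.na(control_z)]
  if (length(control_z) < 2)
    stop("need at least 2 negative-control Z-scores to build a null")
  k_values <- sort(unique(as.integer(k_values)))
  if (length(k_values) == 0) stop("k_values is empty")
  # sorted pool: with a fixed seed the null is invariant to guide input order
  pool <- rep(sort(control_z), each = resample_factor)
  if (max(k_values) > length(pool))
    stop("largest element has more guides (", max(k_values),
         ") than the resampled control pool (", length(pool),
         "); add negative controls or raise resample_factor")
  if (!is.null(seed)) set.seed(seed)
  sds <- vapply(k_values, function(k) {
    draws <- vapply(seq_len(n_draws),
                    function(i) sum(pool[sample.int(length(pool), k)]),
                    numeric(1)) / sqrt(k)
    stats::sd(draws)
  }, numeric(1))
  if (any(sds <= 0))
    stop("degenerate control null (zero variance); controls are identical ",
         "or the pool is exhausted by a single draw")
  structure(list(sd = stats::setNames(sds, k_values),
                 resample_factor = resample_factor, n_draws = n_draws,
                 n_controls = length(control_z)),
            class = "control_null")
}

#' @export
print.control_null <- function(x, ...) {
  cat("Resampled negative-control Stouffer null\n")
  cat(sprintf("  %d controls x %d copies, %d draws per k\n",
              x$n_controls, x$resample_factor, x$n_draws))
  print(round(x$sd, 4))
  invisible(x)
}

# score one guide set: effect, stouffer, significance, tail probabilities
score_guide_set <- function(z, null_sd) {
  k <- length(z)
  sz <- stouffer_combine(z)
  sig <- sz / null_sd
  p_up <- stats::pnorm(sig, lower.tail = FALSE)
  p_down <- stats::pnorm(sig)
  p_min <- min(p_up, p_down)
  data.frame(n_guides = k, effect_z = mean(z), stouffer_z = sz,
             significance_z = sig, p_up = p_up, p_down = p_down,
             p_either = min(1, 2 * p_min), p_min = p_min)
}

#' Significance of one element's guide set against the control null
#'
#' Scales the Stouffer Z by the null SD for the matching guide count, then
#' converts to tail probabilities of the standard normal: \code{p_up}
#' (upregulation), \code{p_down} (downregulation), and a two-tailed
#' \code{p_either = min(1, 2 * min(p_up, p_down))}; the uncorrected minimum
#' is kept as the diagnostic \code{p_min}.
#'
#' @param z member guide Z-scores.
#' @param null a \code{\link{build_null_model}} object with an entry for
#'   \code{length(z)}.
#' @return one-row data frame: \code{n_guides}, \code{effect_z},
#'   \code{stouffer_z}, \code{significance_z}, \code{p_up}, \code{p_down},
#'   \code{p_either}, \code{p_min}.
#' @export
element_significance <- function(z, null) {
  k <- as.character(length(z))
  if (!k %in% names(null$sd))
    stop("null model has no entry for elements with ", k, " guides")
  score_guide_set(z, null$sd[[k]])
}

#' Element-level statistics from a fitted screen
#'
#' Aggregates guide Z-scores into elements — either a-priori annotated
#' groups (\code{by = "annotation"}, using the \code{element_label} column)
#' or de-novo sliding windows over guide genomic positions
#' (\code{by = "window"}) — and scores each element against the resampled
#' negative-control null. Benjamini-Hochberg FDR is applied separately per
#' experiment and per tail family (up, down, either).
#'
#' Sliding windows: for each chromosome, a candidate window of width
#' \code{window_bp} is anchored at every guide position; the guide sets of
#' all candidate windows are deduplicated (windows shifted by less than one
#' inter-guide gap contain identical sets) and sets smaller than
#' \code{min_guides} are dropped. Reported coordinates span the member
#' guides, not the arbitrary window grid.
#'
#' @param fit a \code{\link{sortshift}} fit (or a guide data frame with the
#'   same columns).
#' @param by \code{"annotation"} or \code{"window"}.
#' @param window_bp sliding-window width in bp (default 500).
#' @param min_guides minimum guides per element (default 5); smaller
#'   annotated elements are dropped with a warning.
#' @param resample_factor,n_draws,seed null-model parameters; see
#'   \code{\link{build_null_model}}.
#' @return data frame of class \code{"element_stats"}: element identity
#'   (\code{element_id} or \code{chrom}/\code{start}/\code{end}),
#'   \code{experiment_id}, \code{n_guides}, \code{effect_z},
#'   \code{stouffer_z}, \code{significance_z}, \code{p_up}, \code{p_down},
#'   \code{p_either}, \code{p_min}, \code{fdr_up}, \code{fdr_down},
#'   \code{fdr_either}.
#' @examples
#' sim <- simulate_screen(screen_config(n_elements = 10, n_controls = 50,
#'                                      effects = rep(1, 5)), seed = 1)
#' fit <- sortshift(sim$counts, sim$bins)
#' head(element_stats(fit, n_draws = 500, seed = 2))
#' @export
element_stats <- function(fit, by = c("annotation", "window"),
                          window_bp = 500, min_guides = 5,
                          resample_factor = 10, n_draws = 10000,
                          seed = NULL) {
  by <- match.arg(by)
  guides <- if (inherits(fit, "sortshift")) fit$guides else fit
  guides <- guides[!guides$unquantifiable & !is.na(guides$z_score), ]

  out <- lapply(unique(guides$experiment_id), function(ex) {
    g <- guides[guides$experiment_id == ex, ]
    sets <- if (by == "annotation")
      annotated_guide_sets(g, min_guides)
    else
      window_guide_sets(g, window_bp, min_guides)
    if (length(sets$rows) == 0) return(NULL)
    ctrl_z <- g$z_score[g$is_negative_control]
    ks <- unique(vapply(sets$rows, length, integer(1)))
    null <- build_null_model(ctrl_z, ks, resample_factor, n_draws,
                             seed = seed)
    scores <- do.call(rbind, lapply(sets$rows, function(idx)
      element_significance(g$z_score[idx], null)))
    res <- cbind(sets$meta, experiment_id = ex, scores)
    res
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    warning("no elements with at least ", min_guides, " guides")
    return(structure(data.frame(), class = c("element_stats", "data.frame")))
  }
  rownames(out) <- NULL
  # BH per experiment and per tail family
  for (tail in c("up", "down", "either")) {
    p <- out[[paste0("p_", tail)]]
    out[[paste0("fdr_", tail)]] <- stats::ave(
      p, out$experiment_id, FUN = function(v) stats::p.adjust(v, "BH"))
  }
  class(out) <- c("element_stats", "data.frame")
  out
}

# group rows by element_label
annotated_guide_sets <- function(g, min_guides) {
  if (!"element_label" %in% names(g))
    stop("guide table has no element_label column; use by = \"window\" ",
         "for position-based elements")
  labelled <- which(!g$is_negative_control & !is.na(g$element_label) &
                      g$element_label != "")
  idx <- split(labelled, g$element_label[labelled])
  small <- vapply(idx, length, integer(1)) < min_guides
  if (any(small))
    warning(sum(small), " element(s) with fewer than ", min_guides,
            " guides excluded: ",
            paste(utils::head(names(idx)[small], 5), collapse = ", "))
  idx <- idx[!small]
  list(rows = unname(idx),
       meta = data.frame(element_id = names(idx), stringsAsFactors = FALSE))
}

# enumerate unique guide sets of fixed-width windows anchored at guides
window_guide_sets <- function(g, window_bp, min_guides) {
  if (!all(c("chrom", "pos") %in% names(g)) || all(is.na(g$pos)))
    stop("guide table has no chrom/pos columns; use by = \"annotation\" ",
         "for labelled elements")
  g_t <- which(!g$is_negative_control & !is.na(g$pos))
  rows <- list(); meta <- list()
  for (ch in unique(g$chrom[g_t])) {
    idx <- g_t[g$chrom[g_t] == ch]
    idx <- idx[order(g$pos[idx], g$guide_id[idx])]
    pos <- g$pos[idx]
    seen <- character(0)
    for (a in unique(pos)) {
      inwin <- idx[pos >= a & pos <= a + window_bp]
      if (length(inwin) < min_guides) next
      key <- paste(sort(g$guide_id[inwin]), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- inwin
      meta[[length(meta) + 1L]] <- data.frame(
        chrom = ch, start = min(g$pos[inwin]), end = max(g$pos[inwin]),
        stringsAsFactors = FALSE)
    }
  }
  list(rows = rows,
       meta = if (length(meta)) do.call(rbind, meta) else
         data.frame(chrom = character(), start = integer(),
                    end = integer()))
}

#' @export
print.element_stats <- function(x, ...) {
  cat(sprintf("Element-level statistics: %d elements, %d experiment(s)\n",
              nrow(x), length(unique(x$experiment_id))))
  if (nrow(x)) {
    cat(sprintf("  significant at 1%% FDR (either tail): %d\n",
                sum(x$fdr_either < 0.01)))
    print.data.frame(utils::head(x[order(x$p_either), ], 10), digits = 3,
                     row.names = FALSE)
  }
  invisible(x)
}

#' Elements reproducibly called across replicate experiments
#'
#' Keeps elements that pass the FDR threshold in \emph{every} replicate
#' and, optionally, shift expression in the same direction in all of them.
#'
#' @param elements an \code{\link{element_stats}} data frame covering two or
#'   more experiments that share element definitions.
#' @param fdr_threshold FDR cutoff applied per replicate (default 0.01).
#' @param tail which FDR column to threshold: \code{"either"} (default),
#'   \code{"up"} or \code{"down"}.
#' @param require_consistent_sign demand a common sign of \code{effect_z}
#'   across replicates (default TRUE).
#' @return data frame with one row per called element: identity columns,
#'   \code{n_replicates}, \code{direction} (\code{"up"}/\code{"down"}),
#'   \code{mean_effect_z}, \code{max_fdr}.
#' @export
combine_replicates <- function(elements, fdr_threshold = 0.01,
                               tail = c("either", "up", "down"),
                               require_consistent_sign = TRUE) {
  tail <- match.arg(tail)
  if (nrow(elements) == 0) return(elements)
  id_cols <- intersect(c("element_id", "chrom", "start", "end"),
                       names(elements))
  key <- do.call(paste, c(elements[id_cols], sep = "\r"))
  n_rep <- length(unique(elements$experiment_id))
  if (n_rep < 2)
    stop("combine_replicates needs element results from >= 2 experiments")
  fdr_col <- paste0("fdr_", tail)
  keep <- tapply(seq_len(nrow(elements)), key, function(i) {
    if (length(unique(elements$experiment_id[i])) < n_rep) return(NULL)
    if (any(elements[[fdr_col]][i] >= fdr_threshold)) return(NULL)
    s <- sign(elements$effect_z[i])
    if (require_consistent_sign && length(unique(s)) > 1) return(NULL)
    data.frame(elements[i[1], id_cols, drop = FALSE],
               n_replicates = length(i),
               direction = if (mean(elements$effect_z[i]) > 0) "up" else "down",
               mean_effect_z = mean(elements$effect_z[i]),
               max_fdr = max(elements[[fdr_col]][i]),
               stringsAsFactors = FALSE)
  })
  keep <- keep[!vapply(keep, is.null, logical(1))]
  if (length(keep) == 0) {
    warning("no elements reproducible across all replicates")
    return(data.frame())
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Convert a guide or element Z-score to percent of normal expression
#'
#' Z-scores live in SD units of the overall (log-scale) FACS distribution.
#' Given the distribution's log-mean and log-SD and the measured log
#' expression of wild type and of a null mutant, a Z maps back to log
#' expression \code{x = sigma * z + mu_log} and then to
#' \deqn{\%EL(x) = 100 \times \frac{10^x - 10^{EL_{null}}}{10^{EL_{wt}} -
#' 10^{EL_{null}}}.}
#'
#' @param z Z-score(s).
#' @param sigma SD of log FACS expression.
#' @param mu_log mean of log FACS expression.
#' @param el_wt log expression of wild type; must exceed \code{el_null}.
#' @param el_null log expression of a null mutant; \code{-Inf} gives the
#'   no-background limit \code{100 * 10^(x - el_wt)}.
#' @return percentage(s) of normal expression.
#' @export
percent_normal_expression <- function(z, sigma, mu_log, el_wt, el_null) {
  if (el_wt <= el_null)
    stop("el_wt must exceed el_null; percent of normal is undefined")
  x <- sigma * z + mu_log
  if (is.infinite(el_null) && el_null < 0)
    return(100 * 10^(x - el_wt))
  100 * (10^x - 10^el_null) / (10^el_wt - 10^el_null)
}
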