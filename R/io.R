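#' Read a guide count table
#'
#' Tab-separated, UTF-8, header row, \code{#} comment lines, no quoting.
#' Required columns: \code{guide_id}, \code{is_negative_control} (0/1 or
#' true/false), one integer column per bin, \code{unsorted}. Optional:
#' \code{experiment_id}, \code{chrom}, \code{pos}, \code{element_label};
#' any further annotation columns are preserved. Duplicate guide IDs within
#' an experiment, negative counts and missing bin columns are rejected.
#'
#' @param path file path.
#' @param bins the \code{\link{sorting_bins}} the counts must cover (used
#'   for validation); optional.
#' @return validated data frame of guide counts.
#' @export
read_guide_counts <- function(path, bins = NULL) {
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("guide_id", "is_negative_control", "unsorted")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  count_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                        c("pos", "start", "end", "is_negative_control"))
  for (col in count_cols) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      stop(path, ": negative count in column '", col, "', row ", bad[1])
  }
  if (!is.null(bins)) df <- validate_counts(df, bins)
  df
}

#' Read per-experiment bin definitions
#'
#' Tab-separated with columns \code{experiment_id} (optional when a single
#' layout is shared), \code{bin_id}, \code{binStartQ}, \code{binEndQ} and
#' optionally \code{binStartZ}, \code{binEndZ}. Z bounds are recomputed from
#' the quantiles when absent and validated against them
#' (\code{|pnorm(Z) - Q| <= 1e-6}) when present.
#'
#' @param path file path.
#' @return a \code{\link{sorting_bins}} data frame covering all experiments
#'   in the file.
#' @export
read_bins <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("bin_id", "binStartQ", "binEndQ")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  if (!"experiment_id" %in% names(df)) df$experiment_id <- "expt"
  has_z <- all(c("binStartZ", "binEndZ") %in% names(df))
  sorting_bins(bin_id = df$bin_id, startQ = df$binStartQ, endQ = df$binEndQ,
               startZ = if (has_z) df$binStartZ else NULL,
               endZ = if (has_z) df$binEndZ else NULL,
               experiment_id = df$experiment_id)
}

#' Write bin definitions
#'
#' @param bins a \code{\link{sorting_bins}} data frame.
#' @param path output path.
#' @param header_comments extra \code{#} comment lines.
#' @export
write_bins <- function(bins, path, header_comments = character()) {
  out <- data.frame(experiment_id = bins$experiment_id, bin_id = bins$bin_id,
                    binStartQ = bins$startQ, binEndQ = bins$endQ,
                    binStartZ = bins$startZ, binEndZ = bins$endZ)
  out <- out[order(out$experiment_id, out$binStartQ), ]
  write_tsv(out, path, header_comments)
}

#' Write the per-guide result table
#'
#' Columns \code{guide_id}, \code{experiment_id}, \code{mu_hat},
#' \code{z_score}, \code{ll_ratio}, \code{unquantifiable} (plus any guide
#' annotations), sorted by experiment then guide, with \code{#} header
#' comments recording parameters.
#'
#' @param fit a \code{\link{sortshift}} fit.
#' @param path output path.
#' @param header_comments extra comment lines (e.g. the seed).
#' @export
write_guide_results <- function(fit, path, header_comments = character()) {
  g <- fit$guides[order(fit$guides$experiment_id, fit$guides$guide_id), ]
  hdr <- c(sprintf("sortshift %s guide results",
                   as.character(utils::packageVersion("sortshift"))),
           sprintf("pseudocount=%g mu_limits=[%g,%g] tol=%g center=%s",
                   fit$params$pseudocount, fit$params$mu_limits[1],
                   fit$params$mu_limits[2], fit$params$tol,
                   fit$params$center),
           header_comments)
  write_tsv(g, path, hdr)
}

#' Write the element result table
#'
#' @param elements an \code{\link{element_stats}} data frame.
#' @param path output path.
#' @param header_comments extra comment lines.
#' @export
write_element_results <- function(elements, path,
                                  header_comments = character()) {
  if (nrow(elements) == 0) {
    warning("writing header-only element table (no elements)")
    writeLines(c(paste0("# ", header_comments),
                 paste(c("element_id", "experiment_id"), collapse = "\t")),
               path)
    return(invisible(path))
  }
  id_cols <- intersect(c("element_id", "chrom", "start", "end"),
                       names(elements))
  el <- elements[do.call(order, c(list(elements$experiment_id),
                                  elements[id_cols])), ]
  write_tsv(el, path, header_comments)
}

#' Export called elements as BED6
#'
#' Positions are converted from 1-based inclusive guide coordinates to
#' 0-based half-open BED intervals; the score is \code{|significance_z|}
#' clamped to \code{[0, 1000]}; strand is \code{"."}.
#'
#' @param elements an \code{\link{element_stats}} data frame with
#'   \code{chrom}/\code{start}/\code{end} (window mode).
#' @param path output path.
#' @param fdr_threshold only elements below this FDR (either tail) are
#'   written (default 0.01); use \code{Inf} for all.
#' @export
write_elements_bed <- function(elements, path, fdr_threshold = 0.01) {
  if (!all(c("chrom", "start", "end") %in% names(elements)))
    stop("BED export needs chrom/start/end columns (window-mode elements)")
  el <- elements[elements$fdr_either < fdr_threshold, ]
  bed <- data.frame(chrom = el$chrom,
                    start = el$start - 1L,  # to 0-based half-open
                    end = el$end,
                    name = sprintf("%s:%d-%d_%s", el$chrom, el$start,
                                   el$end, el$experiment_id),
                    score = pmin(1000, round(abs(el$significance_z), 1)),
                    strand = ".")
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# shared TSV writer: '#' comments, no quoting, tab-separated
write_tsv <- function(df, path, header_comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
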