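# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

# a count table whose sorted-bin counts are exactly proportional to the bin
# fractions (the null configuration: every guide should fit mu ~ 0)
null_counts <- function(bins, n_guides = 4, reads_per_guide = 1e4,
                        experiment_id = bins$experiment_id[1]) {
  cmat <- matrix(rep(reads_per_guide * bins$fraction, each = n_guides),
                 nrow = n_guides, dimnames = list(NULL, bins$bin_id))
  df <- data.frame(guide_id = sprintf("g%02d", seq_len(n_guides)),
                   is_negative_control = c(TRUE, TRUE,
                                           rep(FALSE, n_guides - 2)),
                   experiment_id = experiment_id,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(cmat), unsorted = reads_per_guide)
}

# small guide-result table for element-level tests
guide_results <- function(z, element_label = NULL, chrom = NULL, pos = NULL,
                          is_negative_control = FALSE,
                          experiment_id = "e1") {
  n <- length(z)
  data.frame(guide_id = sprintf("g%03d", seq_len(n)),
             experiment_id = experiment_id,
             is_negative_control = rep_len(is_negative_control, n),
             element_label = if (is.null(element_label)) NA_character_
                             else rep_len(element_label, n),
             chrom = if (is.null(chrom)) NA_character_ else rep_len(chrom, n),
             pos = if (is.null(pos)) NA_integer_ else pos,
             mu_hat = z, z_score = z, ll_ratio = abs(z),
             unquantifiable = FALSE, stringsAsFactors = FALSE)
}

# independent textbook Benjamini-Hochberg step-up with monotonicity
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# brute-force window enumeration: O(n^2) double loop over guide anchors,
# deduplicated by guide-ID set
brute_force_windows <- function(g, window_bp, min_guides) {
  g <- g[!g$is_negative_control & !is.na(g$pos), ]
  sets <- character(0)
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    for (a in gc$pos) {
      ids <- gc$guide_id[gc$pos >= a & gc$pos <= a + window_bp]
      if (length(ids) < min_guides) next
      sets <- c(sets, paste(sort(ids), collapse = "|"))
    }
  }
  sort(unique(sets))
}
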