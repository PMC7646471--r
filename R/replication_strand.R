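#' Lagging-strand-template indicator for a cytosine mutation
#'
#' APOBEC deaminates cytosine in single-stranded DNA, which is most exposed
#' on the lagging-strand template.  Positive RFD marks regions where the
#' Watson strand is replicated mostly as the lagging-strand template,
#' negative RFD the Crick strand.  The mutated cytosine sits on Watson when
#' `ref` is C and on Crick when `ref` is G; the indicator is 1 when that
#' strand is the lagging-strand template, -1 otherwise, and missing when
#' the position is uncovered, the RFD is exactly 0 (no preference
#' information), or the mutation is not at a C:G pair.
#'
#' @param ref plus-strand reference base.
#' @param chrom,pos 1-based position.
#' @param track an `rfd_track`.
#' @return 1, -1 or `NA`.
#' @export
lagging_indicator <- function(ref, chrom, pos, track) {
  if (!ref %in% c("C", "G")) return(NA_real_)
  rfd <- rfd_at(track, chrom, pos)
  if (is.na(rfd) || rfd == 0) return(NA_real_)
  watson_c <- ref == "C"
  if ((watson_c && rfd > 0) || (!watson_c && rfd < 0)) 1 else -1
}

#' Probability of lagging-strand-template localisation across cell lines
#'
#' @param ref,chrom,pos as in [lagging_indicator()].
#' @param tracks list of `rfd_track` objects (one per cell line).
#' @return list with per-cell-line `indicators` and `lagging_probability`
#'   (mean of (indicator + 1)/2 over non-missing tracks; `NA` when all
#'   indicators are missing).
#' @export
lagging_probability <- function(ref, chrom, pos, tracks) {
  ind <- vapply(tracks, function(tr)
    lagging_indicator(ref, chrom, pos, tr), numeric(1))
  names(ind) <- vapply(tracks, `[[`, character(1), "cell_line")
  ok <- !is.na(ind)
  p <- if (any(ok)) mean((ind[ok] + 1) / 2) else NA_real_
  list(indicators = ind, lagging_probability = p, n_covered = sum(ok))
}

#' Replicative strand-asymmetry tests on lagging probabilities
#'
#' Runs (i) a two-sided Wilcoxon rank-sum test comparing the lagging
#' probabilities of two hotspot groups (e.g. APOBEC-associated vs other),
#' and (ii) one-sided Wilcoxon signed-rank tests ("greater") of each
#' group's probabilities against the no-preference value 0.5.
#'
#' @param probs_a,probs_b numeric lagging-probability vectors.
#' @return list with `rank_sum` (htest) and `signed_rank_a`, `signed_rank_b`.
#' @export
compare_lagging <- function(probs_a, probs_b) {
  probs_a <- probs_a[!is.na(probs_a)]
  probs_b <- probs_b[!is.na(probs_b)]
  if (length(probs_a) == 0 || length(probs_b) == 0) {
    stop("both groups need at least one non-missing probability")
  }
  vs_half <- function(x) {
    if (all(x == 0.5)) {
      return(list(p.value = 1, statistic = c(V = 0)))
    }
    stats::wilcox.test(x, mu = 0.5, alternative = "greater", exact = FALSE)
  }
  list(
    rank_sum = stats::wilcox.test(probs_a, probs_b, exact = FALSE),
    signed_rank_a = vs_half(probs_a),
    signed_rank_b = vs_half(probs_b)
  )
}
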