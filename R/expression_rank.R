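#' Housekeeping-normalised expression percentile ranks
#'
#' Each gene's expression is divided, sample by sample, by the expression
#' of a housekeeping anchor gene (GAPDH by default), the per-gene median of
#' these relative values is taken across samples, and genes are ranked on
#' a percentile scale in (0, 1\] (average ranks for ties).  The anchor's
#' relative expression is exactly 1 in every sample by construction, which
#' makes the table invariant to any per-sample positive rescaling.
#'
#' @param expr genes x samples non-negative matrix.
#' @param anchor housekeeping gene symbol.
#' @param labels optional named character vector of functional labels
#'   (`"oncogene"`, `"TSG"`); unlisted genes are `"unknown"`.
#' @return data frame `gene`, `median_relative`, `percentile`, `label`.
#' @export
gapdh_percentile_rank <- function(expr, anchor = "GAPDH", labels = NULL) {
  if (!anchor %in% rownames(expr)) stop("anchor gene absent from matrix")
  a <- expr[anchor, ]
  if (any(a <= 0)) stop("anchor gene must be positive in every sample")
  if (any(is.na(expr))) stop("expression matrix contains missing values")
  rel <- sweep(expr, 2, a, "/")
  med <- apply(rel, 1, stats::median)
  pct <- rank(med, ties.method = "average") / length(med)
  lab <- rep("unknown", length(med))
  names(lab) <- rownames(expr)
  if (!is.null(labels)) {
    hit <- intersect(names(labels), rownames(expr))
    lab[hit] <- labels[hit]
  }
  data.frame(gene = rownames(expr), median_relative = unname(med),
             percentile = unname(pct), label = unname(lab),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison between two groups of values
#'
#' The workhorse comparison used throughout: expression of a gene between
#' mutated and wild-type samples, percentile ranks of cancer genes against
#' genes of unknown function or against the all-gene background, APOBEC
#' signature fractions between molecular subtypes, and so on.
#'
#' @param values_a,values_b numeric vectors (must not overlap in origin
#'   unless `allow_overlap`; identity is checked on names when present).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param allow_overlap permit shared named elements between groups
#'   (needed e.g. when one group is the full background).
#' @return list with `statistic` (W) and `p.value`.
#' @export
expression_group_test <- function(values_a, values_b,
                                  alternative = "two.sided",
                                  allow_overlap = FALSE) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (!allow_overlap && !is.null(names(values_a)) &&
      !is.null(names(values_b)) &&
      length(intersect(names(values_a), names(values_b))) > 0) {
    stop("groups overlap; set allow_overlap = TRUE if intended")
  }
  ht <- stats::wilcox.test(values_a, values_b, alternative = alternative,
                           exact = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
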