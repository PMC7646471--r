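#' Select transcription-factor regulon candidates by anchored co-expression
#'
#' Drops the lowest-variance 20\% of genes, computes the Spearman
#' correlation between the transcription factor and its prototypical
#' target (the anchor pair, e.g. AHR and CYP1A1), and keeps as candidates
#' every other gene whose Spearman correlation with BOTH anchors is at
#' least the anchors' mutual correlation.  The anchors themselves are
#' excluded from the candidate set.
#'
#' @param expr genes x samples expression matrix.
#' @param tf transcription factor gene symbol.
#' @param prototype prototypical target gene symbol.
#' @param var_drop fraction of lowest-variance genes removed first.
#' @return a `regulon_model` list: `anchors`, `rho_threshold`,
#'   `rho_threshold_p`, `candidates`, `validated_set` (NULL until
#'   [finalise_regulon()]).
#' @export
select_regulon_candidates <- function(expr, tf = "AHR",
                                      prototype = "CYP1A1",
                                      var_drop = 0.2) {
  if (!tf %in% rownames(expr) || !prototype %in% rownames(expr)) {
    stop("anchor gene(s) absent from expression matrix")
  }
  v <- apply(expr, 1, stats::var)
  cut <- stats::quantile(v, var_drop)
  keep <- v > cut
  if (!keep[tf] || !keep[prototype]) {
    stop("anchor gene(s) removed by the variance filter")
  }
  sub <- expr[keep, , drop = FALSE]
  ct <- stats::cor.test(sub[tf, ], sub[prototype, ], method = "spearman",
                        exact = FALSE)
  rho0 <- unname(ct$estimate)
  others <- setdiff(rownames(sub), c(tf, prototype))
  rho_tf <- apply(sub[others, , drop = FALSE], 1, function(g)
    stats::cor(g, sub[tf, ], method = "spearman"))
  rho_pt <- apply(sub[others, , drop = FALSE], 1, function(g)
    stats::cor(g, sub[prototype, ], method = "spearman"))
  cand <- others[!is.na(rho_tf) & !is.na(rho_pt) &
                   rho_tf >= rho0 & rho_pt >= rho0]
  structure(list(anchors = c(tf = tf, prototype = prototype),
                 rho_threshold = rho0,
                 rho_threshold_p = ct$p.value,
                 candidates = cand,
                 validated_set = NULL,
                 de_table = NULL),
            class = "regulon_model")
}

#' @exportS3Method base::print
print.regulon_model <- function(x, ...) {
  cat("<regulon_model> anchors ", x$anchors[1], "/", x$anchors[2],
      ", rho threshold ", signif(x$rho_threshold, 3), ", ",
      length(x$candidates), " candidates",
      if (!is.null(x$validated_set))
        paste0(", ", length(x$validated_set), " validated"),
      "\n", sep = "")
  invisible(x)
}

#' Negative-binomial differential expression for knockdown vs control
#'
#' Wald tests with median-of-ratios size factors, computed with DESeq2.
#' Fold changes are unshrunken; p values are Benjamini-Hochberg adjusted.
#' All-zero genes are excluded.
#'
#' @param counts genes x samples integer count matrix.
#' @param group factor/character of length ncol(counts) with two levels;
#'   the SECOND level (e.g. "knockdown") is contrasted against the first.
#' @return data frame `gene`, `log2fc`, `p`, `fdr`.
#' @export
nb_differential_expression <- function(counts, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (min(table(group)) < 2) stop("need >= 2 replicates per group")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  mode(counts) <- "integer"
  coldata <- S4Vectors::DataFrame(condition = group)
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = counts,
                                        colData = coldata,
                                        design = ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds,
                         contrast = c("condition", levels(group)[2],
                                      levels(group)[1]))
  data.frame(gene = rownames(res),
             log2fc = res$log2FoldChange,
             p = res$pvalue,
             fdr = res$padj,
             stringsAsFactors = FALSE)
}

#' Median-of-ratios size factors
#'
#' @param counts genes x samples count matrix.
#' @return numeric size factor per sample.
#' @export
size_factors <- function(counts) {
  DESeq2::estimateSizeFactorsForMatrix(counts)
}

de_ranking_score <- function(de) {
  # descending (-log2FC) * (-log10 FDR): genes that are both strongly and
  # significantly DOWNregulated rank on top; significant upregulated genes
  # sink to the bottom
  fdr <- pmax(de$fdr, 1e-300)
  fdr[is.na(fdr)] <- 1
  lfc <- de$log2fc
  lfc[is.na(lfc)] <- 0
  (-lfc) * (-log10(fdr))
}

#' Randomisation test for candidate enrichment at the top of a DE ranking
#'
#' Genes are ranked by descending (-log2FC) x (-log10 FDR), putting the
#' most significantly downregulated genes on top.  The observed rank sum
#' of the candidate set is compared with `n_rand` seeded random gene sets
#' of the same size; p = (1 + #\{rank sum <= observed\}) / (n_rand + 1),
#' an add-one estimator that can never return 0.
#'
#' @param de DE table from [nb_differential_expression()].
#' @param candidates candidate gene symbols (absent genes dropped with a
#'   warning).
#' @param n_rand number of random sets.
#' @param seed RNG seed.
#' @return list `p`, `observed_rank_sum`, `n_used`.
#' @export
ranksum_randomisation_test <- function(de, candidates, n_rand = 1e6,
                                       seed = 1) {
  score <- de_ranking_score(de)
  rk <- rank(-score, ties.method = "average")
  names(rk) <- de$gene
  present <- intersect(candidates, de$gene)
  if (length(present) < length(candidates)) {
    warning(length(candidates) - length(present),
            " candidate(s) absent from the DE ranking; dropped")
  }
  if (length(present) == 0) stop("no candidates in ranking")
  obs <- sum(rk[present])
  k <- length(present)
  N <- length(rk)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_rand)) {
    if (sum(rk[sample.int(N, k)]) <= obs) hits <- hits + 1L
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(p = (1 + hits) / (n_rand + 1), observed_rank_sum = obs,
       n_used = k)
}

#' Validate regulon candidates against knockdown response
#'
#' The validated regulon is the intersection of the co-expression
#' candidates with the genes significantly downregulated by knockdown of
#' the factor (log2FC < 0 and FDR < `fdr_cut`).
#'
#' @param model a `regulon_model`.
#' @param de DE table from [nb_differential_expression()].
#' @param fdr_cut FDR threshold.
#' @return the model with `validated_set` and `de_table` filled.
#' @export
finalise_regulon <- function(model, de, fdr_cut = 0.05) {
  sig_down <- de$gene[!is.na(de$fdr) & de$fdr < fdr_cut & de$log2fc < 0]
  vs <- intersect(model$candidates, sig_down)
  if (length(vs) == 0) warning("empty validated regulon")
  model$validated_set <- vs
  model$de_table <- de[de$gene %in% model$candidates, , drop = FALSE]
  model
}

#' Single-sample regulon activity scores
#'
#' Rank-based single-sample enrichment: within each sample, genes are
#' ranked by expression and the activity is a weighted Kolmogorov-Smirnov
#' running-sum statistic (in-set steps weighted by rank), so the score
#' depends only on within-sample ranks and is invariant to any strictly
#' monotone transform of a sample's expression vector.  A sample whose
#' regulon genes occupy the top |set| ranks attains the maximal score.
#'
#' @param expr genes x samples expression matrix.
#' @param gene_set regulon gene symbols (>= `min_size` must be present).
#' @param min_size minimum usable set size.
#' @return named numeric score per sample.
#' @export
regulon_activity_score <- function(expr, gene_set, min_size = 5) {
  missing <- setdiff(gene_set, rownames(expr))
  present <- setdiff(gene_set, missing)
  if (length(present) < min_size) {
    stop("regulon genes absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  in_set <- rownames(expr) %in% present
  apply(expr, 2, function(x) {
    r <- rank(x, ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    hit <- in_set[ord]
    w <- r[ord] * hit
    p_hit <- cumsum(w) / sum(w)
    p_miss <- cumsum(!hit) / sum(!hit)
    dev <- p_hit - p_miss
    dev[which.max(abs(dev))]
  })
}

#' Group tests on regulon activity scores
#'
#' Two groups: Wilcoxon rank-sum.  More: Kruskal-Wallis across groups plus
#' pairwise Dunn z tests (rank-based, with tie correction) adjusted by
#' Benjamini-Hochberg.
#'
#' @param scores numeric activity scores.
#' @param groups factor/character of the same length.
#' @return list with `kruskal_p` (or `wilcox_p`) and, for > 2 groups,
#'   a `pairwise` data frame (`group_a`, `group_b`, `z`, `p`, `fdr`).
#' @export
activity_group_tests <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (nlevels(groups) == 2) {
    sp <- split(scores, groups)
    return(list(wilcox_p = stats::wilcox.test(sp[[1]], sp[[2]],
                                              exact = FALSE)$p.value))
  }
  kw <- stats::kruskal.test(scores, groups)
  r <- rank(scores)
  n <- length(scores)
  ties <- table(scores)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- sum(groups == a); nb <- sum(groups == b)
    mra <- mean(r[groups == a]); mrb <- mean(r[groups == b])
    sigma <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
    z[j] <- (mra - mrb) / sigma
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  list(kruskal_p = kw$p.value,
       pairwise = data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                             z = z, p = p,
                             fdr = stats::p.adjust(p, method = "BH"),
                             stringsAsFactors = FALSE))
}

#' Quantile-matched comparison of dependency scores between groups
#'
#' For each cell line in group A its empirical quantile within A is
#' computed, group B's empirical quantile function is read at the same
#' quantile by local linear interpolation, and a Wilcoxon signed-rank test
#' is run on the paired differences (A minus matched B).  With dependency
#' scores, negative deltas mean group A is more dependent.
#'
#' @param dep_a,dep_b numeric dependency scores for the two groups
#'   (`dep_b` needs >= 2 values for interpolation).
#' @param alternative passed to the signed-rank test (`"less"` tests
#'   whether A is more dependent).
#' @return list `deltas`, `p`, `matched_b`.
#' @export
dependency_quantile_comparison <- function(dep_a, dep_b,
                                           alternative = "two.sided") {
  if (length(dep_b) < 2) stop("group B needs >= 2 values")
  if (length(dep_a) == 0) stop("group A is empty")
  qa <- (rank(dep_a, ties.method = "average") - 0.5) / length(dep_a)
  matched <- unname(stats::quantile(dep_b, probs = qa, type = 7))
  deltas <- dep_a - matched
  p <- if (all(deltas == 0)) 1 else
    stats::wilcox.test(dep_a, matched, paired = TRUE,
                       alternative = alternative, exact = FALSE)$p.value
  list(deltas = deltas, p = p, matched_b = matched)
}
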