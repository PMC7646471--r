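#' Assemble feature points for driver/passenger classification
#'
#' @param key mutation identifiers.
#' @param loop_score normalised loop stability scores in \[0, 1\].
#' @param expr_rank expression percentile ranks in \[0, 1\].
#' @param seed_label `"known_driver"`, `"known_passenger"` or `"unknown"`.
#' @return data frame of feature points.
#' @export
feature_points <- function(key, loop_score, expr_rank,
                           seed_label = "unknown") {
  stopifnot(all(is.finite(loop_score)), all(is.finite(expr_rank)))
  seed_label <- rep_len(seed_label, length(key))
  stopifnot(all(seed_label %in%
                  c("known_driver", "known_passenger", "unknown")))
  data.frame(key = key, x1 = loop_score, x2 = expr_rank,
             seed_label = seed_label, stringsAsFactors = FALSE)
}

euclid_to <- function(x, refs) {
  sqrt((x[1] - refs[, 1])^2 + (x[2] - refs[, 2])^2)
}

#' Iterative similarity-based driver/passenger classification
#'
#' Points live in the (loop stability, expression rank) unit square, both
#' axes already scaled to \[0, 1\] so Euclidean distance weights them
#' equally.  Each iteration takes, for every unresolved point, its
#' distances to all current driver references and all current passenger
#' references (seeds plus previously assigned points), runs a two-sided
#' Welch t test between the two distance samples, and, when p < `alpha`,
#' assigns the point to the class with the smaller mean distance.  Newly
#' assigned points join the reference sets of the next iteration.  The
#' procedure stops when every point is assigned or an iteration assigns
#' none; leftovers are `undetermined`.  The mean difference of distances
#' (MDoD) is reported as mean distance to passengers minus mean distance
#' to drivers: large positive values are driver-like.  Seed points are
#' never reassigned.
#'
#' @param points data frame from [feature_points()] with >= 2 known
#'   drivers and >= 2 known passengers.
#' @param alpha Welch test significance threshold per iteration.
#' @return `classifier_result` data frame: one row per unknown point with
#'   `predicted_label`, `iteration_assigned`, `mdod`, `t_p`, `fdr` (NA
#'   until [permutation_fdr()] fills it).
#' @export
iterative_similarity_classify <- function(points, alpha = 0.05) {
  drv <- points[points$seed_label == "known_driver", c("x1", "x2")]
  pas <- points[points$seed_label == "known_passenger", c("x1", "x2")]
  if (nrow(drv) < 2 || nrow(pas) < 2) {
    stop("need >= 2 known drivers and >= 2 known passengers")
  }
  unk <- points[points$seed_label == "unknown", , drop = FALSE]
  res <- data.frame(key = unk$key,
                    predicted_label = "undetermined",
                    iteration_assigned = NA_integer_,
                    mdod = NA_real_, t_p = NA_real_, fdr = NA_real_,
                    stringsAsFactors = FALSE)
  drv_ref <- as.matrix(drv)
  pas_ref <- as.matrix(pas)
  unresolved <- seq_len(nrow(unk))
  iter <- 0L
  while (length(unresolved) > 0) {
    iter <- iter + 1L
    assigned <- integer(0)
    new_drv <- NULL
    new_pas <- NULL
    for (i in unresolved) {
      x <- c(unk$x1[i], unk$x2[i])
      dd <- euclid_to(x, drv_ref)
      dp <- euclid_to(x, pas_ref)
      mdod <- mean(dp) - mean(dd)
      p <- tryCatch(stats::t.test(dd, dp, var.equal = FALSE)$p.value,
                    error = function(e) 1)
      if (is.na(p)) p <- 1  # zero-variance degenerate case
      if (p < alpha) {
        lab <- if (mean(dd) < mean(dp)) "driver" else "passenger"
        res$predicted_label[i] <- lab
        res$iteration_assigned[i] <- iter
        res$mdod[i] <- mdod
        res$t_p[i] <- p
        assigned <- c(assigned, i)
        if (lab == "driver") new_drv <- rbind(new_drv, x)
        else new_pas <- rbind(new_pas, x)
      }
    }
    if (length(assigned) == 0) break
    if (!is.null(new_drv)) drv_ref <- rbind(drv_ref, new_drv)
    if (!is.null(new_pas)) pas_ref <- rbind(pas_ref, new_pas)
    unresolved <- setdiff(unresolved, assigned)
  }
  attr(res, "n_iterations") <- iter
  class(res) <- c("classifier_result", class(res))
  res
}

#' Permutation-based FDR for driver/passenger predictions
#'
#' For each predicted point the driver/passenger labels of the seed
#' coordinates are relabelled over the full combinatorial set (all
#' choose(n, k) ways of choosing which seeds are "drivers", 11,440 for the
#' canonical 9 + 7 configuration); each relabelling yields a permuted MDoD
#' against the seed coordinates.  The permutation p is the fraction of
#' relabelings with MDoD at least as extreme in the direction of the
#' prediction (>= observed for predicted drivers, <= for passengers),
#' where the observed MDoD is computed against the true seed labels.
#' Benjamini-Hochberg adjustment across predictions gives the FDR.  When
#' the combinatorial set exceeds `max_exact`, a seeded Monte-Carlo sample
#' of relabelings is used instead.
#'
#' @param result a `classifier_result`.
#' @param points the feature points the classifier ran on (seed rows used).
#' @param max_exact cap on exhaustive enumeration size.
#' @param mc_draws,seed Monte-Carlo fallback size and seed.
#' @return the result with `mdod` recomputed against seeds, `perm_p` and
#'   `fdr` filled for predicted points.
#' @export
permutation_fdr <- function(result, points, max_exact = 2e5,
                            mc_draws = 20000, seed = 1) {
  seeds <- points[points$seed_label != "unknown", , drop = FALSE]
  n <- nrow(seeds)
  k <- sum(seeds$seed_label == "known_driver")
  coords <- as.matrix(seeds[, c("x1", "x2")])
  is_drv <- seeds$seed_label == "known_driver"
  predicted <- which(result$predicted_label %in% c("driver", "passenger"))
  result$perm_p <- NA_real_
  if (length(predicted) == 0) return(result)
  if (choose(n, k) <= max_exact) {
    combos <- utils::combn(n, k)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    combos <- replicate(mc_draws, sort(sample.int(n, k)))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  n_perm <- ncol(combos)
  pts <- points[match(result$key, points$key), , drop = FALSE]
  for (i in predicted) {
    x <- c(pts$x1[i], pts$x2[i])
    d <- euclid_to(x, coords)
    obs <- mean(d[!is_drv]) - mean(d[is_drv])
    tot_d <- colSums(matrix(d[combos], nrow = k))
    perm_mdod <- (sum(d) - tot_d) / (n - k) - tot_d / k
    result$mdod[i] <- obs
    result$perm_p[i] <- if (result$predicted_label[i] == "driver") {
      mean(perm_mdod >= obs - 1e-12)
    } else {
      mean(perm_mdod <= obs + 1e-12)
    }
  }
  result$fdr[predicted] <- stats::p.adjust(result$perm_p[predicted],
                                           method = "BH")
  attr(result, "n_permutations") <- n_perm
  result
}

ridge_logistic <- function(x, y, lambda = 1) {
  # penalised fallback under perfect separation: minimise the ridge
  # regularised negative log-likelihood directly
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(eta))) - sum(y * eta) + lambda * b[2]^2 / 2
  }
  stats::optim(c(0, 0), nll, method = "BFGS")$par
}

#' Two-step generalised-linear-regression driverness
#'
#' The transparent alternative to the iterative classifier: a mutation's
#' driverness is the product of two independently fitted logistic
#' probabilities, P(functional gene | expression rank), trained on known
#' oncogenes/TSGs versus genes of unknown function, and
#' P(driver | loop score), trained on the known driver and passenger
#' seeds.  Perfect separation in either fit triggers a ridge-penalised
#' fallback (flagged in the `separation` attribute).
#'
#' @param rank_train data frame `rank`, `functional` (logical).
#' @param loop_train data frame `loop_score`, `driver` (logical).
#' @param newdata data frame with `rank` and `loop_score` columns.
#' @return numeric driverness in \[0, 1\] per row of `newdata`, with
#'   attribute `separation` (logical flags for the two models).
#' @export
two_step_glr <- function(rank_train, loop_train, newdata) {
  fit_one <- function(x, y) {
    fit <- suppressWarnings(
      stats::glm(y ~ x, family = stats::binomial()))
    sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) &&
      any(fit$fitted.values < 1e-8)
    if (sep) {
      b <- ridge_logistic(x, y)
    } else {
      b <- stats::coef(fit)
    }
    list(coef = b, separation = sep)
  }
  m1 <- fit_one(rank_train$rank, as.numeric(rank_train$functional))
  m2 <- fit_one(loop_train$loop_score, as.numeric(loop_train$driver))
  p1 <- stats::plogis(m1$coef[1] + m1$coef[2] * newdata$rank)
  p2 <- stats::plogis(m2$coef[1] + m2$coef[2] * newdata$loop_score)
  out <- unname(p1 * p2)
  attr(out, "separation") <- c(rank_model = m1$separation,
                               loop_model = m2$separation)
  attr(out, "coef") <- list(rank_model = m1$coef, loop_model = m2$coef)
  out
}

#' Clonality enrichment of hotspot mutations
#'
#' Within mutation events in APOBEC-target genes, tests whether hotspot
#' mutations are more often clonal than other mutations: Fisher's exact
#' test on the 2x2 (hotspot vs other) x (clonal vs subclonal) table, and a
#' logistic mixed model `clonal ~ hotspot + log10(recurrence)` with a
#' per-gene random intercept to adjust for mutation frequency.
#'
#' @param events data frame with columns `gene`, `is_hotspot` (logical),
#'   `clonality` (`"clonal"`/`"subclonal"`), `count` (recurrence of the
#'   mutation the event belongs to).
#' @return list with `table`, `fisher_or`, `fisher_p`, `glmm_or`,
#'   `glmm_ci`, `glmm_p` (GLMM entries NA when a 2x2 margin is degenerate).
#' @export
clonality_tests <- function(events) {
  ev <- events[events$clonality %in% c("clonal", "subclonal"), , drop = FALSE]
  if (nrow(ev) == 0) stop("no clonal/subclonal events in scope")
  tab <- table(factor(ifelse(ev$is_hotspot, "hotspot", "other"),
                      levels = c("hotspot", "other")),
               factor(ev$clonality, levels = c("clonal", "subclonal")))
  fe <- stats::fisher.test(tab)
  # sample odds ratio (not the conditional MLE fisher.test reports)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  out <- list(table = tab, fisher_or = or,
              fisher_p = fe$p.value,
              glmm_or = NA_real_, glmm_ci = c(NA_real_, NA_real_),
              glmm_p = NA_real_)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 margin; GLMM skipped")
    return(out)
  }
  ev$clonal <- as.numeric(ev$clonality == "clonal")
  ev$log_count <- log10(ev$count)
  fit <- tryCatch(
    lme4::glmer(clonal ~ is_hotspot + log_count + (1 | gene),
                data = ev, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    sm <- summary(fit)$coefficients
    b <- sm["is_hotspotTRUE", ]
    out$glmm_or <- exp(b["Estimate"])
    out$glmm_ci <- exp(b["Estimate"] + c(-1.96, 1.96) * b["Std. Error"])
    out$glmm_p <- b["Pr(>|z|)"]
  } else {
    warning("GLMM fit failed; Fisher results only")
  }
  out
}

#' Mutability-adjusted recurrence enrichment (selection surrogate)
#'
#' A simplified surrogate for selection intensity: each site's expected
#' mutability mass under the cohort's fitted mutational processes is
#' sum over samples and signatures of E\[s,k\] * S\[k, channel(site)\],
#' and the enrichment is observed carrier count over expected mass.
#' Sites with zero expected mass are excluded with a flag.
#'
#' @param sites data frame with `key`, `count` (observed carriers) and
#'   `channel` (96-channel label of site -> alt).
#' @param exposures samples x signatures exposure matrix.
#' @param ref signature matrix.
#' @return data frame `key`, `observed`, `expected`, `enrichment` plus
#'   attribute `excluded` (keys with zero expected mass).
#' @export
mutability_adjusted_recurrence <- function(sites, exposures, ref) {
  S <- unclass(ref)
  mix <- exposures %*% S[colnames(exposures), , drop = FALSE]  # samples x 96
  mass <- colSums(mix)
  expected <- unname(mass[sites$channel])
  keep <- expected > 0
  if (any(!keep)) warning(sum(!keep), " site(s) with zero expected mass excluded")
  out <- data.frame(key = sites$key[keep], observed = sites$count[keep],
                    expected = expected[keep],
                    enrichment = sites$count[keep] / expected[keep],
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- sites$key[!keep]
  out
}

#' Exact weighted one-dimensional two-cluster split
#'
#' Optimal k = 2 clustering of scalar values minimising the weighted
#' within-cluster sum of squares.  In one dimension the optimal clusters
#' are contiguous in sorted order, so the exact optimum is found by
#' scanning every split point of the sorted values.
#'
#' @param values numeric vector (length >= 2).
#' @param weights positive weights (default 1).
#' @return factor with levels `low`, `high` in the input order, with
#'   attribute `wcss` (the minimised criterion) and `boundary` (largest
#'   value in the low cluster).
#' @export
univariate_two_cluster <- function(values, weights = NULL) {
  n <- length(values)
  if (n < 2) stop("need at least two values")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0), length(weights) == n)
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord]
  wcss_part <- function(v, w) {
    mu <- sum(w * v) / sum(w)
    sum(w * (v - mu)^2)
  }
  best <- Inf
  best_split <- 1L
  for (split in seq_len(n - 1)) {
    tot <- wcss_part(v[1:split], w[1:split]) +
      wcss_part(v[(split + 1):n], w[(split + 1):n])
    if (tot < best - 1e-12) {
      best <- tot
      best_split <- split
    }
  }
  lab <- rep("high", n)
  lab[ord[seq_len(best_split)]] <- "low"
  out <- factor(lab, levels = c("low", "high"))
  attr(out, "wcss") <- best
  attr(out, "boundary") <- v[best_split]
  out
}
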