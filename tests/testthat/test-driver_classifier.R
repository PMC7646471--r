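mk_seeds <- function(seed = 1) {
  set.seed(seed)
  drv <- feature_points(sprintf("D%02d", 1:9),
                        pmin(1, pmax(0, rnorm(9, 0.9, 0.06))),
                        pmin(1, pmax(0, rnorm(9, 0.85, 0.08))),
                        "known_driver")
  pas <- feature_points(sprintf("P%02d", 1:7),
                        pmin(1, pmax(0, rnorm(7, 0.12, 0.1))),
                        pmin(1, pmax(0, rnorm(7, 0.45, 0.25))),
                        "known_passenger")
  rbind(drv, pas)
}

test_that("coincident points resolve in iteration 1; symmetry stalls", {
  seeds <- mk_seeds(2)
  drv_centroid <- colMeans(seeds[seeds$seed_label == "known_driver",
                                 c("x1", "x2")])
  pts <- rbind(seeds,
               feature_points("U1", drv_centroid[1], drv_centroid[2]))
  res <- iterative_similarity_classify(pts)
  expect_equal(res$predicted_label[res$key == "U1"], "driver")
  expect_equal(res$iteration_assigned[res$key == "U1"], 1L)
  expect_gt(res$mdod[res$key == "U1"], 0)

  # symmetric configuration: the equidistant point stays undetermined
  sym <- rbind(
    feature_points(c("d1", "d2"), c(0.2, 0.2), c(0.2, 0.8), "known_driver"),
    feature_points(c("p1", "p2"), c(0.8, 0.8), c(0.2, 0.8),
                   "known_passenger"),
    feature_points("mid", 0.5, 0.5))
  res2 <- iterative_similarity_classify(sym)
  expect_equal(res2$predicted_label[res2$key == "mid"], "undetermined")
  expect_true(is.na(res2$fdr[res2$key == "mid"]))
})

test_that("classifier needs two members per reference class", {
  pts <- rbind(feature_points("d", 0.9, 0.9, "known_driver"),
               feature_points(c("p1", "p2"), c(0.1, 0.2), c(0.1, 0.2),
                              "known_passenger"),
               feature_points("u", 0.5, 0.5))
  expect_error(iterative_similarity_classify(pts), ">= 2 known")
})

test_that("simulated unknowns recover their generating class", {
  seeds <- mk_seeds(5)
  set.seed(6)
  unk_d <- feature_points(sprintf("UD%02d", 1:15),
                          pmin(1, pmax(0, rnorm(15, 0.9, 0.06))),
                          pmin(1, pmax(0, rnorm(15, 0.85, 0.08))))
  unk_p <- feature_points(sprintf("UP%02d", 1:13),
                          pmin(1, pmax(0, rnorm(13, 0.12, 0.1))),
                          pmin(1, pmax(0, rnorm(13, 0.45, 0.25))))
  res <- iterative_similarity_classify(rbind(seeds, unk_d, unk_p))
  resolved <- res[res$predicted_label != "undetermined", ]
  truth <- ifelse(grepl("^UD", resolved$key), "driver", "passenger")
  expect_gte(mean(resolved$predicted_label == truth), 0.9)
  expect_gte(nrow(resolved), 20)
})

test_that("classification is invariant to input order and deterministic", {
  seeds <- mk_seeds(8)
  set.seed(9)
  unk <- feature_points(sprintf("U%02d", 1:10), runif(10), runif(10))
  pts <- rbind(seeds, unk)
  res1 <- iterative_similarity_classify(pts)
  perm <- pts[sample(nrow(pts)), ]
  res2 <- iterative_similarity_classify(perm)
  m <- match(res1$key, res2$key)
  expect_equal(res1$predicted_label, res2$predicted_label[m])
  expect_equal(res1$mdod, res2$mdod[m])
})

test_that("permutation p matches an independent exhaustive enumeration", {
  # 5 drivers + 4 passengers: choose(9, 5) = 126 relabelings
  seeds <- rbind(
    feature_points(sprintf("d%d", 1:5), c(0.9, 0.85, 0.95, 0.88, 0.92),
                   c(0.8, 0.9, 0.85, 0.95, 0.9), "known_driver"),
    feature_points(sprintf("p%d", 1:4), c(0.1, 0.2, 0.15, 0.05),
                   c(0.3, 0.5, 0.7, 0.4), "known_passenger"))
  pts <- rbind(seeds, feature_points("u", 0.91, 0.87))
  res <- iterative_similarity_classify(pts)
  expect_equal(res$predicted_label, "driver")
  res <- permutation_fdr(res, pts)

  # oracle: every 0/1 labelling of the 9 seeds with five 1s, enumerated
  # through a full binary grid rather than combinations
  d <- sqrt((0.91 - seeds$x1)^2 + (0.87 - seeds$x2)^2)
  grid <- as.matrix(expand.grid(rep(list(0:1), 9)))
  grid <- grid[rowSums(grid) == 5, , drop = FALSE]
  expect_equal(nrow(grid), choose(9, 5))
  perm_mdod <- apply(grid, 1, function(g)
    mean(d[g == 0]) - mean(d[g == 1]))
  obs <- mean(d[seeds$seed_label == "known_passenger"]) -
    mean(d[seeds$seed_label == "known_driver"])
  p_oracle <- mean(perm_mdod >= obs - 1e-12)
  expect_equal(res$perm_p, p_oracle, tolerance = 1e-12)
  # well-separated seeds put the true labelling at the extreme
  expect_lte(res$perm_p, 5 / choose(9, 5))
})

test_that("a prediction at the driver centroid attains a minimal p", {
  seeds <- mk_seeds(3)
  centroid <- colMeans(seeds[seeds$seed_label == "known_driver",
                             c("x1", "x2")])
  pts <- rbind(seeds, feature_points("u", centroid[1], centroid[2]))
  res <- permutation_fdr(iterative_similarity_classify(pts), pts)
  expect_lte(res$perm_p, 10 / choose(16, 9))
  expect_equal(attr(res, "n_permutations"), choose(16, 9))
})

test_that("permutation p is uniform for exchangeable seeds", {
  set.seed(31)
  ps <- numeric(200)
  for (r in 1:200) {
    xy <- matrix(runif(32), 16, 2)
    seeds <- feature_points(sprintf("s%02d", 1:16), xy[, 1], xy[, 2],
                            rep(c("known_driver", "known_passenger"),
                                c(9, 7)))
    pts <- rbind(seeds, feature_points("u", runif(1), runif(1)))
    res <- data.frame(key = "u", predicted_label = "driver",
                      iteration_assigned = 1L, mdod = NA_real_,
                      t_p = NA_real_, fdr = NA_real_,
                      stringsAsFactors = FALSE)
    ps[r] <- permutation_fdr(res, pts)$perm_p
  }
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("BH ordering of FDR follows the p ordering", {
  seeds <- mk_seeds(13)
  set.seed(14)
  unk <- feature_points(sprintf("U%02d", 1:12),
                        runif(12), runif(12))
  pts <- rbind(seeds, unk)
  res <- permutation_fdr(iterative_similarity_classify(pts), pts)
  got <- res[res$predicted_label != "undetermined", ]
  if (nrow(got) >= 2) {
    o <- order(got$perm_p)
    expect_true(all(diff(got$fdr[o]) >= -1e-12))
  }
  # seed rows are never part of the result
  expect_false(any(res$key %in% seeds$key[seeds$seed_label != "unknown"]))
})

test_that("two-step GLR driverness is bounded and monotone", {
  set.seed(17)
  rank_train <- data.frame(rank = c(runif(30, 0.6, 1), runif(40, 0, 1)),
                           functional = rep(c(TRUE, FALSE), c(30, 40)))
  loop_train <- data.frame(loop_score = c(runif(9, 0.7, 1),
                                          runif(7, 0, 0.4)),
                           driver = rep(c(TRUE, FALSE), c(9, 7)))
  newd <- data.frame(rank = runif(50), loop_score = runif(50))
  p <- two_step_glr(rank_train, loop_train, newd)
  expect_true(all(p >= 0 & p <= 1))
  # monotone non-decreasing in loop score at fixed rank
  grid <- data.frame(rank = 0.8, loop_score = seq(0, 1, 0.05))
  pg <- two_step_glr(rank_train, loop_train, grid)
  expect_true(all(diff(pg) >= -1e-12))
  # iterative-method drivers take the top GLR stratum
  seeds <- mk_seeds(18)
  unk <- feature_points(sprintf("U%02d", 1:20),
                        c(runif(10, 0.75, 1), runif(10, 0, 0.3)),
                        c(runif(10, 0.7, 1), runif(10, 0, 1)))
  res <- iterative_similarity_classify(rbind(seeds, unk))
  newd2 <- data.frame(rank = unk$x2, loop_score = unk$x1)
  glr <- two_step_glr(loop_train = data.frame(
    loop_score = seeds$x1,
    driver = seeds$seed_label == "known_driver"),
    rank_train = rank_train, newdata = newd2)
  lab <- res$predicted_label[match(unk$key, res$key)]
  if (any(lab == "driver") && any(lab == "passenger")) {
    expect_gt(median(glr[lab == "driver"]),
              median(glr[lab == "passenger"]))
  }
})

test_that("Fisher clonality test matches the hypergeometric oracle", {
  ev <- data.frame(
    gene = rep("G", 120),
    is_hotspot = rep(c(TRUE, FALSE), c(40, 80)),
    clonality = c(rep(c("clonal", "subclonal"), c(30, 10)),
                  rep(c("clonal", "subclonal"), c(40, 40))),
    count = 5, stringsAsFactors = FALSE)
  res <- suppressWarnings(clonality_tests(ev))
  expect_equal(res$fisher_or, (30 * 40) / (10 * 40))  # sample OR 3.0
  expect_equal(res$fisher_p, oracle_fisher_p(30, 10, 40, 40),
               tolerance = 1e-9)
  # identical clonal fractions: OR ~ 1, p ~ 1
  ev2 <- ev
  ev2$clonality <- rep(c("clonal", "subclonal"), 60)
  res2 <- suppressWarnings(clonality_tests(ev2))
  expect_equal(res2$fisher_or, 1)
  expect_gt(res2$fisher_p, 0.9)
})

test_that("GLMM recovers planted clonality enrichment", {
  set.seed(25)
  n <- 500
  gene <- sample(sprintf("g%02d", 1:20), n, replace = TRUE)
  hot <- runif(n) < 0.3
  p_clonal <- ifelse(hot, 0.8, 0.45)
  ev <- data.frame(gene = gene, is_hotspot = hot,
                   clonality = ifelse(runif(n) < p_clonal,
                                      "clonal", "subclonal"),
                   count = ifelse(hot, sample(4:20, n, replace = TRUE),
                                  sample(1:3, n, replace = TRUE)),
                   stringsAsFactors = FALSE)
  res <- clonality_tests(ev)
  expect_gt(res$glmm_or, 1)
  expect_lt(res$glmm_p, 0.05)
  expect_true(res$glmm_ci[1] < res$glmm_or && res$glmm_or < res$glmm_ci[2])
})

test_that("mutability adjustment and exact 1-D two-cluster split", {
  sigs <- synthetic_signature_reference(5)
  E <- matrix(c(0.5, 0.5, 0, 0, 0, 0.2, 0.2, 0.2, 0.2, 0.2),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), rownames(sigs)))
  sites <- data.frame(key = c("a", "b"),
                      count = c(10L, 10L),
                      channel = c("T[C>T]A", "A[C>T]G"),
                      stringsAsFactors = FALSE)
  sel <- mutability_adjusted_recurrence(sites, E, sigs)
  expect_equal(sel$observed / sel$expected, sel$enrichment)
  expect_true(all(sel$expected > 0))
  # uniform mutability: enrichment proportional to raw counts
  flat <- matrix(rep(1 / 96, 96 * 2), nrow = 2,
                 dimnames = list(c("f1", "f2"), sbs96_channels()))
  class(flat) <- c("signature_matrix", class(flat))
  Ef <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("s1", "s2"),
                                                    c("f1", "f2")))
  sites2 <- data.frame(key = c("a", "b"), count = c(4L, 12L),
                       channel = c("T[C>T]A", "A[C>T]G"))
  self <- mutability_adjusted_recurrence(sites2, Ef, flat)
  expect_equal(self$enrichment[2] / self$enrichment[1], 3)

  cl <- univariate_two_cluster(c(1, 2, 100, 110))
  expect_equal(as.character(cl), c("low", "low", "high", "high"))
})

test_that("two-cluster DP matches exhaustive partitioning up to n = 12", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    v <- rnorm(n, sd = 5)
    w <- runif(n, 0.5, 2)
    cl <- univariate_two_cluster(v, w)
    expect_equal(attr(cl, "wcss"), oracle_two_cluster_wcss(v, w),
                 tolerance = 1e-9)
  }
})
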