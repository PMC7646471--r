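ref30 <- synthetic_signature_reference()

test_that("96-channel catalog assigns pyrimidine-strand channels", {
  ctx_c <- paste0(strrep("G", 11), "ACA", strrep("G", 11))
  rec <- data.frame(patient = "P1", sample = "S1", chrom = "chr1",
                    pos = 1:2, ref = c("C", "G"), alt = c("T", "A"),
                    gene = "X", protein_change = NA_character_,
                    context25 = c(ctx_c,
                                  # TGA on plus strand -> pyrimidine TCA
                                  paste0(strrep("A", 11), "TGA",
                                         strrep("A", 11))),
                    clonality = NA_character_, stringsAsFactors = FALSE)
  co <- apohot:::new_cohort_table(rec)
  cat96 <- build_96_catalog(co)
  expect_equal(sum(cat96), 2)
  expect_equal(cat96[1, "A[C>T]A"], 1L)
  expect_equal(cat96[1, "T[C>T]A"], 1L)   # reverse complement of TGA G>A
  expect_equal(attr(cat96, "n_excluded"), 0L)
})

test_that("records without context are excluded and counted", {
  rec <- data.frame(patient = "P1", sample = "S1", chrom = "chr1",
                    pos = 1:2, ref = "C", alt = "T", gene = "X",
                    protein_change = NA_character_,
                    context25 = c(paste0(strrep("A", 12), "C",
                                         strrep("A", 12)),
                                  NA_character_),
                    clonality = NA_character_, stringsAsFactors = FALSE)
  cat96 <- build_96_catalog(apohot:::new_cohort_table(rec))
  expect_equal(sum(cat96), 1)
  expect_equal(attr(cat96, "n_excluded"), 1L)
})

test_that("catalog of a simulated sample equals the simulator tally", {
  cfg <- small_sim_config(seed = 12)
  cfg$n_samples <- 20
  cfg$tail_counts <- c("2" = 5)
  cfg$planted_sites <- cfg$planted_sites[0, ]
  sim <- simulate_cohort(cfg)
  cat96 <- build_96_catalog(sim$cohort)
  # every record has a synthesised context, so catalog totals must equal
  # per-sample record counts exactly
  expect_equal(attr(cat96, "n_excluded"), 0L)
  expect_equal(unname(rowSums(cat96)),
               unname(as.vector(table(sim$cohort$records$sample))))
})

test_that("EM refitting recovers single and mixed signatures", {
  S <- unclass(ref30)
  set.seed(101)
  pure <- matrix(rmultinom(1, 500, S["2", ])[, 1], nrow = 1,
                 dimnames = list("s", sbs96_channels()))
  E <- fit_signature_exposures(pure, ref30)
  expect_gte(E["s", "2"], 0.95)
  expect_equal(sum(E["s", ]), 1, tolerance = 1e-6)

  mix <- 0.6 * S["2", ] + 0.4 * S["5", ]
  two <- matrix(rmultinom(1, 2000, mix)[, 1], nrow = 1,
                dimnames = list("s", sbs96_channels()))
  ref2 <- ref30[c("2", "5"), ]
  class(ref2) <- class(ref30)
  E2 <- fit_signature_exposures(two, ref2)
  expect_lt(abs(E2["s", "2"] - 0.6), 0.05)
  expect_lt(abs(E2["s", "5"] - 0.4), 0.05)
})

test_that("zero catalogs are flagged undefined with zero exposures", {
  z <- matrix(0L, nrow = 1, ncol = 96,
              dimnames = list("s0", sbs96_channels()))
  E <- fit_signature_exposures(z, ref30)
  expect_true(attr(E, "undefined")[1])
  expect_equal(sum(E), 0)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  S <- unclass(ref30)
  set.seed(77)
  m <- rmultinom(1, 300, 0.5 * S["1", ] + 0.5 * S["13", ])[, 1]
  K <- nrow(S)
  e <- rep(1 / K, K)
  ll <- c()
  for (it in 1:60) {
    mixp <- as.numeric(crossprod(S, e))
    ll <- c(ll, sum(m * log(mixp)))
    e <- e * as.numeric(S %*% (m / mixp)) / sum(m)
    e <- e / sum(e)
  }
  expect_true(all(diff(ll) > -1e-9))
})

test_that("exposure recovery MAE stays below 0.05 at 2000 mutations", {
  S <- unclass(ref30)
  maes <- vapply(1:20, function(sd) {
    set.seed(sd)
    true_e <- setNames(numeric(30), rownames(S))
    true_e[c("1", "2", "5", "13")] <- as.numeric(
      apohot:::rdirichlet1(c(2, 2, 2, 2)))
    m <- matrix(rmultinom(1, 2000, as.numeric(crossprod(S, true_e)))[, 1],
                nrow = 1, dimnames = list("s", sbs96_channels()))
    E <- fit_signature_exposures(m, ref30)
    mean(abs(E["s", ] - true_e))
  }, numeric(1))
  expect_lt(mean(maes), 0.05)
})

test_that("per-mutation attribution follows the exposure-weighted formula", {
  sigs <- synthetic_signature_reference(5)
  E <- matrix(c(1, 0, 0, 0, 0), nrow = 1,
              dimnames = list("s", rownames(sigs)))
  p <- per_mutation_process_probability(E, sigs, "s", "T[C>T]A")
  expect_equal(unname(p["1"]), 1)

  # two signatures, exposures (0.5, 0.5), channel intensities (0.09, 0.01)
  toy <- matrix(c(0.09, rep(0.91 / 95, 95),
                  0.01, rep(0.99 / 95, 95)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), sbs96_channels()))
  class(toy) <- c("signature_matrix", class(toy))
  E2 <- matrix(c(0.5, 0.5), nrow = 1, dimnames = list("s", c("a", "b")))
  p2 <- per_mutation_process_probability(E2, toy, "s", sbs96_channels()[1])
  expect_equal(as.numeric(p2), c(0.9, 0.1))
  expect_equal(sum(p2), 1)
})

test_that("planted APOBEC mutations attribute to the APOBEC signature", {
  S <- unclass(ref30)
  set.seed(5)
  true_e <- setNames(numeric(30), rownames(S))
  true_e[c("1", "2")] <- c(0.5, 0.5)
  m <- matrix(rmultinom(1, 1000, as.numeric(crossprod(S, true_e)))[, 1],
              nrow = 1, dimnames = list("s", sbs96_channels()))
  E <- fit_signature_exposures(m, ref30)
  p_tc <- per_mutation_process_probability(E, ref30, "s", "T[C>T]A")
  p_cg <- per_mutation_process_probability(E, ref30, "s", "A[C>T]G")
  # a TpC mutation attributes mostly to signature 2, an NpCpG one to 1
  expect_gt(p_tc["2"], p_cg["2"])
  expect_gt(p_cg["1"], p_tc["1"])
})

test_that("association test flags planted hotspots, not random carriers", {
  set.seed(21)
  n <- 200
  samples <- sprintf("S%03d", 1:n)
  score <- c(rbeta(n / 2, 2, 8), rbeta(n / 2, 8, 3))  # bimodal
  names(score) <- samples
  ctx <- paste0(strrep("A", 11), "TCA", strrep("A", 11))
  mk_panel <- function(carrier_sets) {
    panel <- data.frame(key = paste0("k", seq_along(carrier_sets)),
                        chrom = "chr1", pos = seq_along(carrier_sets),
                        ref = "C", alt = "T", gene = "X",
                        protein_change = NA, count = lengths(carrier_sets),
                        context25 = ctx,
                        motif_class = "APOBEC_TCN", subclass = "YTCN",
                        apobec_associated = NA, association_p = NA_real_,
                        stringsAsFactors = FALSE)
    panel$carriers <- carrier_sets
    panel
  }
  # carriers drawn preferentially from high-score samples
  w <- score / sum(score)
  planted <- lapply(1:5, function(i) sample(samples, 12, prob = w^3))
  out <- hotspot_association_test(mk_panel(planted), score)
  expect_true(all(out$apobec_associated))

  # carriers from the same distribution as everyone: type-I <= alpha
  reps <- 200
  calls <- numeric(0)
  for (r in 1:reps) {
    rnd <- lapply(1:3, function(i) sample(samples, 10))
    o <- hotspot_association_test(mk_panel(rnd), score)
    calls <- c(calls, o$apobec_associated)
  }
  expect_lte(mean(calls), 0.05)
})

test_that("hotspots with no carriers among scored samples are flagged NA", {
  ctx <- paste0(strrep("A", 11), "TCA", strrep("A", 11))
  panel <- data.frame(key = "k1", chrom = "chr1", pos = 1, ref = "C",
                      alt = "T", gene = "X", protein_change = NA,
                      count = 2L, context25 = ctx,
                      motif_class = "APOBEC_TCN", subclass = "YTCN",
                      apobec_associated = NA, association_p = NA_real_,
                      stringsAsFactors = FALSE)
  panel$carriers <- list(c("ZZZ1", "ZZZ2"))
  score <- setNames(runif(10), sprintf("S%02d", 1:10))
  out <- hotspot_association_test(panel, score)
  expect_true(is.na(out$apobec_associated[1]))
})
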