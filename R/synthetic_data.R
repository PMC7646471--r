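# Fully seeded synthetic inputs with the statistical structure the
# pipeline assumes: per-sample catalogues drawn from signature mixtures,
# planted recurrent APOBEC-motif sites with tunable hairpin stability,
# log-normal expression with an oncogene/TSG stratum and a housekeeping
# anchor, sawtooth RFD tracks, negative-binomial knockdown counts with a
# planted downregulated regulon, and clonality labels enriched among
# hotspots.  A truth manifest accompanies every cohort for recovery tests.

#' Default planted hotspot specification
#'
#' Sixteen classifier seed sites (9 known drivers in weak-or-no hairpins
#' on highly expressed genes, 7 known passengers in strong hairpin loops)
#' plus twelve sites of hidden truth (6 driver-like, 6 passenger-like)
#' and two recurrent non-APOBEC sites.  APOBEC sites carry a 10x
#' APOBEC-score carrier multiplier.
#'
#' @return data frame, one row per planted site.
#' @export
default_planted_sites <- function() {
  site <- function(gene, role, seed_label, tier, apobec, baseline,
                   multiplier) {
    data.frame(gene = gene, role = role, seed_label = seed_label,
               tier = tier, apobec = apobec, baseline = baseline,
               multiplier = multiplier, stringsAsFactors = FALSE)
  }
  rbind(
    do.call(rbind, lapply(1:9, function(i)
      site(sprintf("DRV%02d", i), "driver", "known_driver",
           if (i %% 3 == 0) "weak" else "none", TRUE, 0.004, 10))),
    do.call(rbind, lapply(1:7, function(i)
      site(sprintf("PSG%02d", i), "passenger", "known_passenger",
           "strong", TRUE, 0.004, 10))),
    do.call(rbind, lapply(1:6, function(i)
      site(sprintf("UDR%02d", i), "driver", "unknown",
           if (i %% 3 == 0) "weak" else "none", TRUE, 0.004, 10))),
    do.call(rbind, lapply(1:6, function(i)
      site(sprintf("UPS%02d", i), "passenger", "unknown",
           "strong", TRUE, 0.004, 10))),
    site("OTH01", "other", "unknown", "none", FALSE, 0.02, 1),
    site("OTH02", "other", "unknown", "none", FALSE, 0.015, 1)
  )
}

#' Simulation configuration
#'
#' Defaults mirror the cohort the pipeline is designed for: 602
#' exome-sequenced tumours averaging ~270 SNVs each (negative binomial),
#' signature exposures drawn from a Dirichlet prior dominated by ageing
#' and APOBEC processes, a long-tail background of private and mildly
#' recurrent sites, and the planted panel of [default_planted_sites()].
#'
#' @param n_samples cohort size.
#' @param mut_mean,mut_size negative-binomial per-sample mutation count.
#' @param signatures signature matrix (defaults to the synthetic
#'   30-profile reference).
#' @param dirichlet_alpha named values overriding both exposure priors.
#' @param apobec_high_frac fraction of APOBEC-high tumours in the cohort.
#' @param planted_sites planted hotspot specification data frame.
#' @param tail_counts named integer vector: number of background sites at
#'   each recurrence level >= 2 (the long-tail "head" shoulder).
#' @param n_bg_genes background gene pool size.
#' @param n_expr_genes genes in the simulated expression matrix.
#' @param clonal_p_hotspot,clonal_p_other clonal-label probabilities.
#' @param kd_regulon_size,kd_fold,kd_reps,kd_dispersion knockdown design.
#' @param rfd_cell_lines,rfd_chrom_length,rfd_origin_spacing,rfd_bin,rfd_noise
#'   RFD track shape.
#' @param seed master seed; every stage derives its stream from it.
#' @return config list.
#' @export
sim_config <- function(n_samples = 602,
                       mut_mean = 270, mut_size = 1.5,
                       signatures = synthetic_signature_reference(),
                       dirichlet_alpha = NULL,
                       apobec_high_frac = 0.5,
                       planted_sites = default_planted_sites(),
                       tail_counts = c("2" = 300, "3" = 130, "4" = 20,
                                       "5" = 10),
                       n_bg_genes = 1500,
                       n_expr_genes = 2000,
                       clonal_p_hotspot = 0.8,
                       clonal_p_other = 0.45,
                       kd_regulon_size = 25,
                       kd_fold = 4,
                       kd_reps = 4,
                       kd_dispersion = 0.05,
                       rfd_cell_lines = paste0("CL", 1:9),
                       rfd_chrom_length = 2e6,
                       rfd_origin_spacing = 2e5,
                       rfd_bin = 1e3,
                       rfd_noise = 0.05,
                       seed = 17) {
  K <- nrow(signatures)
  # bimodal cohort: APOBEC-high tumours are dominated by the two APOBEC
  # signatures, APOBEC-low tumours by the ageing/clock-like ones, giving
  # the strongly bimodal per-sample APOBEC fraction seen in bladder cohorts
  alpha_low <- rep(0.02, K)
  names(alpha_low) <- rownames(signatures)
  alpha_high <- alpha_low
  alpha_low[c("1", "5")] <- 2.5
  alpha_low[c("2", "13")] <- 0.3
  alpha_high[c("1", "5")] <- 1
  alpha_high[c("2", "13")] <- 3.5
  if (!is.null(dirichlet_alpha)) {
    alpha_low[names(dirichlet_alpha)] <- dirichlet_alpha
    alpha_high[names(dirichlet_alpha)] <- dirichlet_alpha
  }
  stopifnot(all(planted_sites$tier %in% c("strong", "weak", "none")),
            all(planted_sites$baseline >= 0),
            all(planted_sites$multiplier >= 0))
  if (any(planted_sites$tier == "strong" & !planted_sites$apobec &
            planted_sites$role == "driver")) {
    stop("infeasible planted site: non-APOBEC driver in a strong hairpin")
  }
  list(n_samples = n_samples, mut_mean = mut_mean, mut_size = mut_size,
       signatures = signatures, alpha_low = alpha_low,
       alpha_high = alpha_high, apobec_high_frac = apobec_high_frac,
       planted_sites = planted_sites, tail_counts = tail_counts,
       n_bg_genes = n_bg_genes, n_expr_genes = n_expr_genes,
       clonal_p_hotspot = clonal_p_hotspot,
       clonal_p_other = clonal_p_other,
       kd_regulon_size = kd_regulon_size, kd_fold = kd_fold,
       kd_reps = kd_reps, kd_dispersion = kd_dispersion,
       rfd_cell_lines = rfd_cell_lines,
       rfd_chrom_length = rfd_chrom_length,
       rfd_origin_spacing = rfd_origin_spacing,
       rfd_bin = rfd_bin, rfd_noise = rfd_noise,
       seed = seed)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# 25-nt plus-strand context with the centre base mutable and a hairpin of
# the requested stability tier; APOBEC sites put the centre C in a TCN
# motif inside the terminal loop
planted_context25 <- function(tier, apobec) {
  centre3 <- if (apobec) c("T", "C", "A") else c("A", "C", "A")
  loop5 <- c(sample(c("T", "A"), 1), centre3, sample(c("A", "T"), 1))
  if (tier == "strong") {
    arm <- sample(c("G", "C"), 7, replace = TRUE)
    ctx <- c(rep("A", 3), arm, loop5, rev(unname(DNA_COMPLEMENT[arm])),
             rep("A", 3))
  } else if (tier == "weak") {
    arm <- c("C", sample(c("A", "T"), 4, replace = TRUE))
    ctx <- c(rep("A", 5), arm, loop5, rev(unname(DNA_COMPLEMENT[arm])),
             rep("A", 5))
  } else {
    # A/C alphabet admits no Watson-Crick pair: guaranteed unstructured
    flank <- function(n) sample(c("A", "C"), n, replace = TRUE)
    ctx <- c(flank(11), centre3, flank(11))
  }
  paste(ctx, collapse = "")
}

# random 25-nt context consistent with a 96-channel label (pyrimidine
# strand); flipped to the purine strand with probability 0.5
context_for_channel <- function(channel, flip = NULL) {
  up <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  down <- substr(channel, 7, 7)
  flank5 <- paste(sample(c("A", "C", "G", "T"), 11, replace = TRUE),
                  collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), 11, replace = TRUE),
                  collapse = "")
  ctx <- paste0(flank5, up, ref, down, flank3)
  if (is.null(flip)) flip <- stats::runif(1) < 0.5
  if (flip) {
    list(context = revcomp(ctx), ref = unname(DNA_COMPLEMENT[ref]),
         alt = unname(DNA_COMPLEMENT[alt]))
  } else {
    list(context = ctx, ref = ref, alt = alt)
  }
}

#' Simulate a mutation cohort with planted hotspots
#'
#' Background mutations are drawn per sample from the exposure-weighted
#' signature mixture at private positions; a configurable shoulder of
#' mildly recurrent background sites forms the tail/head boundary; the
#' planted sites of `config$planted_sites` recruit carriers with
#' probability `baseline * (1 + (multiplier - 1) * apobec_score)`,
#' truncated at 1, so APOBEC-role sites concentrate in high-APOBEC
#' samples.  Clonality labels are drawn per the config.  Fully
#' reproducible from (config, seed).
#'
#' @param config from [sim_config()].
#' @return list `cohort` (a `cohort_table`) and `truth` (manifest with
#'   per-site roles/carriers, per-sample true exposures and APOBEC score).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  S <- unclass(config$signatures)
  K <- nrow(S)
  high <- stats::runif(n) < config$apobec_high_frac
  E <- t(vapply(seq_len(n), function(i)
    rdirichlet1(if (high[i]) config$alpha_high else config$alpha_low),
    numeric(K)))
  dimnames(E) <- list(sample_ids, rownames(S))
  apo <- rowSums(E[, intersect(c("2", "13"), colnames(E)), drop = FALSE])
  chans <- sbs96_channels()
  bg_genes <- sprintf("G%04d", seq_len(config$n_bg_genes))

  records <- list()
  # background private mutations
  m_counts <- stats::rnbinom(n, mu = config$mut_mean, size = config$mut_size)
  total_bg <- sum(m_counts)
  pos_pool <- sample.int(1.8e8, total_bg +
                           sum(as.integer(config$tail_counts)) +
                           nrow(config$planted_sites))
  pos_i <- 0L
  for (s in seq_len(n)) {
    m <- m_counts[s]
    if (m == 0) next
    p_chan <- as.numeric(crossprod(S, E[s, ]))
    ch_counts <- stats::rmultinom(1, m, p_chan)[, 1]
    ch <- rep(chans, ch_counts)
    ctx <- lapply(ch, context_for_channel)
    records[[length(records) + 1]] <- data.frame(
      patient = sample_ids[s], sample = sample_ids[s], chrom = "chr1",
      pos = pos_pool[pos_i + seq_len(m)],
      ref = vapply(ctx, `[[`, character(1), "ref"),
      alt = vapply(ctx, `[[`, character(1), "alt"),
      gene = sample(bg_genes, m, replace = TRUE),
      protein_change = NA_character_,
      context25 = vapply(ctx, `[[`, character(1), "context"),
      clonality = ifelse(stats::runif(m) < config$clonal_p_other,
                         "clonal", "subclonal"),
      stringsAsFactors = FALSE)
    pos_i <- pos_i + m
  }
  # mildly recurrent background shoulder
  tail_rows <- list()
  for (cc in names(config$tail_counts)) {
    cnt <- as.integer(cc)
    for (r in seq_len(config$tail_counts[[cc]])) {
      pos_i <- pos_i + 1L
      ctx <- context_for_channel(sample(chans, 1,
                                        prob = colMeans(E %*% S)))
      carriers <- sample(sample_ids, cnt)
      tail_rows[[length(tail_rows) + 1]] <- data.frame(
        patient = carriers, sample = carriers, chrom = "chr1",
        pos = pos_pool[pos_i], ref = ctx$ref, alt = ctx$alt,
        gene = sample(bg_genes, 1), protein_change = NA_character_,
        context25 = ctx$context,
        clonality = ifelse(stats::runif(cnt) < config$clonal_p_other,
                           "clonal", "subclonal"),
        stringsAsFactors = FALSE)
    }
  }
  # planted sites
  ps <- config$planted_sites
  truth_sites <- ps
  truth_sites$key <- rep(NA_character_, nrow(ps))
  truth_sites$context25 <- rep(NA_character_, nrow(ps))
  truth_sites$carriers <- vector("list", nrow(ps))
  planted_rows <- list()
  for (i in seq_len(nrow(ps))) {
    pos_i <- pos_i + 1L
    ctx <- planted_context25(ps$tier[i], ps$apobec[i])
    ref <- "C"
    alt <- if (ps$apobec[i] && stats::runif(1) < 0.85) "T" else
      if (ps$apobec[i]) "G" else "T"
    p_carry <- pmin(1, ps$baseline[i] * (1 + (ps$multiplier[i] - 1) * apo))
    carriers <- sample_ids[stats::runif(n) < p_carry]
    truth_sites$key[i] <- paste("chr1", pos_pool[pos_i], ref, alt,
                                sep = ":")
    truth_sites$context25[i] <- ctx
    truth_sites$carriers[[i]] <- carriers
    if (length(carriers) == 0) next
    planted_rows[[length(planted_rows) + 1]] <- data.frame(
      patient = carriers, sample = carriers, chrom = "chr1",
      pos = pos_pool[pos_i], ref = ref, alt = alt,
      gene = ps$gene[i],
      protein_change = sprintf("%s%dX", "Q", 100 + i),
      context25 = ctx,
      clonality = ifelse(stats::runif(length(carriers)) <
                           config$clonal_p_hotspot,
                         "clonal", "subclonal"),
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, c(records, tail_rows, planted_rows))
  rec <- rec[order(rec$sample, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  cohort <- new_cohort_table(rec)
  truth <- list(sites = truth_sites, exposures = E, apobec_score = apo,
                seed = config$seed)
  list(cohort = cohort, truth = truth)
}

#' Simulate a gene x sample expression matrix
#'
#' Log-normal expression with an oncogene/TSG stratum (planted driver
#' genes, elevated mean), a heterogeneous unknown stratum, a positive
#' housekeeping anchor (GAPDH), and a latent AhR-programme factor that
#' induces the anchored co-expression structure (AHR, CYP1A1 and the
#' regulon genes load on it).
#'
#' @param config from [sim_config()].
#' @param anchor housekeeping anchor symbol.
#' @return genes x samples matrix; attributes `strata` (named character)
#'   and `regulon_genes`.
#' @export
simulate_expression <- function(config, anchor = "GAPDH") {
  set.seed(config$seed + 1L)
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  ps <- config$planted_sites
  driver_genes <- unique(ps$gene[ps$role == "driver"])
  other_planted <- setdiff(unique(ps$gene), driver_genes)
  n_fill <- max(0, config$n_expr_genes - length(driver_genes) -
                  length(other_planted) - 3)
  fill <- sprintf("G%04d", seq_len(n_fill))
  regulon <- sprintf("REG%03d", seq_len(config$kd_regulon_size))
  genes <- c(anchor, "AHR", "CYP1A1", driver_genes, other_planted,
             regulon, fill)
  genes <- unique(genes)
  strata <- rep("unknown", length(genes))
  names(strata) <- genes
  strata[driver_genes] <- "og_tsg"
  strata[anchor] <- "anchor"
  meanlog <- ifelse(strata == "og_tsg", 2.5,
                    ifelse(strata == "anchor", 8, 0))
  sdlog <- ifelse(strata == "og_tsg", 0.8,
                  ifelse(strata == "anchor", 0.1, 1.5))
  z <- stats::rnorm(n)  # latent AhR-programme activity per sample
  loading <- stats::setNames(rep(0, length(genes)), genes)
  # programme genes load at least as strongly on the latent activity as
  # the anchors do, so their pairwise correlations with both anchors can
  # clear the anchors' mutual correlation threshold
  loading[c("AHR", "CYP1A1")] <- 0.7
  loading[regulon] <- 1.3
  prog <- match(c("AHR", "CYP1A1", regulon), genes)
  sdlog[prog] <- 1.0
  meanlog[prog] <- 1.5  # moderately expressed, clear of the variance filter
  m <- matrix(0, nrow = length(genes), ncol = n,
              dimnames = list(genes, sample_ids))
  for (g in seq_along(genes)) {
    m[g, ] <- exp(stats::rnorm(n, meanlog[g], sdlog[g]) + loading[g] * z)
  }
  attr(m, "strata") <- strata
  attr(m, "regulon_genes") <- regulon
  attr(m, "units") <- "normalised"
  m
}

#' Simulate a knockdown vs control count matrix
#'
#' Negative-binomial counts for `2 * kd_reps` libraries; the planted
#' regulon genes are downregulated `kd_fold`-fold in the knockdown arm.
#'
#' @param config from [sim_config()].
#' @param n_genes genes in the count matrix (regulon genes included).
#' @return integer matrix with attribute `group` (condition factor) and
#'   `regulon_genes`.
#' @export
simulate_knockdown <- function(config, n_genes = 4000) {
  set.seed(config$seed + 2L)
  regulon <- sprintf("REG%03d", seq_len(config$kd_regulon_size))
  fill <- sprintf("G%04d", seq_len(n_genes - length(regulon)))
  genes <- c(regulon, fill)
  reps <- config$kd_reps
  group <- factor(rep(c("control", "knockdown"), each = reps),
                  levels = c("control", "knockdown"))
  mu0 <- exp(stats::rnorm(length(genes), log(200), 1))
  size <- 1 / config$kd_dispersion
  m <- matrix(0L, nrow = length(genes), ncol = 2 * reps,
              dimnames = list(genes,
                              paste0(rep(c("ctl", "kd"), each = reps),
                                     seq_len(reps))))
  for (g in seq_along(genes)) {
    mu <- rep(mu0[g], 2 * reps)
    if (genes[g] %in% regulon) {
      mu[group == "knockdown"] <- mu[group == "knockdown"] / config$kd_fold
    }
    m[g, ] <- stats::rnbinom(2 * reps, mu = mu, size = size)
  }
  attr(m, "group") <- group
  attr(m, "regulon_genes") <- regulon
  m
}

#' Simulate replication fork directionality tracks
#'
#' Piecewise-linear sawtooth profiles between evenly spaced (jittered)
#' replication origins, falling from +1 just right of an origin to -1
#' approaching the next, plus bounded noise, clipped to \[-1, 1\], binned
#' as bedGraph-style intervals.  One track per configured cell line.
#'
#' @param config from [sim_config()].
#' @return list of `rfd_track` objects.
#' @export
simulate_rfd <- function(config) {
  set.seed(config$seed + 3L)
  lapply(config$rfd_cell_lines, function(cl) {
    len <- config$rfd_chrom_length
    sp <- config$rfd_origin_spacing
    origins <- seq(0, len, by = sp) +
      c(0, stats::runif(length(seq(0, len, by = sp)) - 1, -0.2, 0.2) * sp)
    origins <- sort(pmax(0, pmin(len, origins)))
    starts <- seq(0, len - config$rfd_bin, by = config$rfd_bin)
    mids <- starts + config$rfd_bin / 2
    iv <- findInterval(mids, origins)
    left <- origins[pmax(iv, 1)]
    right <- origins[pmin(iv + 1, length(origins))]
    frac <- ifelse(right > left, (mids - left) / (right - left), 0.5)
    rfd <- 1 - 2 * frac + stats::rnorm(length(mids), 0, config$rfd_noise)
    rfd <- pmax(-1, pmin(1, rfd))
    new_rfd_track(data.frame(chrom = "chr1", start = as.integer(starts),
                             end = as.integer(starts + config$rfd_bin),
                             rfd = rfd),
                  cell_line = cl)
  })
}
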