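#' Build per-sample 96-channel mutation catalogues
#'
#' Each SNV with at least a +/-1 nt context is assigned to its
#' pyrimidine-strand trinucleotide channel; records lacking context or with
#' ambiguous bases are excluded and counted in the `n_excluded` attribute.
#'
#' @param cohort a `cohort_table`.
#' @return integer matrix samples x 96 with attribute `n_excluded`.
#' @export
build_96_catalog <- function(cohort) {
  rec <- cohort$records
  chans <- sbs96_channels()
  samples <- sort(unique(rec$sample))
  m <- matrix(0L, nrow = length(samples), ncol = 96,
              dimnames = list(samples, chans))
  excluded <- 0L
  for (i in seq_len(nrow(rec))) {
    ctx <- rec$context25[i]
    ch <- if (is.na(ctx)) NA_character_ else
      tryCatch(channel_from_context(ctx, rec$ref[i], rec$alt[i]),
               error = function(e) NA_character_)
    if (is.na(ch)) {
      excluded <- excluded + 1L
    } else {
      m[rec$sample[i], ch] <- m[rec$sample[i], ch] + 1L
    }
  }
  attr(m, "n_excluded") <- excluded
  m
}

#' Refit fixed signature profiles to mutation catalogues
#'
#' Exposures are per-sample mixing fractions of the reference profiles,
#' estimated by expectation-maximisation for the multinomial mixture
#' m_c ~ sum_k E\[k\] S\[k,c\]: the maximum-likelihood non-negative
#' refit with profiles held fixed (profiles are inputs, never learned).
#' The log-likelihood is non-decreasing across iterations.  Samples with
#' zero usable mutations receive all-zero exposures and are flagged in the
#' `undefined` attribute.
#'
#' @param catalog samples x 96 integer matrix.
#' @param ref signature matrix (signatures x 96).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return exposure matrix samples x signatures, rows summing to 1, with
#'   attribute `undefined` (logical per sample).
#' @export
fit_signature_exposures <- function(catalog, ref, max_iter = 5000,
                                    tol = 1e-9) {
  if (is.null(dim(catalog))) {
    catalog <- matrix(catalog, nrow = 1,
                      dimnames = list("sample", sbs96_channels()))
  }
  S <- unclass(ref)[, colnames(catalog), drop = FALSE]
  K <- nrow(S)
  E <- matrix(0, nrow = nrow(catalog), ncol = K,
              dimnames = list(rownames(catalog), rownames(S)))
  undefined <- logical(nrow(catalog))
  converged <- logical(nrow(catalog))
  for (s in seq_len(nrow(catalog))) {
    m <- as.numeric(catalog[s, ])
    M <- sum(m)
    if (M == 0) {
      undefined[s] <- TRUE
      converged[s] <- TRUE
      next
    }
    e <- rep(1 / K, K)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      mix <- as.numeric(crossprod(S, e))          # length 96
      mix[mix <= 0] <- .Machine$double.xmin
      # E-step responsibilities folded into the M-step update
      w <- m / mix
      e_new <- e * as.numeric(S %*% w) / M
      e_new <- e_new / sum(e_new)
      ll <- sum(m * log(mix))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
        e <- e_new
        converged[s] <- TRUE
        break
      }
      ll_old <- ll
      e <- e_new
    }
    if (!converged[s]) {
      warning("EM did not converge for sample ", rownames(catalog)[s],
              "; best iterate returned")
    }
    E[s, ] <- e
  }
  attr(E, "undefined") <- undefined
  E
}

#' APOBEC signature score per sample
#'
#' The arithmetic sum of the fitted fractions of the two APOBEC-attributed
#' signatures (by default those labelled "2" and "13").
#'
#' @param exposures exposure matrix from [fit_signature_exposures()].
#' @param apobec_ids character ids of the APOBEC signatures in the reference.
#' @return named numeric vector in \[0, 1\].
#' @export
apobec_score <- function(exposures, apobec_ids = c("2", "13")) {
  present <- intersect(apobec_ids, colnames(exposures))
  if (length(present) == 0) stop("no APOBEC signatures in exposure matrix")
  rowSums(exposures[, present, drop = FALSE])
}

#' Test candidate hotspots for association with APOBEC mutagenesis
#'
#' For every hotspot with an APOBEC-type motif, carriers' APOBEC scores are
#' compared with the scores of samples carrying none of the APOBEC-motif
#' candidates (one-sided Wilcoxon rank-sum, "greater").  P values are
#' Benjamini-Hochberg adjusted across candidates; a hotspot is
#' APOBEC-associated iff adjusted p < `alpha`.  Non-candidate hotspots are
#' not APOBEC-associated by definition.
#'
#' @param panel a `hotspot_panel`.
#' @param scores named per-sample APOBEC score vector.
#' @param alpha significance level after BH adjustment.
#' @param adjust apply BH adjustment (the documented default) or use raw p.
#' @return the panel with `apobec_associated` and `association_p` filled.
#' @export
hotspot_association_test <- function(panel, scores, alpha = 0.05,
                                     adjust = TRUE) {
  cand <- which(panel$motif_class == "APOBEC_TCN")
  if (length(cand) == 0) {
    panel$apobec_associated <- FALSE
    return(panel)
  }
  cand_carriers <- unique(unlist(panel$carriers[cand]))
  background <- setdiff(names(scores), cand_carriers)
  p <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    carriers <- intersect(panel$carriers[[cand[i]]], names(scores))
    if (length(carriers) == 0 || length(background) == 0) next
    p[i] <- stats::wilcox.test(scores[carriers], scores[background],
                               alternative = "greater", exact = FALSE)$p.value
  }
  padj <- if (adjust) stats::p.adjust(p, method = "BH") else p
  panel$association_p[cand] <- padj
  panel$apobec_associated <- FALSE
  panel$apobec_associated[cand] <- !is.na(padj) & padj < alpha
  panel$apobec_associated[cand][is.na(padj)] <- NA
  panel
}

#' Per-mutation attribution to mutational processes
#'
#' Given a sample's fitted exposures and the reference profiles, the
#' probability that a mutation in channel `c` arose from signature `k` is
#' E\[k\] S\[k,c\] / sum_j E\[j\] S\[j,c\].  When the denominator is zero the
#' attribution is uniform over signatures with nonzero exposure and flagged.
#'
#' @param exposures exposure matrix (samples x signatures).
#' @param ref signature matrix.
#' @param sample sample id (row of `exposures`).
#' @param channel 96-channel label of the mutation.
#' @return numeric vector over signatures, summing to 1, with attribute
#'   `degenerate` when the uniform fallback was used.
#' @export
per_mutation_process_probability <- function(exposures, ref, sample,
                                             channel) {
  e <- exposures[sample, ]
  s_c <- unclass(ref)[, channel]
  num <- e * s_c
  tot <- sum(num)
  if (tot <= 0) {
    nz <- e > 0
    p <- ifelse(nz, 1 / sum(nz), 0)
    names(p) <- colnames(exposures)
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  p <- num / tot
  attr(p, "degenerate") <- FALSE
  p
}

#' Synthetic 30-signature reference matrix
#'
#' A deterministic, synthetic stand-in for a 30-profile reference catalogue
#' of 96-channel mutational signatures (real catalogues require a download
#' and are not bundled).  Signatures "2" and "13" are built as APOBEC-like
#' profiles: "2" concentrates ~90\% of its mass on T\[C>T\]N channels and
#' "13" on T\[C>G\]N channels, mirroring the known APOBEC substitution
#' spectra; signature "1" is ageing-like (N\[C>T\]G-heavy); the remainder
#' are smooth pseudo-random profiles.  Deterministic: the same matrix is
#' produced on every call.
#'
#' @param n_signatures number of profiles (>= 13 retains the APOBEC pair).
#' @return a `signature_matrix` (n x 96), rows summing to 1.
#' @export
synthetic_signature_reference <- function(n_signatures = 30) {
  chans <- sbs96_channels()
  n <- n_signatures
  set <- function(profile, idx, mass) {
    profile[idx] <- profile[idx] + mass / length(idx)
    profile
  }
  sub_of <- sub("^.\\[(.+)\\].$", "\\1", chans)
  up_of <- substr(chans, 1, 1)
  down_of <- substr(chans, 7, 7)
  out <- matrix(0, nrow = n, ncol = 96, dimnames = list(as.character(1:n),
                                                        chans))
  # reproducible pseudo-random baseline, independent of the user RNG stream
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20200928L)
  for (k in seq_len(n)) {
    base <- stats::rgamma(96, shape = 0.35)
    out[k, ] <- base / sum(base)
  }
  # signature 1: ageing-like, C>T at NpCpG
  s1 <- rep(0.1 / 96, 96)
  s1 <- set(s1, which(sub_of == "C>T" & down_of == "G"), 0.75)
  s1 <- set(s1, which(sub_of == "C>T"), 0.15)
  out[1, ] <- s1 / sum(s1)
  # signature 2: APOBEC-like C>T at TpC
  s2 <- rep(0.08 / 96, 96)
  s2 <- set(s2, which(sub_of == "C>T" & up_of == "T"), 0.90)
  s2 <- set(s2, which(sub_of == "C>G" & up_of == "T"), 0.02)
  out[2, ] <- s2 / sum(s2)
  # signature 13: APOBEC-like C>G at TpC
  s13 <- rep(0.08 / 96, 96)
  s13 <- set(s13, which(sub_of == "C>G" & up_of == "T"), 0.90)
  s13 <- set(s13, which(sub_of == "C>T" & up_of == "T"), 0.02)
  if (n >= 13) out[13, ] <- s13 / sum(s13)
  # signature 5: flat-ish (clock-like), helps mixture identifiability tests
  if (n >= 5) {
    s5 <- stats::rgamma(96, shape = 5)
    out[5, ] <- s5 / sum(s5)
  }
  class(out) <- c("signature_matrix", class(out))
  out
}
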