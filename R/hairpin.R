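# Nearest-neighbour minimum-free-energy folding of short single-stranded
# DNA windows: Zuker-style dynamic programme restricted to structures
# without multiloops (helices with bulges/internal loops, terminal hairpin
# loops, any number of stems in the exterior loop).  Energies are unified
# nearest-neighbour DNA stack free energies at 37 C plus loop-length
# initiation penalties, shipped as editable TSVs under extdata.  Absolute
# free energies are approximate; downstream use rests on ordering and
# thresholding at 0, not on equality with any particular folding tool.

.fold_env <- new.env(parent = emptyenv())

fold_params <- function() {
  if (is.null(.fold_env$stack)) {
    st <- read.delim(system.file("extdata", "dna_stack_dg37.tsv",
                                 package = "apohot"),
                     stringsAsFactors = FALSE)
    stack <- st$dg
    names(stack) <- st$dimer
    lp <- read.delim(system.file("extdata", "dna_loop_dg37.tsv",
                                 package = "apohot"),
                     stringsAsFactors = FALSE)
    .fold_env$stack <- stack
    .fold_env$loops <- lp
  }
  list(stack = .fold_env$stack, loops = .fold_env$loops)
}

# loop initiation penalty with linear interpolation between tabulated sizes
# and Jacobson-Stockmayer extrapolation beyond the largest one
loop_penalty <- function(type, size, loops) {
  tab <- loops[loops$type == type, ]
  if (size < min(tab$size)) return(Inf)
  if (size > max(tab$size)) {
    # 2.44 * R * T at 310.15 K
    return(tab$dg[which.max(tab$size)] +
             1.5044 * log(size / max(tab$size)))
  }
  stats::approx(tab$size, tab$dg, xout = size)$y
}

pair_ok <- function(a, b, allow_gt = FALSE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (allow_gt) {
    wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  } else {
    wc
  }
}

#' Minimum-free-energy fold of a short DNA window
#'
#' Finds the minimum-free-energy secondary structure of a 13-31 nt DNA
#' sequence over all non-pseudoknotted structures without multiloops:
#' stems (stacked Watson-Crick pairs, optionally G.T wobbles) interrupted
#' by bulges or internal loops, closed by terminal hairpin loops of at
#' least 3 nt, with any number of stems in the exterior loop.  If no
#' structure has negative free energy the empty structure is returned with
#' `delta_g = 0`.  Ties are broken deterministically during traceback
#' (hairpin closure before stacking, smaller 5' indices first).
#'
#' @param sequence uppercase A/C/G/T string, 13-31 nt (shorter sequences
#'   are accepted when `strict_length = FALSE`, used by window escalation).
#' @param allow_gt allow G.T wobble pairs (off by default; wobble stacks
#'   use a single approximate energy).
#' @param strict_length enforce the 13-31 nt window contract.
#' @return a `fold_result`: list with `sequence`, `pairing` (partner index
#'   per position, 0 = unpaired), `delta_g` (kcal/mol), `centre_in_loop`,
#'   `loop_closing_pair` (c(i, j) or NULL).
#' @export
fold_mfe <- function(sequence, allow_gt = FALSE, strict_length = TRUE) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (any(!s %in% c("A", "C", "G", "T"))) {
    stop("sequence must contain only A/C/G/T")
  }
  if (strict_length && (n < 13 || n > 31)) {
    stop("sequence length must be within 13-31 nt")
  }
  pr <- fold_params()
  wobble_stack <- -0.5  # approximate energy for stacks involving G.T
  stack_energy <- function(i, j) {
    # closing pair (i,j) stacked on (i+1, j-1)
    dimer <- paste0(s[i], s[i + 1])
    e <- pr$stack[dimer]
    if (is.na(e) ||
        !pair_ok(s[i], s[j]) || !pair_ok(s[i + 1], s[j - 1])) {
      return(wobble_stack)
    }
    unname(e)
  }
  INF <- 1e9
  V <- matrix(INF, n, n)
  # V[i, j]: best energy of a structure closed by pair (i, j)
  for (span in 4:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      if (!pair_ok(s[i], s[j], allow_gt)) next
      best <- loop_penalty("hairpin", j - i - 1, pr$loops)
      if (j - i >= 6) {
        for (k in (i + 1):(j - 5)) {
          for (l in (k + 4):(j - 1)) {
            if (V[k, l] >= INF) next
            n1 <- k - i - 1
            n2 <- j - l - 1
            if (n1 + n2 > 30) next
            e <- if (n1 == 0 && n2 == 0) {
              stack_energy(i, j)
            } else if (n1 == 0 || n2 == 0) {
              loop_penalty("bulge", n1 + n2, pr$loops)
            } else {
              loop_penalty("internal", n1 + n2, pr$loops)
            }
            cand <- V[k, l] + e
            if (cand < best) best <- cand
          }
        }
      }
      V[i, j] <- best
    }
  }
  # exterior loop
  W <- c(0, rep(0, n))  # W[j + 1] = best energy of prefix 1..j
  Wchoice <- vector("list", n + 1)
  for (j in seq_len(n)) {
    best <- W[j]          # j unpaired
    choice <- NULL
    for (i in seq_len(max(j - 4, 0))) {
      if (V[i, j] < INF) {
        cand <- W[i] + V[i, j]
        if (cand < best - 1e-12) {
          best <- cand
          choice <- c(i, j)
        }
      }
    }
    W[j + 1] <- best
    Wchoice[j + 1] <- list(choice)
  }
  mfe <- W[n + 1]
  pairing <- integer(n)
  if (mfe < -1e-12) {
    # traceback exterior
    stack_iv <- list()
    j <- n
    while (j >= 1) {
      ch <- Wchoice[[j + 1]]
      if (is.null(ch)) {
        j <- j - 1
      } else {
        stack_iv[[length(stack_iv) + 1]] <- ch
        j <- ch[1] - 1
      }
    }
    trace_v <- function(i, j) {
      pairing[i] <<- j
      pairing[j] <<- i
      hp <- loop_penalty("hairpin", j - i - 1, pr$loops)
      if (abs(V[i, j] - hp) < 1e-12) return(invisible())
      if (j - i >= 6) {
        for (k in (i + 1):(j - 5)) {
          for (l in (k + 4):(j - 1)) {
            if (V[k, l] >= INF) next
            n1 <- k - i - 1
            n2 <- j - l - 1
            if (n1 + n2 > 30) next
            e <- if (n1 == 0 && n2 == 0) {
              stack_energy(i, j)
            } else if (n1 == 0 || n2 == 0) {
              loop_penalty("bulge", n1 + n2, pr$loops)
            } else {
              loop_penalty("internal", n1 + n2, pr$loops)
            }
            if (abs(V[i, j] - (V[k, l] + e)) < 1e-9) {
              trace_v(k, l)
              return(invisible())
            }
          }
        }
      }
    }
    for (iv in stack_iv) trace_v(iv[1], iv[2])
  } else {
    mfe <- 0
  }
  centre <- (n + 1L) %/% 2L
  loop_pair <- enclosing_hairpin_loop(pairing, centre)
  structure(list(sequence = sequence,
                 pairing = pairing,
                 delta_g = round(mfe, 6),
                 centre_in_loop = !is.null(loop_pair),
                 loop_closing_pair = loop_pair),
            class = "fold_result")
}

# the hairpin loop (closing pair) containing position `pos`, if any:
# pos unpaired, enclosed by a pair (i, j) with every base between i and j
# unpaired
enclosing_hairpin_loop <- function(pairing, pos) {
  if (pairing[pos] != 0) return(NULL)
  n <- length(pairing)
  for (i in rev(seq_len(pos - 1))) {
    j <- pairing[i]
    if (j > pos) {
      inside <- (i + 1):(j - 1)
      if (all(pairing[inside] == 0)) return(c(i, j))
      return(NULL)  # innermost enclosing pair is not a hairpin closure
    }
    if (j != 0 && j < pos) return(NULL)  # sibling helix; pos is exterior here
  }
  NULL
}

#' @exportS3Method base::print
print.fold_result <- function(x, ...) {
  dots <- rep(".", nchar(x$sequence))
  dots[x$pairing != 0 & seq_along(dots) < x$pairing] <- "("
  dots[x$pairing != 0 & seq_along(dots) > x$pairing] <- ")"
  cat(x$sequence, "\n", paste(dots, collapse = ""),
      sprintf("  dG = %.2f kcal/mol%s\n", x$delta_g,
              if (x$centre_in_loop) "  [centre in loop]" else ""), sep = "")
  invisible(x)
}

#' Window escalation scan around a mutation site
#'
#' Folds centred windows of increasing length (13, 17, 21, 25, 29 nt by
#' default) and reports, per length, the fold and the identity of the stem
#' enclosing the centre.  The completion length is the smallest window at
#' which the centre's stem-loop (its enclosing helix, in centre-relative
#' coordinates) is identical to the one found at the largest window; the
#' scan also reports whether stems not involving the centre first appear
#' in windows longer than 25 nt.
#'
#' @param context plus-strand sequence of odd length >= the largest window,
#'   centred on the mutation site.
#' @param lengths window lengths to scan.
#' @param allow_gt passed to [fold_mfe()].
#' @return list with `folds` (per length), `completion_length` (NA when the
#'   centre is never in a stable stem-loop), `secondary_after_25`.
#' @export
window_escalation_scan <- function(context, lengths = c(13, 17, 21, 25, 29),
                                   allow_gt = FALSE) {
  n <- nchar(context)
  if (n %% 2L == 0L) stop("context must have odd length")
  if (n < max(lengths)) stop("context shorter than the largest window")
  mid <- (n + 1L) %/% 2L
  folds <- list()
  stems <- list()
  secondary <- logical(length(lengths))
  for (w in seq_along(lengths)) {
    L <- lengths[w]
    half <- (L - 1L) %/% 2L
    win <- substr(context, mid - half, mid + half)
    f <- fold_mfe(win, allow_gt = allow_gt, strict_length = FALSE)
    folds[[as.character(L)]] <- f
    centre <- half + 1L
    # enclosing helix in centre-relative coordinates
    enclosing <- which(f$pairing != 0 &
                         seq_along(f$pairing) < centre &
                         f$pairing > centre)
    stems[w] <- list(if (length(enclosing) == 0) NULL else
      cbind(enclosing - centre, f$pairing[enclosing] - centre))
    other <- which(f$pairing != 0 &
                     !(seq_along(f$pairing) %in%
                         c(enclosing, f$pairing[enclosing])))
    secondary[w] <- length(other) > 0
  }
  final_stem <- stems[[length(lengths)]]
  completion <- NA_integer_
  if (!is.null(final_stem)) {
    for (w in seq_along(lengths)) {
      if (!is.null(stems[[w]]) && identical(stems[[w]], final_stem)) {
        completion <- lengths[w]
        break
      }
    }
    if (is.na(completion)) completion <- lengths[length(lengths)]
  }
  list(folds = folds,
       completion_length = completion,
       secondary_after_25 = !any(secondary[lengths <= 25]) &&
         any(secondary[lengths > 25]))
}

#' Normalised loop stability scores
#'
#' Min-max rescaling of hairpin-loop free energies over a panel: for sites
#' located in a hairpin loop with `delta_g < 0`, the score is
#' (dG - min(dG)) / (max(dG) - min(dG)) over the qualifying sites, so the
#' most stable loop maps to 0 and the least stable to 1.  Sites not in a
#' loop, or with `delta_g >= 0`, score 1.  A degenerate range (all
#' qualifying energies equal) maps qualifying scores to 0 with a warning.
#'
#' @param delta_g numeric free energies (kcal/mol).
#' @param in_loop logical, same length.
#' @return numeric scores in \[0, 1\].
#' @export
normalised_loop_stability <- function(delta_g, in_loop) {
  stopifnot(length(delta_g) == length(in_loop))
  qual <- in_loop & delta_g < 0
  score <- rep(1, length(delta_g))
  if (!any(qual)) return(score)
  rng <- range(delta_g[qual])
  if (diff(rng) == 0) {
    warning("degenerate free-energy range; qualifying scores set to 0")
    score[qual] <- 0
    return(score)
  }
  score[qual] <- (delta_g[qual] - rng[1]) / (rng[2] - rng[1])
  score
}

#' Expression-matched null distribution of loop free energies
#'
#' Assesses how unusual the known passengers' hairpin stabilities are
#' among comparable background mutations.  The background pool is every
#' non-recurrent APOBEC-motif mutation whose gene's expression percentile
#' rank lies within `match_tol` of any known-passenger gene's rank
#' (controlling for expression as a confounder).  `n_draws` pool mutations
#' are sampled without replacement (seeded), their 25-nt windows folded,
#' and free energies recorded (0 when the site is not in a loop or dG > 0).
#' Each passenger's quantile location in that null is returned (fraction
#' of null draws with dG <= the passenger's dG; stable loops sit in the
#' lower tail).
#'
#' @param cohort a `cohort_table`.
#' @param ranks a gene rank table from [gapdh_percentile_rank()].
#' @param passengers data frame with columns `gene` and `delta_g`.
#' @param n_draws null size (sampled without replacement; the whole pool
#'   with a warning when smaller).
#' @param seed RNG seed for the draw.
#' @param exclude_genes genes to drop from the pool (e.g. hotspot genes).
#' @param match_tol rank-matching half-width (percentile points / 100).
#' @param allow_gt passed to [fold_mfe()].
#' @return list with `null_dg`, `quantiles` (one per passenger row).
#' @export
matched_null_quantiles <- function(cohort, ranks, passengers,
                                   n_draws = 1000, seed = 1,
                                   exclude_genes = NULL,
                                   match_tol = 0.01, allow_gt = FALSE) {
  tab <- recurrence_table(cohort)
  pool <- tab[tab$count == 1 & !is.na(tab$context25), , drop = FALSE]
  if (!is.null(exclude_genes)) {
    pool <- pool[!(pool$gene %in% exclude_genes), , drop = FALSE]
  }
  motif <- vapply(seq_len(nrow(pool)), function(i)
    annotate_apobec_motif(pool$context25[i], pool$ref[i],
                          pool$alt[i])$motif_class, character(1))
  pool <- pool[motif == "APOBEC_TCN", , drop = FALSE]
  p_ranks <- ranks$percentile[match(passengers$gene, ranks$gene)]
  if (any(is.na(p_ranks))) stop("passenger gene(s) missing from rank table")
  g_ranks <- ranks$percentile[match(pool$gene, ranks$gene)]
  matched <- !is.na(g_ranks) &
    vapply(g_ranks, function(r) any(abs(r - p_ranks) <= match_tol),
           logical(1))
  pool <- pool[matched, , drop = FALSE]
  if (nrow(pool) == 0) stop("empty expression-matched pool")
  if (nrow(pool) < n_draws) {
    warning("pool smaller than n_draws; using the whole pool (n = ",
            nrow(pool), ")")
    idx <- seq_len(nrow(pool))
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    idx <- sample.int(nrow(pool), n_draws)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  null_dg <- vapply(idx, function(i) {
    f <- fold_mfe(pool$context25[i], allow_gt = allow_gt)
    if (f$centre_in_loop && f$delta_g < 0) f$delta_g else 0
  }, numeric(1))
  q <- vapply(passengers$delta_g, function(dg) mean(null_dg <= dg),
              numeric(1))
  list(null_dg = null_dg, quantiles = q)
}
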