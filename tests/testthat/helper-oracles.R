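# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths: brute-force searches, exhaustive enumeration,
# direct formula arithmetic.

# --- recurrence threshold: exhaustive search over every integer ---------
oracle_threshold <- function(counts) {
  tab <- table(counts)
  vals <- as.integer(names(tab))
  for (t in 1:max(counts)) {
    num <- sum(tab[vals > t])
    den <- if (t %in% vals) tab[[as.character(t)]] else 0L
    if ((den == 0 && num > 0) || (den > 0 && num / den > 1)) return(t)
  }
  NA_integer_
}

# --- hairpin folding: enumerate every admissible structure --------------
# energy tables read directly from the shipped TSVs
.or_env <- new.env()
oracle_fold_tables <- function() {
  if (is.null(.or_env$stack)) {
    st <- read.delim(system.file("extdata", "dna_stack_dg37.tsv",
                                 package = "apohot"))
    .or_env$stack <- setNames(st$dg, st$dimer)
    .or_env$loops <- read.delim(system.file("extdata", "dna_loop_dg37.tsv",
                                            package = "apohot"))
  }
  list(stack = .or_env$stack, loops = .or_env$loops)
}

oracle_loop_pen <- function(type, size) {
  tabs <- oracle_fold_tables()$loops
  tab <- tabs[tabs$type == type, ]
  if (size < min(tab$size)) return(Inf)
  if (size > max(tab$size)) {
    return(tab$dg[which.max(tab$size)] + 1.5044 * log(size / max(tab$size)))
  }
  approx(tab$size, tab$dg, xout = size)$y
}

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "CG", "GC")
}

# all non-crossing pair sets with minimum hairpin separation 3, as lists
# of 2-column matrices (possibly empty)
enumerate_structures <- function(n) {
  rec <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), ncol = 2)))
    out <- rec(i + 1, j)                       # i unpaired
    for (k in (i + 4):j) {
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1]] <- rbind(c(i, k), a, b)
      }
    }
    out
  }
  rec(1, n)
}

# score a structure under the package's energy model; Inf if inadmissible
# (multiloop, non-complementary pair, hairpin loop < 3, loop > 30)
oracle_score <- function(s, pairs) {
  if (nrow(pairs) == 0) return(0)
  st <- oracle_fold_tables()$stack
  chars <- strsplit(s, "")[[1]]
  for (r in seq_len(nrow(pairs))) {
    if (!oracle_can_pair(chars[pairs[r, 1]], chars[pairs[r, 2]])) return(Inf)
  }
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # direct children: pairs strictly inside (i, j) not nested in another
    inside <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
    if (nrow(inside) > 0) {
      top <- rep(TRUE, nrow(inside))
      for (a in seq_len(nrow(inside))) {
        for (b in seq_len(nrow(inside))) {
          if (a != b && inside[b, 1] < inside[a, 1] &&
              inside[a, 2] < inside[b, 2]) top[a] <- FALSE
        }
      }
      children <- inside[top, , drop = FALSE]
    } else {
      children <- inside
    }
    if (nrow(children) == 0) {
      size <- j - i - 1
      if (size < 3) return(Inf)
      total <- total + oracle_loop_pen("hairpin", size)
    } else if (nrow(children) == 1) {
      k <- children[1, 1]; l <- children[1, 2]
      n1 <- k - i - 1; n2 <- j - l - 1
      if (n1 + n2 > 30) return(Inf)
      if (n1 == 0 && n2 == 0) {
        total <- total + unname(st[paste0(chars[i], chars[k])])
      } else if (n1 == 0 || n2 == 0) {
        total <- total + oracle_loop_pen("bulge", n1 + n2)
      } else {
        total <- total + oracle_loop_pen("internal", n1 + n2)
      }
    } else {
      return(Inf)  # multiloop: outside the model
    }
  }
  total
}

oracle_mfe <- function(s) {
  n <- nchar(s)
  structs <- enumerate_structures(n)
  best <- 0
  for (p in structs) {
    e <- oracle_score(s, p)
    if (e < best) best <- e
  }
  best
}

# --- exact hypergeometric two-sided p for a 2x2 table -------------------
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- exhaustive weighted 2-partition search (all 2^(n-1) splits) --------
oracle_two_cluster_wcss <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  wcss <- function(v, w) {
    if (length(v) == 0) return(0)
    mu <- sum(w * v) / sum(w)
    sum(w * (v - mu)^2)
  }
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    tot <- wcss(values[grp], weights[grp]) + wcss(values[!grp], weights[!grp])
    if (tot < best) best <- tot
  }
  best
}

# --- small simulation configs used throughout the suite -----------------
small_sim_config <- function(seed = 1, ...) {
  # 150-sample miniature of the default study conditions; planted carrier
  # baselines scaled up by 602/150 so expected carrier counts match
  ps <- default_planted_sites()
  ps$baseline <- ps$baseline * 4
  sim_config(n_samples = 150, mut_mean = 80, mut_size = 1.5,
             planted_sites = ps,
             tail_counts = c("2" = 75, "3" = 33, "4" = 5, "5" = 3),
             n_bg_genes = 400, n_expr_genes = 600, seed = seed, ...)
}
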