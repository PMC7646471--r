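#' Head/tail recurrence threshold for hotspot calling
#'
#' Per-mutation recurrence counts in an exome cohort follow a long-tail
#' distribution.  The hotspot threshold is the smallest integer `t` for
#' which the ratio N(count > t) / N(count = t) exceeds 1, separating the
#' recurrent "head" from the private "tail".  A zero denominator with a
#' positive numerator satisfies the rule (the ratio is effectively
#' infinite); search runs over 1..max(count).
#'
#' @param counts integer vector (or table) of per-mutation recurrence counts.
#' @return the threshold, an integer scalar.
#' @export
find_recurrence_threshold <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) == 0 || max(counts) < 2L) {
    stop("no recurrence threshold: no mutation recurs")
  }
  for (t in seq_len(max(counts))) {
    n_above <- sum(counts > t)
    n_at <- sum(counts == t)
    ok <- if (n_at == 0L) n_above > 0L else (n_above / n_at) > 1
    if (ok) return(t)
  }
  stop("no recurrence threshold satisfies the head/tail ratio rule")
}

#' Tally per-mutation recurrence
#'
#' @param cohort a `cohort_table`.
#' @return data frame keyed by (chrom, pos, ref, alt) with carrier counts,
#'   gene/protein annotation and carrier sample ids.
#' @export
recurrence_table <- function(cohort) {
  rec <- cohort$records
  key <- paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = ":")
  idx <- split(seq_len(nrow(rec)), key)
  out <- data.frame(
    key = names(idx),
    chrom = vapply(idx, function(i) rec$chrom[i[1]], character(1)),
    pos = vapply(idx, function(i) rec$pos[i[1]], integer(1)),
    ref = vapply(idx, function(i) rec$ref[i[1]], character(1)),
    alt = vapply(idx, function(i) rec$alt[i[1]], character(1)),
    gene = vapply(idx, function(i) rec$gene[i[1]], character(1)),
    protein_change = vapply(idx, function(i) rec$protein_change[i[1]],
                            character(1)),
    count = vapply(idx, function(i) length(unique(rec$sample[i])),
                   integer(1)),
    context25 = vapply(idx, function(i) {
      ctx <- rec$context25[i]
      ctx <- ctx[!is.na(ctx)]
      if (length(ctx) == 0) NA_character_ else ctx[1]
    }, character(1)),
    stringsAsFactors = FALSE
  )
  out$carriers <- lapply(idx, function(i) unique(rec$sample[i]))
  rownames(out) <- NULL
  out
}

#' Classify the APOBEC trinucleotide motif of a mutation
#'
#' Converts the plus-strand context to the pyrimidine strand
#' (reverse-complementing when the reference base is a purine) and calls
#' `APOBEC_TCN` iff the pyrimidine-strand change is C>G or C>T with a T
#' immediately 5' of the cytosine (TCN -> T\[G/T\]N).  The subclass reflects
#' the base 5' of that T: `YTCN` (C/T, the APOBEC3A-preferred tetramer) or
#' `RTCN` (A/G, APOBEC3B-preferred); it is `NA` when the window is too
#' short to see that base.
#'
#' @param context plus-strand window of odd length >= 3 centred on the site.
#' @param ref,alt plus-strand reference/alternate bases.
#' @return list with `motif_class` (`"APOBEC_TCN"` or `"other"`) and
#'   `subclass` (`"YTCN"`, `"RTCN"` or `NA`).
#' @export
annotate_apobec_motif <- function(context, ref, alt) {
  n <- nchar(context)
  if (n < 3L || n %% 2L == 0L) stop("context must have odd length >= 3")
  mid <- (n + 1L) %/% 2L
  if (substr(context, mid, mid) != ref) {
    stop("central base of context does not match ref")
  }
  if (ref %in% c("G", "A")) {
    context <- revcomp(context)
    ref <- unname(DNA_COMPLEMENT[ref])
    alt <- unname(DNA_COMPLEMENT[alt])
  }
  up1 <- substr(context, mid - 1L, mid - 1L)
  is_apobec <- ref == "C" && alt %in% c("G", "T") && up1 == "T"
  if (!is_apobec) {
    return(list(motif_class = "other", subclass = NA_character_))
  }
  if (mid - 2L < 1L) {
    return(list(motif_class = "APOBEC_TCN", subclass = NA_character_))
  }
  up2 <- substr(context, mid - 2L, mid - 2L)
  sub <- if (up2 %in% c("C", "T")) "YTCN"
         else if (up2 %in% c("A", "G")) "RTCN"
         else NA_character_
  list(motif_class = "APOBEC_TCN", subclass = sub)
}

#' Call hotspot mutations in a cohort
#'
#' Computes the recurrence threshold on the cohort's per-mutation counts,
#' keeps mutations at or above it, and annotates each with its APOBEC
#' motif class.  Ordering is deterministic: descending count, then genomic
#' key.
#'
#' @param cohort a `cohort_table`.
#' @return a `hotspot_panel` data frame (threshold stored as attribute).
#' @export
call_hotspots <- function(cohort) {
  if (nrow(cohort$records) == 0) stop("empty cohort")
  tab <- recurrence_table(cohort)
  thr <- find_recurrence_threshold(tab$count)
  hot <- tab[tab$count >= thr, , drop = FALSE]
  hot <- hot[order(-hot$count, hot$key), , drop = FALSE]
  motif <- lapply(seq_len(nrow(hot)), function(i) {
    ctx <- hot$context25[i]
    if (is.na(ctx)) {
      # no context: no motif call possible
      return(list(motif_class = "other", subclass = NA_character_))
    }
    annotate_apobec_motif(ctx, hot$ref[i], hot$alt[i])
  })
  hot$motif_class <- vapply(motif, `[[`, character(1), "motif_class")
  hot$subclass <- vapply(motif, `[[`, character(1), "subclass")
  hot$apobec_associated <- NA
  hot$association_p <- NA_real_
  rownames(hot) <- NULL
  attr(hot, "threshold") <- thr
  class(hot) <- c("hotspot_panel", class(hot))
  hot
}

#' Read a hotspot panel fixture (gene, protein_change, count TSV)
#' @param path TSV path.
#' @return data frame.
#' @export
read_hotspot_panel <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
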