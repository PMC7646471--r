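#' Canonical 96-channel trinucleotide mutation classes
#'
#' Channels follow the standard ordering used for mutational signature
#' catalogues: the six pyrimidine-strand substitutions (C>A, C>G, C>T,
#' T>A, T>C, T>G), each expanded over the 16 flanking-base contexts in
#' lexicographic order, e.g. `"A[C>A]A"`, `"A[C>A]C"`, ..., `"T[T>G]T"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (b5 in bases) {
      for (b3 in bases) {
        out <- c(out, paste0(b5, "[", s, "]", b3))
      }
    }
  }
  out
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, uppercase).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(DNA_COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Map a mutation with trinucleotide context to its 96-channel class
#'
#' The context is given on the plus strand; mutations at purine reference
#' bases are reverse-complemented onto the pyrimidine strand.
#'
#' @param ref,alt single reference/alternate bases (plus strand).
#' @param up,down single flanking bases 5' and 3' of the site (plus strand).
#' @return channel label, or `NA_character_` if any base is ambiguous.
#' @export
channel_of <- function(ref, alt, up, down) {
  stopifnot(length(ref) == length(alt), length(up) == length(ref),
            length(down) == length(ref))
  out <- character(length(ref))
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; u <- up[i]; d <- down[i]
    if (any(!c(r, a, u, d) %in% c("A", "C", "G", "T"))) {
      out[i] <- NA_character_
      next
    }
    if (r %in% c("G", "A")) {
      r <- unname(DNA_COMPLEMENT[r]); a <- unname(DNA_COMPLEMENT[a])
      tmp <- u
      u <- unname(DNA_COMPLEMENT[d]); d <- unname(DNA_COMPLEMENT[tmp])
    }
    out[i] <- paste0(u, "[", r, ">", a, "]", d)
  }
  out
}

#' Extract the 96-channel class of an SNV record from its context window
#'
#' @param context odd-length plus-strand window centred on the mutated base.
#' @param ref,alt plus-strand reference and alternate bases.
#' @return channel label or `NA_character_`.
#' @export
channel_from_context <- function(context, ref, alt) {
  n <- nchar(context)
  if (is.na(context) || n < 3L || n %% 2L == 0L) return(NA_character_)
  mid <- (n + 1L) %/% 2L
  if (substr(context, mid, mid) != ref) {
    stop("context centre does not match ref base")
  }
  channel_of(ref, alt,
             substr(context, mid - 1L, mid - 1L),
             substr(context, mid + 1L, mid + 1L))
}
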