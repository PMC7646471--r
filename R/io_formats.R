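#' @importFrom utils read.delim write.table
NULL

REQUIRED_SNV_COLS <- c("patient", "sample", "chrom", "pos", "ref", "alt", "gene")

new_cohort_table <- function(records) {
  records$pos <- as.integer(records$pos)
  structure(list(records = records,
                 n_samples = length(unique(records$sample))),
            class = "cohort_table")
}

#' @exportS3Method base::print
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$records), " SNVs in ", x$n_samples,
      " samples (", length(unique(x$records$patient)), " patients)\n", sep = "")
  invisible(x)
}

#' Keep one sample per patient
#'
#' Cohorts assembled from time series or multi-site sampling carry several
#' samples per patient; recurrence counting assumes one.  The lexicographically
#' smallest `sample` id is retained per patient (a deterministic rule).
#'
#' @param records SNV data frame with `patient` and `sample` columns.
#' @return data frame restricted to the retained samples.
#' @export
dedup_samples <- function(records) {
  keep <- tapply(records$sample, records$patient,
                 function(s) sort(unique(s))[1])
  records[records$sample %in% unname(keep), , drop = FALSE]
}

#' Read a cohort SNV table
#'
#' Expects a TSV with header columns `patient, sample, chrom, pos, ref, alt,
#' gene` and optional `protein_change`, `context25` (25-base plus-strand
#' window centred on the site) and `clonality` (`clonal`/`subclonal`/
#' `unknown`).  One sample is retained per patient.  When `fasta` is given
#' and `context25` is absent, contexts are extracted from the reference
#' (+/- 12 nt).  Records whose stored context centre disagrees with `ref`
#' are dropped with a warning; records with ambiguous bases within +/-2 nt
#' of the centre are flagged in the `flagged_ambiguous` column.
#'
#' @param path TSV file path.
#' @param fasta optional FASTA path for context extraction.
#' @return a `cohort_table`.
#' @export
read_snv_table <- function(path, fasta = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(REQUIRED_SNV_COLS, names(df))
  if (length(missing) > 0) {
    stop("SNV table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  if (!"protein_change" %in% names(df)) df$protein_change <- NA_character_
  if (!"context25" %in% names(df)) df$context25 <- NA_character_
  if (!"clonality" %in% names(df)) df$clonality <- NA_character_
  for (col in c("protein_change", "context25", "clonality")) {
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  validate_snv_records(df, fasta = fasta)
}

validate_snv_records <- function(df, fasta = NULL) {
  bad <- df$ref == df$alt | !(df$ref %in% c("A", "C", "G", "T")) |
    !(df$alt %in% c("A", "C", "G", "T")) | df$pos < 1L
  if (any(bad)) {
    warning(sum(bad), " record(s) dropped: invalid ref/alt/pos")
    df <- df[!bad, , drop = FALSE]
  }
  df <- dedup_samples(df)
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    need <- is.na(df$context25)
    for (i in which(need)) {
      chrom <- df$chrom[i]
      if (!chrom %in% names(seqs)) next
      s <- seqs[[chrom]]
      p <- df$pos[i]
      if (p - 12L >= 1L && p + 12L <= nchar(s)) {
        df$context25[i] <- toupper(substr(s, p - 12L, p + 12L))
      }
    }
  }
  has_ctx <- !is.na(df$context25)
  mism <- has_ctx &
    substr(df$context25, 13L, 13L) != df$ref
  if (any(mism)) {
    warning(sum(mism), " record(s) dropped: context centre != ref")
    df <- df[!mism, , drop = FALSE]
  }
  ctx <- df$context25
  core <- ifelse(is.na(ctx), NA_character_, substr(ctx, 11L, 15L))
  df$flagged_ambiguous <- !is.na(core) & grepl("[^ACGT]", core)
  new_cohort_table(df)
}

#' Write a cohort table back to TSV
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @export
write_snv_table <- function(cohort, path) {
  out <- cohort$records
  out$flagged_ambiguous <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Minimal FASTA reader
#' @param path FASTA file path.
#' @return named character vector/list of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- tapply(lines[!hdr], grp[!hdr], paste, collapse = "")
  out <- as.list(toupper(unname(seqs)))
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#' @param seqs named character vector or list of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), as.character(seqs[[nm]])), con)
  }
  invisible(path)
}

#' Read a replication fork directionality (RFD) track
#'
#' bedGraph input: `chrom  start  end  value`, 0-based half-open, values in
#' \[-1, 1\].  Positive values mark regions where the Watson strand is
#' replicated mostly as the lagging-strand template; negative values mark
#' Crick.  Unsorted input is sorted; overlapping intervals are an error.
#'
#' @param path bedGraph file path.
#' @param cell_line label for the track.
#' @return an `rfd_track`.
#' @export
read_rfd_bedgraph <- function(path, cell_line) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "rfd"))
  new_rfd_track(df, cell_line)
}

new_rfd_track <- function(df, cell_line) {
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$rfd <- as.numeric(df$rfd)
  if (any(!is.finite(df$rfd)) || any(df$rfd < -1 | df$rfd > 1)) {
    stop("RFD values must be finite and within [-1, 1]")
  }
  if (any(df$end <= df$start)) stop("RFD intervals must have end > start")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping RFD intervals on ", ch)
    }
  }
  rownames(df) <- NULL
  structure(list(cell_line = cell_line, intervals = df), class = "rfd_track")
}

#' Write an RFD track as bedGraph
#' @param track an `rfd_track`.
#' @param path output path.
#' @export
write_rfd_bedgraph <- function(track, path) {
  write.table(track$intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Look up the RFD value covering a 1-based position
#' @param track an `rfd_track`.
#' @param chrom,pos 1-based genomic position.
#' @return RFD value or `NA` when uncovered.
#' @export
rfd_at <- function(track, chrom, pos) {
  iv <- track$intervals
  # half-open 0-based [start, end) covers 1-based pos iff start < pos <= end
  hit <- iv$chrom == chrom & iv$start < pos & pos <= iv$end
  if (!any(hit)) return(NA_real_)
  iv$rfd[which(hit)[1]]
}

#' Read a gene x sample expression matrix
#'
#' TSV with gene symbols in the first column; remaining columns one per
#' sample.  Values must be non-negative; duplicate gene symbols are an error.
#'
#' @param path TSV file path.
#' @param units free-text tag (`"normalised"` or `"counts"`).
#' @return numeric matrix (genes x samples) with a `units` attribute.
#' @export
read_expression_matrix <- function(path, units = "normalised") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("expression values must be finite and non-negative")
  }
  attr(m, "units") <- units
  m
}

#' Write an expression (or any gene x sample) matrix as TSV
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param id_col header for the identifier column.
#' @export
write_expression_matrix <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature reference matrix
#'
#' TSV with signature ids in the first column and the 96 channel labels as
#' remaining headers.  Rows are probability profiles: any row whose sum
#' deviates from 1 by more than `tol` but is positive is renormalised with a
#' warning; non-positive rows are an error.  Columns are reordered to the
#' canonical channel order.
#'
#' @param path TSV file path.
#' @param tol tolerance on row sums before renormalising.
#' @return numeric matrix (signatures x 96), class `signature_matrix`.
#' @export
read_signature_reference <- function(path, tol = 1e-6) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  chans <- sbs96_channels()
  if (!setequal(colnames(m), chans) || ncol(m) != 96L) {
    stop("signature reference must have exactly the 96 canonical channels")
  }
  m <- m[, chans, drop = FALSE]
  if (any(m < 0)) stop("negative signature probabilities")
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("signature row with zero total probability")
  off <- abs(rs - 1) > tol
  if (any(off)) {
    warning(sum(off), " signature row(s) renormalised to sum 1")
  }
  m <- m / rs
  class(m) <- c("signature_matrix", class(m))
  m
}

#' Write a signature matrix as TSV
#' @param sigs signature matrix (signatures x 96).
#' @param path output path.
#' @export
write_signature_reference <- function(sigs, path) {
  df <- data.frame(signature = rownames(sigs), unclass(sigs),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
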