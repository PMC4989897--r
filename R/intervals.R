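#' Construct a table of genomic intervals
#'
#' Intervals are the atom of all overlap logic in the package. They are kept
#' as plain data frames with columns `chrom`, `start`, `end`, `name`,
#' `strand`, using 0-based half-open coordinates (BED convention)
#' everywhere internally: an interval covers base positions
#' `start, ..., end - 1`.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer-valued vector, 0-based inclusive start.
#' @param end Integer-valued vector, exclusive end; must satisfy
#'   `0 <= start < end`.
#' @param name Optional identifiers (recycled `"."` if missing).
#' @param strand One of `"+"`, `"-"`, `"."` per interval.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`.
#' @export
gintervals <- function(chrom, start, end, name = ".", strand = ".") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (n == 0L) {
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), name = character(0),
                     strand = character(0), stringsAsFactors = FALSE)
    return(df)
  }
  df <- data.frame(
    chrom = rep_len(chrom, n), start = rep_len(start, n),
    end = rep_len(end, n),
    name = rep_len(as.character(name), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end`, non-empty chromosome names, integral
#' coordinates and legal strand codes. Called by every reader/constructor.
#'
#' @param x Interval data frame.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop(what, ": chromosome names must be non-empty")
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)) ||
      any(x$start != floor(x$start)) || any(x$end != floor(x$end)))
    stop(what, ": coordinates must be finite integers")
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(what, ": invalid coordinates (need 0 <= start < end) at row ",
         bad[1L])
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'")
  invisible(x)
}

#' Pairwise interval overlap
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least one base under half-open coordinates:
#' `a$start < b$end && b$start < a$end`.
#'
#' @param a,b Single-row interval data frames (or lists with `chrom`,
#'   `start`, `end`).
#' @return Logical scalar.
#' @export
overlaps <- function(a, b) {
  isTRUE(a$chrom[1L] == b$chrom[1L] &&
           a$start[1L] < b$end[1L] && b$start[1L] < a$end[1L])
}

#' Flag queries that overlap at least one subject
#'
#' The workhorse behind every "overlaps with" rule in the classification
#' cascade. Backed by an interval-tree lookup; the contract is the
#' brute-force all-pairs answer (>= 1 shared bp, same chromosome).
#'
#' @param queries,subjects Interval data frames.
#' @return Logical vector, one flag per query row.
#' @export
intersect_flags <- function(queries, subjects) {
  validate_intervals(queries, "query")
  validate_intervals(subjects, "subject")
  n <- nrow(queries)
  if (n == 0L) return(logical(0))
  if (nrow(subjects) == 0L) return(rep(FALSE, n))
  out <- rep(FALSE, n)
  q_split <- split(seq_len(n), queries$chrom)
  s_split <- split(seq_len(nrow(subjects)), subjects$chrom)
  for (chr in intersect(names(q_split), names(s_split))) {
    qi <- q_split[[chr]]
    si <- s_split[[chr]]
    qr <- IRanges::IRanges(queries$start[qi] + 1, queries$end[qi])
    sr <- IRanges::IRanges(subjects$start[si] + 1, subjects$end[si])
    out[qi] <- IRanges::countOverlaps(qr, sr) > 0L
  }
  out
}

#' Count overlapping subjects per query
#'
#' @inheritParams intersect_flags
#' @return Integer vector of overlap counts per query row.
#' @export
intersect_counts <- function(queries, subjects) {
  validate_intervals(queries, "query")
  validate_intervals(subjects, "subject")
  n <- nrow(queries)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  if (nrow(subjects) == 0L) return(out)
  q_split <- split(seq_len(n), queries$chrom)
  s_split <- split(seq_len(nrow(subjects)), subjects$chrom)
  for (chr in intersect(names(q_split), names(s_split))) {
    qi <- q_split[[chr]]
    si <- s_split[[chr]]
    qr <- IRanges::IRanges(queries$start[qi] + 1, queries$end[qi])
    sr <- IRanges::IRanges(subjects$start[si] + 1, subjects$end[si])
    out[qi] <- IRanges::countOverlaps(qr, sr)
  }
  out
}

# Internal: all overlapping (query, subject) row pairs, as a 2-column matrix.
.overlap_pairs <- function(queries, subjects) {
  if (nrow(queries) == 0L || nrow(subjects) == 0L)
    return(cbind(query = integer(0), subject = integer(0)))
  q_split <- split(seq_len(nrow(queries)), queries$chrom)
  s_split <- split(seq_len(nrow(subjects)), subjects$chrom)
  res <- list()
  for (chr in intersect(names(q_split), names(s_split))) {
    qi <- q_split[[chr]]
    si <- s_split[[chr]]
    qr <- IRanges::IRanges(queries$start[qi] + 1, queries$end[qi])
    sr <- IRanges::IRanges(subjects$start[si] + 1, subjects$end[si])
    hits <- IRanges::findOverlaps(qr, sr)
    res[[chr]] <- cbind(query = qi[S4Vectors::queryHits(hits)],
                        subject = si[S4Vectors::subjectHits(hits)])
  }
  if (!length(res)) return(cbind(query = integer(0), subject = integer(0)))
  do.call(rbind, res)
}

#' Promoter window around a strand-aware TSS
#'
#' Returns the symmetric window `[tss - flank, tss + flank + 1)` around each
#' gene's transcription start site, clipped at position 0. The window covers
#' every base within `flank` bp of the TSS on either side.
#'
#' @param genes Gene table as returned by [read_gene_table()] (columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `coding`, `tss`).
#' @param flank Positive flank size in bp (default 1000).
#' @return Interval data frame, one window per gene, `name` = `gene_id`.
#' @export
promoter_window <- function(genes, flank = 1000) {
  stopifnot(flank > 0)
  if (nrow(genes) == 0L)
    return(gintervals(character(0), numeric(0), numeric(0)))
  gintervals(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - flank),
    end = genes$tss + flank + 1,
    name = genes$gene_id,
    strand = genes$strand
  )
}

#' Nearest gene by TSS-to-midpoint distance
#'
#' Assigns each region the gene whose TSS is closest to the region midpoint
#' `floor((start + end) / 2)`, considering only genes on the same
#' chromosome. Ties break to the smaller TSS coordinate, then to the
#' lexicographically smaller `gene_id`. Regions on a chromosome with no
#' gene are assigned the sentinel `"unassigned"`.
#'
#' @param regions Interval data frame.
#' @param genes Gene table with `chrom`, `tss`, `gene_id`.
#' @return Character vector of gene ids, one per region row.
#' @export
nearest_gene <- function(regions, genes) {
  validate_intervals(regions, "region")
  n <- nrow(regions)
  if (n == 0L) return(character(0))
  out <- rep("unassigned", n)
  mid <- floor((regions$start + regions$end) / 2)
  g_split <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(n)) {
    gi <- g_split[[regions$chrom[i]]]
    if (is.null(gi) || !length(gi)) next
    d <- abs(genes$tss[gi] - mid[i])
    ord <- order(d, genes$tss[gi], genes$gene_id[gi])
    out[i] <- genes$gene_id[gi[ord[1L]]]
  }
  out
}
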