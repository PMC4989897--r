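# File I/O for the plain-text formats the workflow exchanges: BED3/BED6,
# bedGraph, refGene-style gene tables, BEDPE-like interaction links, per-CpG
# beta tables, RPKM expression tables and one-id-per-line gene lists. All
# tab-separated; '#'-prefixed comment lines skipped; coordinates 0-based
# half-open on disk and in memory.

.read_tsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

.num_or_stop <- function(x, path, lineno, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad))
    stop("parse error in ", path, " line ", lineno[bad[1L]],
         ": non-numeric ", what, " '", x[bad[1L]], "'")
  out
}

#' Read a BED3/BED6 file
#'
#' Columns: chrom, start, end, then optionally name (4), score (5, ignored)
#' and strand (6). Malformed coordinates (non-integer, or start >= end)
#' raise a parse error naming the offending line.
#'
#' @param path File path.
#' @return Interval data frame (see [gintervals()]).
#' @export
read_bed <- function(path) {
  tsv <- .read_tsv(path, "BED")
  if (!length(tsv$lines))
    return(gintervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(tsv$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop("parse error in ", path, " line ", tsv$lineno[which(ncol < 3L)[1L]],
         ": fewer than 3 tab-separated columns")
  m <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- .num_or_stop(m(2L), path, tsv$lineno, "start")
  end <- .num_or_stop(m(3L), path, tsv$lineno, "end")
  bad <- which(start != floor(start) | end != floor(end) |
                 start < 0 | start >= end)
  if (length(bad))
    stop("parse error in ", path, " line ", tsv$lineno[bad[1L]],
         ": invalid interval [", start[bad[1L]], ", ", end[bad[1L]], ")")
  name <- m(4L); name[is.na(name)] <- "."
  strand <- m(6L); strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "."
  gintervals(m(1L), start, end, name = name, strand = strand)
}

#' Write intervals as BED6
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @param extra Optional data frame of extra columns appended after strand.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = NULL) {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) x$name else "."
  strand <- if ("strand" %in% names(x)) x$strand else "."
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   name, 0L, strand, stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Four columns: chrom, start, end, value. Segments must be non-overlapping
#' within a chromosome; bases not covered by any segment have value 0.
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  tsv <- .read_tsv(path, "bedGraph")
  if (!length(tsv$lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  fields <- strsplit(tsv$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("parse error in ", path, ": bedGraph needs 4 columns")
  m <- function(i) vapply(fields, `[`, "", i)
  out <- data.frame(
    chrom = m(1L),
    start = .num_or_stop(m(2L), path, tsv$lineno, "start"),
    end = .num_or_stop(m(3L), path, tsv$lineno, "end"),
    value = .num_or_stop(m(4L), path, tsv$lineno, "value"),
    stringsAsFactors = FALSE
  )
  validate_intervals(out, "bedGraph")
  out
}

#' Write a bedGraph coverage track
#' @param x Data frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE), x$value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a refGene-style gene table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `strand`, `start`, `end`,
#' `coding` (TRUE for protein-coding "NM" entries). The strand-aware TSS is
#' derived: `start` on `+`, `end - 1` on `-`.
#'
#' @param path File path.
#' @return Gene data frame with an added `tss` column.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "chrom", "strand", "start", "end", "coding")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  df$coding <- as.logical(df$coding)
  make_gene_table(df$gene_id, df$chrom, df$strand, df$start, df$end, df$coding)
}

#' Construct a gene table with derived TSS
#'
#' @param gene_id,chrom,strand,start,end,coding Per-gene fields; `strand`
#'   must be `+` or `-`; coordinates 0-based half-open.
#' @return Gene data frame with `tss` column (`start` if `+`, `end - 1`
#'   if `-`), so that the TSS always lies within `[start, end)`.
#' @export
make_gene_table <- function(gene_id, chrom, strand, start, end, coding) {
  stopifnot(all(strand %in% c("+", "-")))
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand), start = as.numeric(start),
                   end = as.numeric(end), coding = as.logical(coding),
                   stringsAsFactors = FALSE)
  validate_intervals(df, "gene")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df
}

#' Write a gene table
#' @param genes Gene data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(
    genes[, c("gene_id", "chrom", "strand", "start", "end", "coding")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BEDPE-like chromatin interaction links
#'
#' Seven tab-separated columns with header: chrom1, start1, end1, chrom2,
#' start2, end2, tag_count. Links are undirected; anchors carry no strand.
#'
#' @param path File path.
#' @return Link data frame (see [make_links()]).
#' @export
read_links <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "tag_count")
  if (!all(need %in% names(df)))
    stop("link table must have columns: ", paste(need, collapse = ", "))
  make_links(df$chrom1, df$start1, df$end1, df$chrom2, df$start2, df$end2,
             df$tag_count)
}

#' Construct a link table
#' @param chrom1,start1,end1 First anchor coordinates.
#' @param chrom2,start2,end2 Second anchor coordinates.
#' @param tag_count Integer tag counts, all >= 1.
#' @return Data frame with the seven link columns.
#' @export
make_links <- function(chrom1, start1, end1, chrom2, start2, end2, tag_count) {
  df <- data.frame(chrom1 = as.character(chrom1), start1 = as.numeric(start1),
                   end1 = as.numeric(end1), chrom2 = as.character(chrom2),
                   start2 = as.numeric(start2), end2 = as.numeric(end2),
                   tag_count = as.numeric(tag_count), stringsAsFactors = FALSE)
  validate_intervals(data.frame(chrom = df$chrom1, start = df$start1,
                                end = df$end1), "link anchor1")
  validate_intervals(data.frame(chrom = df$chrom2, start = df$start2,
                                end = df$end2), "link anchor2")
  if (nrow(df) && any(df$tag_count < 1 | df$tag_count != floor(df$tag_count)))
    stop("tag_count must be an integer >= 1")
  df
}

#' Write a link table
#' @param links Link data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  utils::write.table(links, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-CpG beta-value table
#'
#' Tab-separated with header: `chrom`, `position` (0-based coordinate of the
#' C of the CpG), `beta` in \[0, 1\] (NA allowed; dropped downstream).
#'
#' @param path File path.
#' @return Data frame with `chrom`, `position`, `beta`.
#' @export
read_beta_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("chrom", "position", "beta") %in% names(df)))
    stop("beta table must have columns: chrom, position, beta")
  ok <- is.na(df$beta) | (df$beta >= 0 & df$beta <= 1)
  if (!all(ok))
    stop("beta outside [0,1] at ", df$chrom[!ok][1L], ":",
         df$position[!ok][1L])
  df
}

#' Write a beta table
#' @param x Data frame with `chrom`, `position`, `beta`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_table <- function(x, path) {
  utils::write.table(x[, c("chrom", "position", "beta")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene expression table (RPKM)
#' @param path Tab-separated file with header columns `gene_id`, `rpkm`.
#' @return Named numeric vector of RPKM keyed by gene id.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene_id", "rpkm") %in% names(df)))
    stop("expression table must have columns: gene_id, rpkm")
  if (any(df$rpkm < 0, na.rm = TRUE)) stop("negative RPKM in ", path)
  stats::setNames(df$rpkm, df$gene_id)
}

#' Write an expression table
#' @param rpkm Named numeric vector keyed by gene id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(rpkm, path) {
  utils::write.table(data.frame(gene_id = names(rpkm), rpkm = unname(rpkm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line, '#' comments)
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^#", lines)])
  lines[nzchar(lines)]
}

#' Write a gene list
#' @param ids Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
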