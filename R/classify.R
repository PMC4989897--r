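# CGI classification: partition a CpG-island catalogue into promoter CGIs
# (pCGI), noncoding-promoter CGIs (npCGI), enhancer CGIs (eCGI) and inactive
# orphans, and call typical enhancers from the peak tracks.

# Internal: expand TSS-evidence intervals (CAGE or de-novo transcript TSS)
# into promoter-like windows. De-novo TSSs get the same +/- flank window as
# annotated gene promoters; CAGE intervals are used as given.
.tss_windows <- function(tss, flank) {
  if (is.null(tss) || nrow(tss) == 0L)
    return(gintervals(character(0), numeric(0), numeric(0)))
  gintervals(tss$chrom, pmax(0, tss$start - flank), tss$end + flank,
             name = tss$name)
}

#' Classify CpG islands
#'
#' Applies the decision cascade, in order:
#' 1. overlaps any coding-gene promoter window (TSS +/- `flank`) -> `pCGI`;
#' 2. else, if it does NOT overlap both an H3K27ac peak and a DHS peak ->
#'    `orphan_inactive` (not an active orphan);
#' 3. else, if it overlaps any CAGE TSS or any de-novo transcript TSS
#'    window -> `npCGI` (active orphan producing noncoding transcripts);
#' 4. else -> `eCGI` (active orphan with no transcription-start evidence:
#'    an enhancer CpG island).
#'
#' Every input CGI receives exactly one label.
#'
#' @param cgis Interval data frame of CpG islands (`name` used as `cgi_id`;
#'   rows with `name == "."` get ids `cgi_1`, `cgi_2`, ...).
#' @param genes Gene table ([make_gene_table()]); only `coding` genes define
#'   promoter CGIs.
#' @param h3k27ac_peaks,dhs_peaks Peak interval data frames (required).
#' @param cage_tss CAGE-derived TSS intervals (used as given).
#' @param denovo_tss De-novo transcript TSS intervals (expanded by
#'   +/- `flank`).
#' @param flank Promoter window half-width in bp (default 1000).
#' @return The `cgis` data frame with added columns `cgi_id`, `label`
#'   (factor over the four classes) and `length`.
#' @export
classify_cgis <- function(cgis, genes, h3k27ac_peaks, dhs_peaks,
                          cage_tss, denovo_tss, flank = 1000) {
  for (nm in c("h3k27ac_peaks", "dhs_peaks")) {
    if (is.null(get(nm)))
      stop("missing required track: ", sub("_peaks", "", nm))
  }
  validate_intervals(cgis, "CGI")
  out <- cgis
  out$cgi_id <- if ("name" %in% names(cgis)) cgis$name else "."
  anon <- out$cgi_id == "." | is.na(out$cgi_id)
  out$cgi_id[anon] <- paste0("cgi_", which(anon))
  out$length <- out$end - out$start
  n <- nrow(out)
  lvls <- c("pCGI", "npCGI", "eCGI", "orphan_inactive")
  if (n == 0L) {
    out$label <- factor(character(0), levels = lvls)
    return(out)
  }
  prom <- promoter_window(genes[genes$coding, , drop = FALSE], flank)
  is_prom <- intersect_flags(out, prom)
  active <- intersect_flags(out, h3k27ac_peaks) & intersect_flags(out, dhs_peaks)
  tss_ev <- intersect_flags(out, cage_tss) |
    intersect_flags(out, .tss_windows(denovo_tss, flank))
  label <- ifelse(is_prom, "pCGI",
                  ifelse(!active, "orphan_inactive",
                         ifelse(tss_ev, "npCGI", "eCGI")))
  out$label <- factor(label, levels = lvls)
  out
}

#' Call typical enhancers
#'
#' Typical enhancers are H3K27ac-harboring DHS peaks that overlap no CpG
#' island and no transcription-start evidence. Anchored on the DHS peak
#' coordinates: every DHS peak overlapping at least one H3K27ac peak is a
#' candidate, then candidates overlapping any CAGE TSS, any de-novo
#' transcript TSS window (+/- `flank`), or any CGI are removed.
#'
#' @inheritParams classify_cgis
#' @return Interval data frame of retained DHS peaks with a
#'   `source_peak_id` column.
#' @export
call_typical_enhancers <- function(h3k27ac_peaks, dhs_peaks, cage_tss,
                                   denovo_tss, cgis, flank = 1000) {
  validate_intervals(dhs_peaks, "DHS peak")
  keep <- intersect_flags(dhs_peaks, h3k27ac_peaks) &
    !intersect_flags(dhs_peaks, cage_tss) &
    !intersect_flags(dhs_peaks, .tss_windows(denovo_tss, flank)) &
    !intersect_flags(dhs_peaks, cgis)
  out <- dhs_peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  ids <- if ("name" %in% names(out)) out$name else rep(".", nrow(out))
  anon <- ids == "." | is.na(ids)
  ids[anon] <- paste0("dhs_", which(keep)[anon])
  out$source_peak_id <- ids
  out
}

#' Sequence composition statistics of a CpG island
#'
#' Computes length, GC percentage and the Gardiner-Garden observed/expected
#' CpG ratio `(#CpG * L) / (#C * #G)` with `L` the effective (non-N)
#' length. `N` bases are excluded from all counts; a zero C or G count
#' yields ratio 0.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @return List with `length` (bp, including N), `gc_percent` and
#'   `cpg_obs_exp`.
#' @export
sequence_stats <- function(sequence) {
  sequence <- toupper(as.character(sequence)[1L])
  if (is.na(sequence) || !nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over {A,C,G,T,N}")
  eff <- sum(chars != "N")
  n_c <- sum(chars == "C")
  n_g <- sum(chars == "G")
  n_cpg <- sum(chars[-length(chars)] == "C" & chars[-1L] == "G")
  gc <- if (eff > 0) 100 * (n_c + n_g) / eff else 0
  ratio <- if (n_c > 0 && n_g > 0) (n_cpg * eff) / (n_c * n_g) else 0
  list(length = length(chars), gc_percent = gc, cpg_obs_exp = ratio)
}

#' Cell-type-specific and common region sets
#'
#' Splits two same-catalogue region id sets (e.g. the eCGIs of two cell
#' lines) into A-specific, B-specific and common ids, with specificity
#' percentages computed within each cell line:
#' `a_specific_pct = 100 * |A-specific| / (|A-specific| + |common|)`.
#'
#' @param ids_a,ids_b Character vectors of region ids (duplicates are an
#'   error), or data frames with a `cgi_id` column.
#' @return List with `a_specific`, `b_specific`, `common` (character
#'   vectors) and `a_specific_pct`, `b_specific_pct`.
#' @export
cell_specific_sets <- function(ids_a, ids_b) {
  pick <- function(x) if (is.data.frame(x)) x$cgi_id else as.character(x)
  a <- pick(ids_a)
  b <- pick(ids_b)
  if (anyDuplicated(a)) stop("duplicate cgi_id in set A")
  if (anyDuplicated(b)) stop("duplicate cgi_id in set B")
  common <- intersect(a, b)
  a_spec <- setdiff(a, b)
  b_spec <- setdiff(b, a)
  pct <- function(spec) {
    tot <- length(spec) + length(common)
    if (tot == 0) 0 else 100 * length(spec) / tot
  }
  list(a_specific = a_spec, b_specific = b_spec, common = common,
       a_specific_pct = pct(a_spec), b_specific_pct = pct(b_spec))
}
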