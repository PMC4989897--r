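# Synthetic epigenome generator with planted ground truth. Emits every
# layer the workflow consumes — genes, CGI catalogue, H3K27ac/DHS peaks,
# CAGE and de-novo TSS evidence, coverage tracks, ChIA-PET links,
# normal/tumor methylation betas, expression tables, gene category lists —
# mutually consistent with planted class labels, eCGI->gene links, tumor
# hypermethylation and target silencing.
#
# Placement uses disjoint 30-kb cells per chromosome, one feature per cell
# (promoter CGIs share their gene's cell). Features sit in the central
# third of their cell, so any two features on a chromosome are > 9 kb
# apart: planted classes are identifiable by construction when noise-free.

#' Synthetic dataset configuration
#'
#' Defaults encode the study conditions the workflow is designed around: a
#' 3 x 10 Mb toy genome, ~half of CGIs at coding promoters, an
#' active-orphan compartment split into noncoding-promoter and enhancer
#' CGIs, 60% multi-target eCGIs, a 3-fold regulator preference of eCGI
#' links, interaction tag counts shifted +2 over typical enhancers, 30
#' hypermethylated eCGIs with planted dm 0.6 (CpG noise sd 0.05), 3-fold
#' silencing of their targets, and a 3-fold tumor-suppressor preference
#' among silenced genes.
#'
#' @param seed Integer seed (drives every random choice).
#' @param chrom_sizes Named chromosome lengths in bp.
#' @param n_genes,n_cgis,n_typical Feature counts.
#' @param class_mix Proportions over pCGI/npCGI/eCGI/orphan_inactive,
#'   summing to 1; converted to counts by largest remainder.
#' @param frac_coding Fraction of genes with protein-coding ("NM") ids.
#' @param frac_multi_target Fraction of eCGIs with >= 2 targets.
#' @param regulator_enrichment Multiplicative sampling preference of eCGI
#'   links for regulator genes (1 = none).
#' @param frac_regulators Fraction of coding genes labeled transcription
#'   regulators.
#' @param n_hyper_ecgis Number of eCGIs planted as tumor-hypermethylated.
#' @param planted_dm Beta increase planted at hyper-eCGI CpGs.
#' @param dm_noise_sd Per-CpG noise sd on the tumor beta.
#' @param silencing_fold Expression fold by which hyper-eCGI targets drop.
#' @param peak_dropout Probability that a required eCGI/npCGI peak is
#'   omitted (classification noise).
#' @param tag_count_shift Added tag count on eCGI links vs typical-enhancer
#'   links.
#' @param frac_tsg,frac_oncogene Fractions of coding genes in each list.
#' @param tsg_enrichment Sampling preference of the TSG list for silenced
#'   genes.
#' @param cpgs_per_cgi CpGs planted inside each CGI.
#' @param background_cpg_rate Background CpG density per bp outside CGIs.
#' @param expr_noise_sd_log2 Log2-sd of multiplicative expression noise.
#' @param flank Promoter half-width used when planting pCGIs and link
#'   anchors (default 1000).
#' @return Config list (class `synth_config`).
#' @export
synth_config <- function(seed = 1,
                         chrom_sizes = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                         n_genes = 300, n_cgis = 500, n_typical = 150,
                         class_mix = c(pCGI = 0.5, npCGI = 0.15,
                                       eCGI = 0.2, orphan_inactive = 0.15),
                         frac_coding = 0.85, frac_multi_target = 0.6,
                         regulator_enrichment = 3, frac_regulators = 0.2,
                         n_hyper_ecgis = 30, planted_dm = 0.6,
                         dm_noise_sd = 0.05, silencing_fold = 3,
                         peak_dropout = 0, tag_count_shift = 2,
                         frac_tsg = 0.1, frac_oncogene = 0.1,
                         tsg_enrichment = 3, cpgs_per_cgi = 25,
                         background_cpg_rate = 0.01,
                         expr_noise_sd_log2 = 0.3, flank = 1000) {
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1")
  if (any(class_mix < 0 | class_mix > 1))
    stop("class_mix proportions must lie in [0,1]")
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# Largest-remainder apportionment of n into round(n * p) with sum n.
.apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Deterministic given `config$seed`. See [synth_config()] for the planted
#' structure. The returned dataset holds every input layer the pipeline
#' reads plus a `truth` manifest; [write_dataset()] serializes it to the
#' same plain-text formats the readers consume.
#'
#' @param config A [synth_config()] list.
#' @return List with elements `genes`, `cgis`, `h3k27ac_peaks`,
#'   `dhs_peaks`, `cage_tss`, `denovo_tss`, `links`, `beta_normal`,
#'   `beta_tumor`, `expr_normal`, `expr_tumor`, `gene_sets`, `coverage`
#'   (four bedGraph tracks), `chrom_sizes`, `truth`, `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  cell_w <- 30000
  pad_lo <- 10000
  pad_hi <- 20000

  # --- placement cells -----------------------------------------------------
  cells <- do.call(rbind, lapply(names(cfg$chrom_sizes), function(chr) {
    n_cell <- floor(cfg$chrom_sizes[[chr]] / cell_w)
    data.frame(chrom = chr, cell_start = (seq_len(n_cell) - 1) * cell_w,
               stringsAsFactors = FALSE)
  }))
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]

  counts <- .apportion(cfg$n_cgis, cfg$class_mix)
  n_own_cgi <- cfg$n_cgis - counts[["pCGI"]]
  n_bg_peaks <- 60
  need <- cfg$n_genes + n_own_cgi + cfg$n_typical + n_bg_peaks
  if (need > nrow(cells))
    stop("infeasible placement: ", need, " features need cells but only ",
         nrow(cells), " available; enlarge chrom_sizes or reduce counts")
  take <- function(k) {
    out <- cells[seq_len(k), , drop = FALSE]
    cells <<- cells[-seq_len(k), , drop = FALSE]
    out
  }

  # --- genes ---------------------------------------------------------------
  gcell <- take(cfg$n_genes)
  tss_off <- sample(pad_lo:pad_hi, cfg$n_genes, replace = TRUE)
  tss <- gcell$cell_start + tss_off
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  glen <- sample(2000:10000, cfg$n_genes, replace = TRUE)
  gstart <- ifelse(strand == "+", tss, tss - glen + 1)
  gend <- gstart + glen
  n_coding <- round(cfg$frac_coding * cfg$n_genes)
  coding <- rep(FALSE, cfg$n_genes)
  coding[sample.int(cfg$n_genes, n_coding)] <- TRUE
  gene_id <- ifelse(coding, sprintf("NM_%04d", seq_len(cfg$n_genes)),
                    sprintf("NR_%04d", seq_len(cfg$n_genes)))
  genes <- make_gene_table(gene_id, gcell$chrom, strand, gstart, gend, coding)
  if (counts[["pCGI"]] > n_coding)
    stop("infeasible placement: more pCGIs requested than coding genes")

  # --- CGIs ----------------------------------------------------------------
  labels <- rep(names(counts), counts)
  cgi_id <- sprintf("cgi_%04d", seq_len(cfg$n_cgis))
  clen <- sample(200:2000, cfg$n_cgis, replace = TRUE)
  cchrom <- character(cfg$n_cgis)
  cstart <- numeric(cfg$n_cgis)
  is_p <- labels == "pCGI"
  host <- sample(which(genes$coding), sum(is_p))
  cchrom[is_p] <- genes$chrom[host]
  lo <- pmax(0, genes$tss[host] - cfg$flank - clen[is_p] + 1)
  hi <- genes$tss[host] + cfg$flank
  cstart[is_p] <- floor(lo + stats::runif(sum(is_p)) * (hi - lo + 1))
  ccell <- take(n_own_cgi)
  cchrom[!is_p] <- ccell$chrom
  cstart[!is_p] <- ccell$cell_start +
    sample(pad_lo:(pad_hi - 2000), n_own_cgi, replace = TRUE)
  cgis <- gintervals(cchrom, cstart, cstart + clen, name = cgi_id)

  # --- peaks ---------------------------------------------------------------
  dhs <- list(); k27 <- list()
  peak_owner_dhs <- character(0); peak_owner_k27 <- character(0)
  add_peak <- function(lst, chrom, start, end, id) {
    lst[[length(lst) + 1L]] <- data.frame(chrom = chrom, start = pmax(0, start),
                                          end = end, name = id,
                                          stringsAsFactors = FALSE)
    lst
  }
  active <- labels %in% c("eCGI", "npCGI")
  for (i in which(active)) {
    if (stats::runif(1) >= cfg$peak_dropout) {
      dhs <- add_peak(dhs, cchrom[i], cstart[i] - sample(0:300, 1),
                      cstart[i] + clen[i] + sample(0:300, 1),
                      paste0("dhs_", cgi_id[i]))
      peak_owner_dhs <- c(peak_owner_dhs, cgi_id[i])
    }
    if (stats::runif(1) >= cfg$peak_dropout) {
      k27 <- add_peak(k27, cchrom[i], cstart[i] - sample(0:300, 1),
                      cstart[i] + clen[i] + sample(0:300, 1),
                      paste0("k27_", cgi_id[i]))
      peak_owner_k27 <- c(peak_owner_k27, cgi_id[i])
    }
  }
  for (i in which(is_p)) {            # promoters are often open/acetylated
    if (stats::runif(1) < 0.7) {
      dhs <- add_peak(dhs, cchrom[i], cstart[i] - sample(0:300, 1),
                      cstart[i] + clen[i] + sample(0:300, 1),
                      paste0("dhs_", cgi_id[i]))
      peak_owner_dhs <- c(peak_owner_dhs, cgi_id[i])
      k27 <- add_peak(k27, cchrom[i], cstart[i] - sample(0:300, 1),
                      cstart[i] + clen[i] + sample(0:300, 1),
                      paste0("k27_", cgi_id[i]))
      peak_owner_k27 <- c(peak_owner_k27, cgi_id[i])
    }
  }
  for (i in which(labels == "orphan_inactive")) {  # at most one mark
    mode <- sample(c("dhs", "k27", "none"), 1)
    if (mode == "dhs") {
      dhs <- add_peak(dhs, cchrom[i], cstart[i] - 100, cstart[i] + clen[i] + 100,
                      paste0("dhs_", cgi_id[i]))
      peak_owner_dhs <- c(peak_owner_dhs, cgi_id[i])
    } else if (mode == "k27") {
      k27 <- add_peak(k27, cchrom[i], cstart[i] - 100, cstart[i] + clen[i] + 100,
                      paste0("k27_", cgi_id[i]))
      peak_owner_k27 <- c(peak_owner_k27, cgi_id[i])
    }
  }

  # typical enhancers: DHS + H3K27ac pairs away from CGIs and TSS evidence
  tcell <- take(cfg$n_typical)
  twidth <- sample(500:1500, cfg$n_typical, replace = TRUE)
  tstart <- tcell$cell_start + sample(pad_lo:(pad_hi - 1500),
                                      cfg$n_typical, replace = TRUE)
  te_id <- sprintf("te_%04d", seq_len(cfg$n_typical))
  typical <- gintervals(tcell$chrom, tstart, tstart + twidth, name = te_id)
  for (i in seq_len(cfg$n_typical)) {
    dhs <- add_peak(dhs, tcell$chrom[i], tstart[i], tstart[i] + twidth[i],
                    paste0("dhs_", te_id[i]))
    peak_owner_dhs <- c(peak_owner_dhs, te_id[i])
    k27 <- add_peak(k27, tcell$chrom[i], tstart[i] - sample(0:200, 1),
                    tstart[i] + twidth[i] + sample(0:200, 1),
                    paste0("k27_", te_id[i]))
    peak_owner_k27 <- c(peak_owner_k27, te_id[i])
  }

  # background single-mark peaks (never DHS+H3K27ac together)
  bcell <- take(n_bg_peaks)
  bwidth <- sample(500:1500, n_bg_peaks, replace = TRUE)
  bstart <- bcell$cell_start + sample(pad_lo:(pad_hi - 1500), n_bg_peaks,
                                      replace = TRUE)
  for (i in seq_len(n_bg_peaks)) {
    id <- sprintf("bg_%04d", i)
    if (i %% 2 == 0) {
      dhs <- add_peak(dhs, bcell$chrom[i], bstart[i], bstart[i] + bwidth[i],
                      paste0("dhs_", id))
      peak_owner_dhs <- c(peak_owner_dhs, id)
    } else {
      k27 <- add_peak(k27, bcell$chrom[i], bstart[i], bstart[i] + bwidth[i],
                      paste0("k27_", id))
      peak_owner_k27 <- c(peak_owner_k27, id)
    }
  }
  dhs_peaks <- do.call(rbind, dhs); rownames(dhs_peaks) <- NULL
  k27_peaks <- do.call(rbind, k27); rownames(k27_peaks) <- NULL
  dhs_peaks$strand <- "."; k27_peaks$strand <- "."

  # --- TSS evidence --------------------------------------------------------
  cage <- list(); denovo <- list()
  for (i in which(labels == "npCGI")) {  # noncoding transcript start inside
    p <- cstart[i] + sample(0:(clen[i] - 20), 1)
    cage[[length(cage) + 1L]] <- data.frame(chrom = cchrom[i], start = p,
                                            end = p + 20,
                                            name = paste0("cage_", cgi_id[i]),
                                            stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.5)
      denovo[[length(denovo) + 1L]] <- data.frame(
        chrom = cchrom[i], start = p, end = p + 1,
        name = paste0("denovo_", cgi_id[i]), stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_genes)) {      # real gene TSSs carry CAGE signal
    if (stats::runif(1) < 0.5)
      cage[[length(cage) + 1L]] <- data.frame(
        chrom = genes$chrom[i], start = max(0, genes$tss[i] - 10),
        end = genes$tss[i] + 10, name = paste0("cage_", genes$gene_id[i]),
        stringsAsFactors = FALSE)
    if (genes$coding[i] && stats::runif(1) < 0.2)
      denovo[[length(denovo) + 1L]] <- data.frame(
        chrom = genes$chrom[i], start = genes$tss[i],
        end = genes$tss[i] + 1, name = paste0("denovo_", genes$gene_id[i]),
        stringsAsFactors = FALSE)
  }
  bindup <- function(lst) {
    if (!length(lst))
      return(gintervals(character(0), numeric(0), numeric(0)))
    out <- do.call(rbind, lst); rownames(out) <- NULL
    out$strand <- "."
    out
  }
  cage_tss <- bindup(cage)
  denovo_tss <- bindup(denovo)

  # --- ChIA-PET links ------------------------------------------------------
  ecgi_ids <- cgi_id[labels == "eCGI"]
  coding_idx <- which(genes$coding)
  n_reg <- round(cfg$frac_regulators * length(coding_idx))
  regulator_genes <- sort(genes$gene_id[sample(coding_idx, n_reg)])
  reg_w <- ifelse(genes$gene_id[coding_idx] %in% regulator_genes,
                  cfg$regulator_enrichment, 1)
  link_rows <- list()
  ecgi_targets <- stats::setNames(vector("list", length(ecgi_ids)), ecgi_ids)
  link_anchor <- function(chrom, start, len) {
    aw <- min(len, 400)
    a <- start + sample.int(len - aw + 1, 1) - 1
    c(a, a + aw)
  }
  add_link <- function(chrom1, s1, e1, gidx, tag) {
    j <- sample(-300:300, 1)
    a2 <- max(0, genes$tss[gidx] - 200 + j)
    data.frame(chrom1 = chrom1, start1 = s1, end1 = e1,
               chrom2 = genes$chrom[gidx], start2 = a2, end2 = a2 + 400,
               tag_count = tag, stringsAsFactors = FALSE)
  }
  for (id in ecgi_ids) {
    i <- match(id, cgi_id)
    k <- if (stats::runif(1) < cfg$frac_multi_target) sample(2:3, 1) else 1L
    tg <- sample(coding_idx, k, prob = reg_w)
    a1 <- link_anchor(cchrom[i], cstart[i], clen[i])
    for (g in tg) {
      tag <- 3 + cfg$tag_count_shift + stats::rpois(1, 2)
      link_rows[[length(link_rows) + 1L]] <-
        add_link(cchrom[i], a1[1], a1[2], g, tag)
    }
    ecgi_targets[[id]] <- sort(genes$gene_id[tg])
  }
  for (i in seq_len(cfg$n_typical)) {
    if (stats::runif(1) < 0.8) {
      k <- sample(1:2, 1)
      tg <- sample(coding_idx, k)
      a1 <- link_anchor(tcell$chrom[i], tstart[i], twidth[i])
      for (g in tg) {
        tag <- 3 + stats::rpois(1, 2)
        link_rows[[length(link_rows) + 1L]] <-
          add_link(tcell$chrom[i], a1[1], a1[2], g, tag)
      }
    }
  }
  for (i in seq_len(50)) {               # sub-threshold noise links
    chr <- sample(names(cfg$chrom_sizes), 2, replace = TRUE)
    s <- floor(stats::runif(2) * (unlist(cfg$chrom_sizes[chr]) - 400))
    link_rows[[length(link_rows) + 1L]] <- data.frame(
      chrom1 = chr[1], start1 = s[1], end1 = s[1] + 400,
      chrom2 = chr[2], start2 = s[2], end2 = s[2] + 400,
      tag_count = sample(1:2, 1), stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, link_rows); rownames(links) <- NULL

  # --- hypermethylation, silencing, gene categories ------------------------
  if (cfg$n_hyper_ecgis > length(ecgi_ids))
    stop("n_hyper_ecgis exceeds the number of eCGIs (", length(ecgi_ids), ")")
  hyper_ecgis <- sort(sample(ecgi_ids, cfg$n_hyper_ecgis))
  silenced_genes <- sort(unique(unlist(ecgi_targets[hyper_ecgis],
                                       use.names = FALSE)))
  coding_ids <- genes$gene_id[coding_idx]
  n_tsg <- round(cfg$frac_tsg * length(coding_ids))
  tsg_w <- ifelse(coding_ids %in% silenced_genes, cfg$tsg_enrichment, 1)
  tsg_genes <- sort(sample(coding_ids, n_tsg, prob = tsg_w))
  n_onc <- round(cfg$frac_oncogene * length(coding_ids))
  onc_pool <- setdiff(coding_ids, tsg_genes)
  oncogene_genes <- sort(sample(onc_pool, min(n_onc, length(onc_pool))))

  # --- expression ----------------------------------------------------------
  expr_normal <- stats::setNames(2^stats::rnorm(length(coding_ids), 3, 1.5),
                                 coding_ids)
  noise <- 2^stats::rnorm(length(coding_ids), 0, cfg$expr_noise_sd_log2)
  fold <- ifelse(coding_ids %in% silenced_genes, 1 / cfg$silencing_fold, 1)
  expr_tumor <- expr_normal * noise * fold

  # --- methylation betas ---------------------------------------------------
  cpg_rows <- list()
  for (i in seq_len(cfg$n_cgis)) {
    k <- min(cfg$cpgs_per_cgi, clen[i])
    pos <- sort(sample(cstart[i]:(cstart[i] + clen[i] - 1), k))
    bn <- stats::rbeta(k, 1.5, 15)
    delta <- if (cgi_id[i] %in% hyper_ecgis) cfg$planted_dm else 0
    bt <- pmin(1, pmax(0, bn + delta + stats::rnorm(k, 0, cfg$dm_noise_sd)))
    cpg_rows[[i]] <- data.frame(chrom = cchrom[i], position = pos,
                                beta_normal = bn, beta_tumor = bt,
                                stringsAsFactors = FALSE)
  }
  for (chr in names(cfg$chrom_sizes)) {  # background CpGs outside CGIs
    n_bg <- round(cfg$background_cpg_rate * cfg$chrom_sizes[[chr]])
    if (n_bg == 0) next
    pos <- sort(sample.int(cfg$chrom_sizes[[chr]], n_bg) - 1)
    iv <- data.frame(chrom = chr, start = pos, end = pos + 1,
                     stringsAsFactors = FALSE)
    pos <- pos[!intersect_flags(iv, cgis)]
    k <- length(pos)
    bn <- stats::rbeta(k, 8, 2)
    bt <- pmin(1, pmax(0, bn + stats::rnorm(k, 0, cfg$dm_noise_sd)))
    cpg_rows[[length(cpg_rows) + 1L]] <- data.frame(
      chrom = chr, position = pos, beta_normal = bn, beta_tumor = bt,
      stringsAsFactors = FALSE)
  }
  cpgs <- do.call(rbind, cpg_rows); rownames(cpgs) <- NULL
  beta_normal <- data.frame(chrom = cpgs$chrom, position = cpgs$position,
                            beta = cpgs$beta_normal, stringsAsFactors = FALSE)
  beta_tumor <- data.frame(chrom = cpgs$chrom, position = cpgs$position,
                           beta = cpgs$beta_tumor, stringsAsFactors = FALSE)

  # --- coverage tracks -----------------------------------------------------
  mk_cov <- function(peaks, owners) {
    val <- stats::runif(nrow(peaks), 3, 8)
    lost <- owners %in% hyper_ecgis
    normal <- data.frame(chrom = peaks$chrom, start = peaks$start,
                         end = peaks$end, value = val,
                         stringsAsFactors = FALSE)
    tumor <- normal
    tumor$value[lost] <- tumor$value[lost] * 0.5   # planted 50% signal loss
    ord <- order(normal$chrom, normal$start)
    list(normal = normal[ord, ], tumor = tumor[ord, ])
  }
  cov_dhs <- mk_cov(dhs_peaks, peak_owner_dhs)
  cov_k27 <- mk_cov(k27_peaks, peak_owner_k27)

  truth <- list(
    cgi_labels = stats::setNames(labels, cgi_id),
    ecgi_targets = ecgi_targets,
    hyper_ecgis = hyper_ecgis,
    silenced_genes = silenced_genes,
    regulator_genes = regulator_genes,
    tsg_genes = tsg_genes,
    oncogene_genes = oncogene_genes,
    typical_enhancer_ids = te_id
  )
  list(genes = genes, cgis = cgis, h3k27ac_peaks = k27_peaks,
       dhs_peaks = dhs_peaks, cage_tss = cage_tss, denovo_tss = denovo_tss,
       typical_enhancers_planted = typical, links = links,
       beta_normal = beta_normal, beta_tumor = beta_tumor,
       expr_normal = expr_normal, expr_tumor = expr_tumor,
       gene_sets = list(regulators = regulator_genes, tsg = tsg_genes,
                        oncogene = oncogene_genes),
       coverage = list(dhs_normal = cov_dhs$normal, dhs_tumor = cov_dhs$tumor,
                       h3k27ac_normal = cov_k27$normal,
                       h3k27ac_tumor = cov_k27$tumor),
       chrom_sizes = cfg$chrom_sizes, truth = truth, config = cfg)
}

#' Write a synthetic dataset to disk
#'
#' Serializes every layer in the plain-text formats the package readers
#' consume (BED6, gene TSV, BEDPE-like links, beta TSV, RPKM TSV, gene
#' lists, bedGraph) plus `ground_truth.json`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_bed(dataset$cgis, p("cgis.bed"))
  write_gene_table(dataset$genes, p("genes.tsv"))
  write_bed(dataset$h3k27ac_peaks, p("h3k27ac_peaks.bed"))
  write_bed(dataset$dhs_peaks, p("dhs_peaks.bed"))
  write_bed(dataset$cage_tss, p("cage_tss.bed"))
  write_bed(dataset$denovo_tss, p("denovo_tss.bed"))
  write_links(dataset$links, p("links.tsv"))
  write_beta_table(dataset$beta_normal, p("beta_normal.tsv"))
  write_beta_table(dataset$beta_tumor, p("beta_tumor.tsv"))
  write_expression(dataset$expr_normal, p("expr_normal.tsv"))
  write_expression(dataset$expr_tumor, p("expr_tumor.tsv"))
  write_gene_list(dataset$gene_sets$regulators, p("regulators.txt"))
  write_gene_list(dataset$gene_sets$tsg, p("tsg.txt"))
  write_gene_list(dataset$gene_sets$oncogene, p("oncogene.txt"))
  for (nm in names(dataset$coverage))
    write_bedgraph(dataset$coverage[[nm]], p(paste0(nm, ".bedgraph")))
  utils::write.table(
    data.frame(chrom = names(dataset$chrom_sizes),
               size = unname(dataset$chrom_sizes)),
    p("chrom_sizes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(dataset$truth, p("ground_truth.json"))
  invisible(dir)
}

#' Read a synthetic dataset from disk
#' @param dir Directory written by [write_dataset()].
#' @return Dataset list in the shape of [generate_dataset()] output
#'   (without `config`).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  cs <- utils::read.delim(p("chrom_sizes.tsv"), stringsAsFactors = FALSE)
  list(
    genes = read_gene_table(p("genes.tsv")),
    cgis = read_bed(p("cgis.bed")),
    h3k27ac_peaks = read_bed(p("h3k27ac_peaks.bed")),
    dhs_peaks = read_bed(p("dhs_peaks.bed")),
    cage_tss = read_bed(p("cage_tss.bed")),
    denovo_tss = read_bed(p("denovo_tss.bed")),
    links = read_links(p("links.tsv")),
    beta_normal = read_beta_table(p("beta_normal.tsv")),
    beta_tumor = read_beta_table(p("beta_tumor.tsv")),
    expr_normal = read_expression(p("expr_normal.tsv")),
    expr_tumor = read_expression(p("expr_tumor.tsv")),
    gene_sets = list(regulators = read_gene_list(p("regulators.txt")),
                     tsg = read_gene_list(p("tsg.txt")),
                     oncogene = read_gene_list(p("oncogene.txt"))),
    coverage = list(
      dhs_normal = read_bedgraph(p("dhs_normal.bedgraph")),
      dhs_tumor = read_bedgraph(p("dhs_tumor.bedgraph")),
      h3k27ac_normal = read_bedgraph(p("h3k27ac_normal.bedgraph")),
      h3k27ac_tumor = read_bedgraph(p("h3k27ac_tumor.bedgraph"))),
    chrom_sizes = stats::setNames(cs$size, cs$chrom),
    truth = read_manifest(p("ground_truth.json"))
  )
}

#' Write the ground-truth manifest as JSON
#' @param truth Ground-truth list (see [generate_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(truth, path) {
  out <- truth
  out$cgi_labels <- as.list(out$cgi_labels)
  out$ecgi_targets <- lapply(out$ecgi_targets, as.list)
  jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth manifest
#' @param path JSON path written by [write_manifest()].
#' @return Ground-truth list with the same shapes as in
#'   [generate_dataset()].
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path)
  chr_vec <- function(x) vapply(x, as.character, "")
  list(
    cgi_labels = if (length(raw$cgi_labels))
      vapply(raw$cgi_labels, as.character, "") else
        stats::setNames(character(0), character(0)),
    ecgi_targets = lapply(raw$ecgi_targets, chr_vec),
    hyper_ecgis = chr_vec(raw$hyper_ecgis),
    silenced_genes = chr_vec(raw$silenced_genes),
    regulator_genes = chr_vec(raw$regulator_genes),
    tsg_genes = chr_vec(raw$tsg_genes),
    oncogene_genes = chr_vec(raw$oncogene_genes),
    typical_enhancer_ids = chr_vec(raw$typical_enhancer_ids)
  )
}
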