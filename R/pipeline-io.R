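# Readers/writers for the standard formats (FASTA via Biostrings, GFF3 via
# rtracklayer, BLAST-style 12-column tabular, TSV/JSON) and the end-to-end
# orchestration: simulate/load -> hits -> duplicate classes -> Ks ->
# mixture peaks -> dating -> shared-WGD test -> telomeres -> syntenic depth
# -> fractionation -> retention -> report. Internal coordinates are 0-based
# half-open; GFF3 (1-based inclusive) converts at the boundary.

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

#' Read a BLAST-style 12-column tabular hit file
#'
#' Drops self-hits, applies an e-value ceiling, keeps the `top_n` best
#' non-self subjects per query (by bitscore), and collapses to one best
#' record per unordered gene pair (maximum bitscore).
#'
#' @param path Tab-separated file with the standard 12 columns (qseqid
#'   sseqid pident length mismatch gapopen qstart qend sstart send evalue
#'   bitscore), no header.
#' @param evalue_max E-value ceiling (default 1e-10).
#' @param top_n Best subjects kept per query (default 5).
#' @return Data frame `gene_a`, `gene_b`, `score` (bitscore), `evalue`.
#' @export
read_hit_table <- function(path, evalue_max = 1e-10, top_n = 5) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 12) {
    stop("expected 12 tab-separated columns, found ", ncol(raw),
         call. = FALSE)
  }
  names(raw) <- .BLAST_COLS
  bad <- which(!is.finite(raw$evalue) | !is.finite(raw$bitscore))
  if (length(bad)) {
    stop("malformed hit row at line ", bad[1], call. = FALSE)
  }
  filter_hits(raw[, c("qseqid", "sseqid", "evalue", "bitscore")],
              evalue_max = evalue_max, top_n = top_n)
}

#' Filter raw hits into one best record per unordered pair
#'
#' @param raw Data frame with `qseqid`, `sseqid`, `evalue`, `bitscore`.
#' @inheritParams read_hit_table
#' @return Data frame `gene_a`, `gene_b`, `score`, `evalue`.
#' @export
filter_hits <- function(raw, evalue_max = 1e-10, top_n = 5) {
  raw <- raw[raw$qseqid != raw$sseqid, , drop = FALSE]
  raw <- raw[raw$evalue <= evalue_max, , drop = FALSE]
  if (nrow(raw) && is.finite(top_n)) {
    raw <- do.call(rbind, lapply(split(raw, raw$qseqid), function(q) {
      q <- q[order(-q$bitscore, q$sseqid), , drop = FALSE]
      utils::head(q, top_n)
    }))
  }
  if (nrow(raw) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), evalue = numeric(0)))
  }
  key <- paste(pmin(raw$qseqid, raw$sseqid),
               pmax(raw$qseqid, raw$sseqid), sep = "\r")
  ord <- order(key, -raw$bitscore)
  raw <- raw[ord, ]
  key <- key[ord]
  keep <- raw[!duplicated(key), ]
  out <- data.frame(gene_a = pmin(keep$qseqid, keep$sseqid),
                    gene_b = pmax(keep$qseqid, keep$sseqid),
                    score = keep$bitscore, evalue = keep$evalue,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Similarity hits for synthetic genomes by k-mer seeding
#'
#' A deterministic stand-in for an all-vs-all protein search, intended only
#' for simulated data: gene pairs sharing at least one exact `k`-mer are
#' verified by ungapped nucleotide identity and reported in BLAST-like
#' form. With the simulator's indel-free genes this recovers paralog and
#' ortholog pairs exactly.
#'
#' @param cds Named character vector of query CDS.
#' @param cds2 Optional subject set (default: self comparison, each
#'   unordered pair once).
#' @param k Seed k-mer length.
#' @param min_pident Minimum percent identity to report.
#' @return Data frame `qseqid`, `sseqid`, `pident`, `length`, `bitscore`,
#'   `evalue` (a monotone transform of the score, for filter interfaces).
#' @export
synthetic_hits <- function(cds, cds2 = NULL, k = 16, min_pident = 50) {
  self <- is.null(cds2)
  if (self) cds2 <- cds
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  idx <- new.env(parent = emptyenv())
  for (id in names(cds2)) {
    for (km in kmers_of(cds2[[id]])) {
      idx[[km]] <- c(idx[[km]], id)
    }
  }
  chars_q <- lapply(cds, function(s) strsplit(s, "")[[1]])
  chars_s <- if (self) chars_q else lapply(cds2, function(s) strsplit(s, "")[[1]])
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (qa in names(cds)) {
    subs <- unique(unlist(lapply(kmers_of(cds[[qa]]),
                                 function(km) idx[[km]]), use.names = FALSE))
    for (sb in subs) {
      if (sb == qa) next
      pk <- if (self) paste(min(qa, sb), max(qa, sb), sep = "\r") else
        paste(qa, sb, sep = "\r")
      if (!is.null(seen[[pk]])) next
      seen[[pk]] <- TRUE
      a <- chars_q[[qa]]
      b <- chars_s[[sb]]
      L <- min(length(a), length(b))
      matches <- sum(a[seq_len(L)] == b[seq_len(L)])
      pident <- 100 * matches / L
      if (pident < min_pident) next
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = qa, sseqid = sb, pident = pident, length = L,
        bitscore = 2 * matches, evalue = 10^(-matches / 10),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      bitscore = numeric(0), evalue = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$qseqid, out$sseqid), ]
}

#' Write one simulated species (or all) to FASTA/GFF3/TSV
#'
#' Per species writes `<sp>.chromosomes.fa`, `<sp>.cds.fa`,
#' `<sp>.genes.gff3` (1-based inclusive, gene/mRNA/CDS features), and the
#' truth log as `truth.<table>.tsv` plus `truth.json`.
#'
#' @param sim A `sim_clade` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_sim_clade <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_clade"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (sp in names(sim$species)) {
    g <- sim$species[[sp]]
    f_chr <- file.path(dir, paste0(sp, ".chromosomes.fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(g$chromosomes), f_chr)
    f_cds <- file.path(dir, paste0(sp, ".cds.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$cds), f_cds)
    f_gff <- file.path(dir, paste0(sp, ".genes.gff3"))
    write_gene_models(g$genes, f_gff)
    files <- c(files, f_chr, f_cds, f_gff)
  }
  for (nm in names(sim$truth)) {
    f <- file.path(dir, paste0("truth.", nm, ".tsv"))
    utils::write.table(sim$truth[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f_json <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, f_json, dataframe = "rows")
  invisible(c(files, f_json))
}

#' Write a gene-model table as GFF3
#'
#' @param genes Data frame `gene_id`, `scaffold`, `start`, `end` (1-based
#'   inclusive), `strand`.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  mk <- function(type, id, parent = NA) {
    GenomicRanges::GRanges(
      seqnames = genes$scaffold,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand, type = type, ID = id,
      Parent = ifelse(is.na(parent), NA_character_, parent),
      phase = if (type == "CDS") 0L else NA_integer_)
  }
  gr <- c(mk("gene", genes$gene_id),
          mk("mRNA", paste0(genes$gene_id, ".m1"), genes$gene_id),
          mk("CDS", paste0(genes$gene_id, ".m1.cds"),
             paste0(genes$gene_id, ".m1")))
  rtracklayer::export(sort(gr), path, format = "gff3")
  invisible(path)
}

#' Load gene models from a genome FASTA and GFF3
#'
#' Builds one record per gene using the longest mRNA's CDS (CDS parts
#' concatenated in transcription order; minus-strand CDS reverse
#' complemented), computes gene-order ranks per scaffold, and flags genes
#' whose CDS length is not a multiple of 3 (`ks_ok = FALSE`; they remain
#' usable for order-based analyses).
#'
#' @param fasta_path Genome (chromosome) FASTA.
#' @param gff3_path GFF3 with gene/mRNA/CDS features.
#' @return List of class `gene_models`: `genes` (data frame `gene_id`,
#'   `scaffold`, `rank`, `start`, `end`, `strand`, `ks_ok`), `cds` (named
#'   character vector).
#' @export
load_gene_models <- function(fasta_path, gff3_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*", "", names(genome))
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  gff_df <- as.data.frame(gff)
  genes_df <- gff_df[gff_df$type == "gene", ]
  mrna_df <- gff_df[gff_df$type == "mRNA", ]
  cds_df <- gff_df[gff_df$type == "CDS", ]
  first_chr <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v)[1] else NA_character_, character(1))
  mrna_df$parent_gene <- first_chr(mrna_df$Parent)
  cds_df$parent_mrna <- first_chr(cds_df$Parent)
  missing_scaf <- setdiff(unique(as.character(cds_df$seqnames)),
                          names(genome))
  if (length(missing_scaf)) {
    stop("CDS features on scaffold(s) absent from FASTA: ",
         paste(missing_scaf, collapse = ", "), call. = FALSE)
  }
  rows <- list(); cds_seqs <- character(0)
  for (i in seq_len(nrow(genes_df))) {
    gid <- genes_df$ID[i]
    mr <- mrna_df[mrna_df$parent_gene %in% gid, , drop = FALSE]
    if (nrow(mr) == 0) next
    # longest mRNA by summed CDS length
    cds_len <- vapply(mr$ID, function(m)
      sum(cds_df$width[cds_df$parent_mrna %in% m]), numeric(1))
    m_best <- mr$ID[which.max(cds_len)]
    parts <- cds_df[cds_df$parent_mrna %in% m_best, , drop = FALSE]
    if (nrow(parts) == 0) next
    strand <- as.character(parts$strand[1])
    parts <- parts[order(parts$start, decreasing = (strand == "-")), ]
    seq <- paste(vapply(seq_len(nrow(parts)), function(k) {
      s <- Biostrings::subseq(genome[[as.character(parts$seqnames[k])]],
                              parts$start[k], parts$end[k])
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1)), collapse = "")
    cds_seqs[gid] <- seq
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, scaffold = as.character(genes_df$seqnames[i]),
      start = genes_df$start[i], end = genes_df$end[i],
      strand = as.character(genes_df$strand[i]),
      ks_ok = nchar(seq) %% 3 == 0, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  if (any(!genes$ks_ok)) {
    warning(sum(!genes$ks_ok),
            " gene(s) with CDS length not a multiple of 3; ",
            "excluded from Ks analyses")
  }
  rk <- gene_ranks(genes)
  genes$rank <- rk$rank[match(genes$gene_id, rk$gene_id)]
  genes <- genes[order(genes$scaffold, genes$rank),
                 c("gene_id", "scaffold", "rank", "start", "end", "strand",
                   "ks_ok")]
  rownames(genes) <- NULL
  structure(list(genes = genes, cds = cds_seqs), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", nrow(x$genes), "genes on",
      length(unique(x$genes$scaffold)), "scaffolds\n")
  invisible(x)
}

#' Write telomere windows as BED
#'
#' Retained windows only, 0-based half-open, score = total copy count.
#'
#' @param windows Output of [scan_telomere_windows()].
#' @param path Output path.
#' @export
write_telomere_bed <- function(windows, path) {
  w <- windows[windows$retained, , drop = FALSE]
  bed <- data.frame(w$scaffold, w$start, w$end,
                    paste0("telomere_w", w$window_index),
                    w$fwd_count + w$rev_count, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full WGD detection/dating/consequence pipeline on a simulation
#'
#' Simulates a 4-species clade, then runs every downstream stage on the
#' simulated genomes: within-genome hits and collinear blocks for the
#' focal ingroup, duplicate classification, Ks estimation for WGD pairs,
#' log-normal mixture peaks, age calibration, cross-species ortholog Ks
#' and the shared-WGD test, telomere window scan, syntenic depth against
#' an outgroup (plus an outgroup-vs-outgroup negative control),
#' fractionation profile and bias test, and pangene retention
#' classification.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, stage outputs (FASTA,
#'   GFF3, TSV, BED) and the report JSON are written there.
#' @param min_block,max_gap Block-chaining parameters.
#' @param tandem_gap,proximal_gap Duplicate-classification rank gaps.
#' @param ks_filter Ks filter range for mixture fitting.
#' @param k_paralog,k_ortholog Candidate component counts for the paralog
#'   and ortholog mixture fits.
#' @param calib_peak_ks,calib_age_my Age calibration pair (defaults: the
#'   Brassicaceae alpha-WGD, Ks 0.85 at 35 My).
#' @param telomere_window Window size (bp) for the telomere scan; the
#'   default suits simulated chromosomes, real genomes use 1e6.
#' @param telomere_min_count Copy threshold for retaining a window.
#' @param fractionation_window Reference-gene window for fractionation
#'   (default 25 to suit simulated scaffold sizes; 100 matches
#'   chromosome-scale data).
#' @param max_ks_pairs Cap on gene pairs sent to the Ka/Ks engine per
#'   stage (uniform subsample, deterministic under the run seed).
#' @return A list of class `wgd_report` with per-stage summaries: see
#'   `print.wgd_report`.
#' @export
run_wgd_pipeline <- function(config = sim_config(), outdir = NULL,
                             min_block = 5, max_gap = 25,
                             tandem_gap = 1, proximal_gap = 10,
                             ks_filter = c(0.005, 3),
                             k_paralog = 1:4, k_ortholog = 1:3,
                             calib_peak_ks = 0.85, calib_age_my = 35,
                             telomere_window = 10000,
                             telomere_min_count = 20,
                             fractionation_window = 25,
                             max_ks_pairs = 500) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  sim <- simulate_clade(config)
  focal <- "ingroupA"; sibling <- "ingroupB"
  ref <- "outgroup1"; ref2 <- "outgroup2"
  cds_f <- sim$species[[focal]]$cds
  ranks_f <- gene_ranks(sim$species[[focal]]$genes)

  # --- within-genome duplicates
  hits_self <- synthetic_hits(cds_f)
  pairs_self <- filter_hits(hits_self[, c("qseqid", "sseqid", "evalue",
                                          "bitscore")],
                            evalue_max = 1, top_n = 5)
  blocks_self <- chain_anchors(pairs_self, ranks_f, ranks_f,
                               min_block = min_block, max_gap = max_gap,
                               self = TRUE)
  dup <- classify_duplicates(pairs_self, ranks_f, blocks_self,
                             tandem_gap = tandem_gap,
                             proximal_gap = proximal_gap)

  # --- paralog Ks over WGD-classified pairs
  wgd_pairs <- dup[dup$class == "wgd", c("gene_a", "gene_b")]
  wgd_pairs <- .subsample_rows(wgd_pairs, max_ks_pairs)
  ks_par <- ks_batch(wgd_pairs, cds_f)
  fit_par <- ks_mixture(ks_par$ks[!is.na(ks_par$ks) & !ks_par$saturated],
                        k = k_paralog, filter_range = ks_filter,
                        seed = config$seed)
  peaks_par <- extract_peaks(fit_par)
  age <- estimate_wgd_age(peaks_par$peak[1], calib_peak_ks, calib_age_my)

  # --- ortholog Ks between the two ingroups
  hits_x <- synthetic_hits(cds_f, sim$species[[sibling]]$cds)
  best_x <- do.call(rbind, lapply(split(hits_x, hits_x$qseqid), function(q)
    q[which.max(q$pident), , drop = FALSE]))
  orth_pairs <- data.frame(gene_a = best_x$qseqid, gene_b = best_x$sseqid,
                           stringsAsFactors = FALSE)
  orth_pairs <- .subsample_rows(orth_pairs, max_ks_pairs)
  cds_both <- c(cds_f, sim$species[[sibling]]$cds)
  ks_orth <- ks_batch(orth_pairs, cds_both)
  fit_orth <- ks_mixture(ks_orth$ks[!is.na(ks_orth$ks) & !ks_orth$saturated],
                         k = k_ortholog, filter_range = ks_filter,
                         seed = config$seed)
  peaks_orth <- extract_peaks(fit_orth)
  verdict <- test_shared_wgd(peaks_par$peak[1], peaks_orth$peak[1])

  # --- telomeres on the focal genome
  telo <- scan_telomere_windows(sim$species[[focal]]$chromosomes,
                                window = telomere_window,
                                min_count = telomere_min_count)
  telo_status <- classify_contig_telomeres(telo)

  # --- syntenic depth vs an outgroup + negative control
  ranks_ref <- gene_ranks(sim$species[[ref]]$genes)
  hits_ref <- synthetic_hits(sim$species[[ref]]$cds, cds_f)
  pairs_ref <- data.frame(gene_a = hits_ref$qseqid, gene_b = hits_ref$sseqid,
                          stringsAsFactors = FALSE)
  blocks_ref <- chain_anchors(pairs_ref, ranks_ref, ranks_f,
                              min_block = min_block, max_gap = max_gap,
                              self = FALSE)
  depth <- syntenic_depth_ratio(blocks_ref, ranks_ref)
  ranks_ref2 <- gene_ranks(sim$species[[ref2]]$genes)
  hits_ctrl <- synthetic_hits(sim$species[[ref]]$cds,
                              sim$species[[ref2]]$cds)
  blocks_ctrl <- chain_anchors(
    data.frame(gene_a = hits_ctrl$qseqid, gene_b = hits_ctrl$sseqid,
               stringsAsFactors = FALSE),
    ranks_ref, ranks_ref2, min_block = min_block, max_gap = max_gap,
    self = FALSE)
  depth_ctrl <- syntenic_depth_ratio(blocks_ctrl, ranks_ref)

  # --- fractionation vs the outgroup reference
  omap <- data.frame(ref_gene = blocks_ref$gene_a,
                     target_scaffold = ranks_f$scaffold[
                       match(blocks_ref$gene_b, ranks_f$gene_id)],
                     stringsAsFactors = FALSE)
  fw <- fractionation_profile(ranks_ref, omap,
                              window = fractionation_window)
  bias <- fractionation_bias_test(fw)

  # --- pangene retention
  retention <- classify_retention(pangene_table(sim))

  report <- structure(list(
    config = unclass(config),
    seed = config$seed,
    n_genes = vapply(sim$species, function(s) nrow(s$genes), integer(1)),
    duplicate_classes = as.list(table(dup$class)),
    n_blocks_self = length(unique(blocks_self$block)),
    paralog_ks = list(n = fit_par$n, K = fit_par$K,
                      peaks = peaks_par$peak, weights = peaks_par$weight),
    wgd_age_my = age$age_my,
    calibration = list(peak_ks = calib_peak_ks, age_my = calib_age_my),
    ortholog_ks = list(n = fit_orth$n, K = fit_orth$K,
                       peaks = peaks_orth$peak),
    shared_wgd = verdict,
    telomere_status = as.list(table(telo_status$status)),
    syntenic_modal_depth = depth$modal_depth,
    syntenic_modal_depth_control = depth_ctrl$modal_depth,
    fractionation = list(p_value = bias$p_value, mean1 = bias$mean1,
                         mean2 = bias$mean2, n_windows = bias$n_windows),
    retention_totals = as.list(retention$totals)
  ), class = "wgd_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_sim_clade(sim, file.path(outdir, "genomes"))
    wt <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(dup, "duplicate_pairs.tsv")
    wt(as.data.frame(blocks_self), "blocks_self.tsv")
    wt(ks_par, "ks_paralogs.tsv")
    wt(ks_orth, "ks_orthologs.tsv")
    wt(telo, "telomere_windows.tsv")
    wt(telo_status, "telomere_status.tsv")
    write_telomere_bed(telo, file.path(outdir, "telomere_windows.bed"))
    wt(fw, "fractionation_windows.tsv")
    wt(retention$rows, "retention_classes.tsv")
    jsonlite::write_json(unclass(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(report, "outdir") <- outdir
  }
  report
}

.subsample_rows <- function(df, n_max) {
  if (nrow(df) <= n_max) return(df)
  df[sort(sample.int(nrow(df), n_max)), , drop = FALSE]
}

#' @export
print.wgd_report <- function(x, ...) {
  cat("WGD pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  duplicate classes:",
      paste(names(x$duplicate_classes), unlist(x$duplicate_classes),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  paralog Ks: n = %d, K = %d, peaks = %s\n",
              x$paralog_ks$n, x$paralog_ks$K,
              paste(round(x$paralog_ks$peaks, 3), collapse = ", ")))
  cat(sprintf("  WGD age: %.2f My (calibration Ks %.3g at %.3g My)\n",
              x$wgd_age_my, x$calibration$peak_ks, x$calibration$age_my))
  cat(sprintf("  ortholog Ks peak(s): %s -> WGD %s\n",
              paste(round(x$ortholog_ks$peaks, 3), collapse = ", "),
              x$shared_wgd))
  cat("  telomere contig status:",
      paste(names(x$telomere_status), unlist(x$telomere_status),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  syntenic modal depth: %d (ingroup) vs %d (outgroup control)\n",
              x$syntenic_modal_depth, x$syntenic_modal_depth_control))
  cat(sprintf("  fractionation: %.1f%% vs %.1f%% retention, sign-test p = %.3g\n",
              x$fractionation$mean1, x$fractionation$mean2,
              x$fractionation$p_value))
  cat("  retention totals:",
      paste(names(x$retention_totals), unlist(x$retention_totals),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks that every field named in the package's report schema
#' (`inst/extdata/report-schema.json`) is present and of the declared
#' JSON type.
#'
#' @param report A `wgd_report` (or a list parsed from `report.json`).
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report-schema.json",
                             package = "wgdkit")
  schema <- jsonlite::read_json(schema_path)
  for (field in names(schema$required)) {
    if (is.null(report[[field]])) {
      stop("report is missing required field: ", field, call. = FALSE)
    }
    type <- schema$required[[field]]
    val <- report[[field]]
    ok <- switch(type,
                 number = is.numeric(val) || is.integer(val),
                 string = is.character(val),
                 object = is.list(val),
                 array = is.numeric(val) || is.list(val),
                 TRUE)
    if (!ok) {
      stop("report field ", field, " is not of type ", type, call. = FALSE)
    }
  }
  invisible(TRUE)
}
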