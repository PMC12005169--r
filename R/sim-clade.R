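# Synthetic 4-species clade simulator: two outgroups without the WGD and two
# ingroups sharing a WGD, with known event times, per-homoeolog gene losses
# (optionally biased between subgenomes), tandem duplicates, and perfect
# telomere arrays planted at chromosome ends. Every stochastic choice is
# logged in a truth table so downstream stages have parameter-recovery tests.

.FOURFOLD_FAMILIES <- c("GC", "GG", "GT", "CC", "AC")  # Ala Gly Val Pro Thr

#' Simulation configuration for a 4-species clade with a shared WGD
#'
#' Species tree: `(((ingroup_A, ingroup_B), outgroup_1), outgroup_2)`, with
#' the WGD on the ingroup stem. Divergence-time defaults are chosen so that,
#' at the default synonymous rate, expected WGD-pair Ks is
#' `2 * syn_rate * wgd_age ~ 0.18` and expected ingroup ortholog Ks
#' `~ 0.08` — the signature of a recent duplication shared by both ingroups.
#'
#' @param n_genes Ancestral gene count (default 200).
#' @param n_chromosomes Chromosomes per (unduplicated) genome; ingroups get
#'   `2 * n_chromosomes`, one set per subgenome.
#' @param codon_length Codons per CDS.
#' @param wgd_age Age of the shared WGD, My.
#' @param speciation_ages Named numeric: `outgroup2` (root split),
#'   `outgroup1`, `ingroup` (ingroup A/B split), in My. The ingroup split
#'   defaults younger than `wgd_age` (shared-WGD scenario).
#' @param syn_rate Synonymous substitutions per synonymous site per My, so
#'   expected pairwise Ks = `2 * syn_rate * divergence_age`.
#' @param ka_ks Ratio of nonsynonymous to synonymous rate (purifying
#'   selection; nonsynonymous rate = `ka_ks * syn_rate`).
#' @param loss_prob Per homoeolog pair, per ingroup species: probability
#'   that one of the two WGD copies is lost.
#' @param loss_bias Fraction of losses that hit subgenome B (0.5 =
#'   unbiased).
#' @param tandem_prob Per gene, per species: probability of carrying an
#'   adjacent tandem duplicate.
#' @param tandem_age Age of tandem duplications, My.
#' @param telomere_repeats_per_end Count of `TTTAGGG` units planted at each
#'   chromosome end (forward at the 5' end, reverse complement at the 3').
#' @param intergenic_length Random spacer length between genes, bp.
#' @param fourfold_only If TRUE (default) ancestral CDS use only codons
#'   whose third position is four-fold degenerate, making synonymous-site
#'   bookkeeping exact; FALSE allows any sense codon.
#' @param seed Integer RNG seed; the same seed gives byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_chromosomes = 4, codon_length = 300,
                       wgd_age = 7.4,
                       speciation_ages = c(outgroup2 = 40, outgroup1 = 25,
                                           ingroup = 3.3),
                       syn_rate = 0.012, ka_ks = 0.2,
                       loss_prob = 0.2, loss_bias = 0.5,
                       tandem_prob = 0.05, tandem_age = 1,
                       telomere_repeats_per_end = 30,
                       intergenic_length = 200,
                       fourfold_only = TRUE, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              codon_length = as.integer(codon_length),
              wgd_age = wgd_age, speciation_ages = speciation_ages,
              syn_rate = syn_rate, ka_ks = ka_ks,
              loss_prob = loss_prob, loss_bias = loss_bias,
              tandem_prob = tandem_prob, tandem_age = tandem_age,
              telomere_repeats_per_end = as.integer(telomere_repeats_per_end),
              intergenic_length = as.integer(intergenic_length),
              fourfold_only = isTRUE(fourfold_only), seed = as.integer(seed))
  for (p in c("loss_prob", "loss_bias", "tandem_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must be in [0, 1]", call. = FALSE)
    }
  }
  ages <- c(cfg$wgd_age, cfg$speciation_ages, cfg$tandem_age)
  if (any(ages < 0)) stop("ages must be >= 0", call. = FALSE)
  if (cfg$syn_rate < 0) stop("syn_rate must be >= 0", call. = FALSE)
  if (cfg$n_genes < cfg$n_chromosomes) {
    stop("n_genes (", cfg$n_genes, ") must be >= n_chromosomes (",
         cfg$n_chromosomes, ")", call. = FALSE)
  }
  need <- c("outgroup2", "outgroup1", "ingroup")
  if (!all(need %in% names(cfg$speciation_ages))) {
    stop("speciation_ages needs named entries: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (cfg$speciation_ages[["outgroup1"]] <= cfg$wgd_age) {
    stop("outgroup1 split must predate the WGD", call. = FALSE)
  }
  if (cfg$speciation_ages[["outgroup2"]] <= cfg$speciation_ages[["outgroup1"]]) {
    stop("outgroup2 split must predate outgroup1 split", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Clade simulation config:\n")
  cat(sprintf("  %d ancestral genes on %d chromosomes, %d codons each\n",
              x$n_genes, x$n_chromosomes, x$codon_length))
  cat(sprintf("  WGD at %.2f My; splits: outgroup2 %.1f, outgroup1 %.1f, ingroup %.2f My\n",
              x$wgd_age, x$speciation_ages[["outgroup2"]],
              x$speciation_ages[["outgroup1"]], x$speciation_ages[["ingroup"]]))
  cat(sprintf("  syn rate %.4g /site/My (expected WGD-pair Ks %.3f); ka/ks %.2f\n",
              x$syn_rate, 2 * x$syn_rate * x$wgd_age, x$ka_ks))
  cat(sprintf("  loss prob %.2f (bias to B %.2f), tandem prob %.2f, seed %d\n",
              x$loss_prob, x$loss_bias, x$tandem_prob, x$seed))
  invisible(x)
}

.random_cds <- function(codon_length, fourfold_only = TRUE) {
  nts <- c("A", "C", "G", "T")
  if (fourfold_only) {
    fams <- sample(.FOURFOLD_FAMILIES, codon_length, replace = TRUE)
    paste0(paste0(fams, sample(nts, codon_length, replace = TRUE)),
           collapse = "")
  } else {
    gc <- .genetic_code()
    sense <- names(gc)[gc != "*"]
    paste0(sample(sense, codon_length, replace = TRUE), collapse = "")
  }
}

#' Evolve a coding sequence along a branch
#'
#' Applies a continuous-time single-nucleotide substitution process in which
#' third codon positions receive `Poisson(branch_ks)` substitution events
#' per site and first/second positions `Poisson(branch_ka)` events per site,
#' each event replacing the base uniformly among the alternatives that do
#' not create a stop codon. Multiple hits at a site are therefore possible,
#' so the Jukes-Cantor-corrected NG86 estimator is consistent for the
#' branch lengths. On sequences made of four-fold-degenerate codons the
#' third-position process is purely synonymous.
#'
#' @param cds Coding sequence, length divisible by 3, no internal stops.
#' @param branch_ks Expected substitutions per synonymous (third) position.
#' @param branch_ka Expected substitutions per nonsynonymous (first/second)
#'   position.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (the clade simulator relies on this to keep one global stream).
#' @return The evolved coding sequence (character scalar).
#' @export
evolve_cds <- function(cds, branch_ks, branch_ka = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (branch_ks < 0 || branch_ka < 0) {
    stop("branch lengths must be >= 0", call. = FALSE)
  }
  codons <- .split_codons(cds)
  .check_no_stops(codons, "cds")
  gc <- .genetic_code()
  nts <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(codons, "")), nrow = 3)
  n_codon <- ncol(mat)
  # events per position: rows 1-2 at branch_ka, row 3 at branch_ks
  nev <- matrix(stats::rpois(3 * n_codon,
                             lambda = rep(c(branch_ka, branch_ka, branch_ks),
                                          n_codon)),
                nrow = 3)
  hit <- which(nev > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(hit))) {
    pos <- hit[k, 1]; cod <- hit[k, 2]
    for (ev in seq_len(nev[pos, cod])) {
      cur <- paste0(mat[, cod], collapse = "")
      cand <- setdiff(nts, mat[pos, cod])
      ok <- vapply(cand, function(nt) {
        alt <- cur
        substr(alt, pos, pos) <- nt
        gc[[alt]] != "*"
      }, logical(1))
      cand <- cand[ok]
      if (length(cand) == 0) next  # cannot substitute without a stop
      mat[pos, cod] <- if (length(cand) == 1) cand else sample(cand, 1)
    }
  }
  paste0(as.vector(mat), collapse = "")
}

.evolve_set <- function(cds_vec, branch_ks, branch_ka) {
  vapply(cds_vec, evolve_cds, character(1),
         branch_ks = branch_ks, branch_ka = branch_ka, USE.NAMES = TRUE)
}

.random_spacer <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Assemble one species' genome from an ordered gene list.
# gene_tab: data.frame(gene_id, chrom_index); cds named by gene_id, already
# in gene order within chromosome.
.assemble_genome <- function(species, gene_ids, chrom_index, cds, cfg,
                             chrom_names) {
  telo_fwd <- strrep("TTTAGGG", cfg$telomere_repeats_per_end)
  telo_rev <- .revcomp(telo_fwd)
  genes <- list(); chroms <- setNames(character(length(chrom_names)),
                                      chrom_names)
  for (ci in seq_along(chrom_names)) {
    ids <- gene_ids[chrom_index == ci]
    pieces <- character(0)
    pos <- 1L
    pieces <- c(pieces, telo_fwd)
    pos <- pos + nchar(telo_fwd)
    rows <- vector("list", length(ids))
    for (gi in seq_along(ids)) {
      sp <- .random_spacer(cfg$intergenic_length)
      pieces <- c(pieces, sp)
      pos <- pos + nchar(sp)
      seq_g <- cds[[ids[gi]]]
      strand <- sample(c("+", "-"), 1)
      genomic <- if (strand == "+") seq_g else .revcomp(seq_g)
      pieces <- c(pieces, genomic)
      rows[[gi]] <- data.frame(
        gene_id = ids[gi], scaffold = chrom_names[ci], rank = gi - 1L,
        start = pos, end = pos + nchar(genomic) - 1L, strand = strand,
        stringsAsFactors = FALSE)
      pos <- pos + nchar(genomic)
    }
    pieces <- c(pieces, .random_spacer(cfg$intergenic_length), telo_rev)
    chroms[ci] <- paste0(pieces, collapse = "")
    genes[[ci]] <- do.call(rbind, rows)
  }
  genes <- do.call(rbind, genes[!vapply(genes, is.null, logical(1))])
  list(genes = genes, cds = cds[genes$gene_id], chromosomes = chroms)
}

#' Simulate a 4-species clade with a shared whole-genome duplication
#'
#' Generates genomes (gene models, CDS, chromosome sequences with planted
#' telomere arrays) for two outgroup species without the WGD and two
#' ingroup species sharing it, plus a complete truth log of WGD pairs,
#' ortholog pairs, tandem pairs, loss events and planted telomere counts.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_clade` with elements `species` (named list
#'   `outgroup1`, `outgroup2`, `ingroupA`, `ingroupB`; each has `genes`
#'   data frame, `cds` named vector, `chromosomes` named vector), `truth`
#'   (lists `wgd_pairs`, `ortholog_pairs`, `tandem_pairs`, `loss_events`,
#'   `telomeres` as data frames) and `config`.
#' @export
simulate_clade <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)
  r <- cfg$syn_rate
  ka_r <- cfg$syn_rate * cfg$ka_ks
  t_out2 <- cfg$speciation_ages[["outgroup2"]]
  t_out1 <- cfg$speciation_ages[["outgroup1"]]
  t_in <- cfg$speciation_ages[["ingroup"]]
  t_wgd <- cfg$wgd_age

  anc_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  anc <- setNames(vapply(anc_ids, function(i)
    .random_cds(cfg$codon_length, cfg$fourfold_only), character(1)), anc_ids)
  chrom_index <- sort(rep_len(seq_len(cfg$n_chromosomes), cfg$n_genes))

  ev <- function(set, dt) .evolve_set(set, branch_ks = r * dt,
                                      branch_ka = ka_r * dt)
  # root -> outgroup2 tip
  out2_cds <- ev(anc, t_out2)
  # root -> outgroup1 split node
  node1 <- ev(anc, t_out2 - t_out1)
  out1_cds <- ev(node1, t_out1)
  # node1 -> WGD node on the ingroup stem
  wgd_node <- ev(node1, t_out1 - t_wgd)
  # WGD: two subgenome copies, each evolves to the ingroup split
  subA_split <- ev(wgd_node, t_wgd - t_in)
  subB_split <- ev(wgd_node, t_wgd - t_in)
  # ingroup split -> two tip species, per subgenome copy
  tip <- list(
    ingroupA = list(A = ev(subA_split, t_in), B = ev(subB_split, t_in)),
    ingroupB = list(A = ev(subA_split, t_in), B = ev(subB_split, t_in)))

  loss_events <- list()
  surv <- list()  # surv[[species]][[subgenome]] logical per ancestral gene
  for (sp in c("ingroupA", "ingroupB")) {
    lost <- stats::runif(cfg$n_genes) < cfg$loss_prob
    on_b <- stats::runif(cfg$n_genes) < cfg$loss_bias
    keepA <- !(lost & !on_b)
    keepB <- !(lost & on_b)
    surv[[sp]] <- list(A = keepA, B = keepB)
    if (any(lost)) {
      loss_events[[sp]] <- data.frame(
        species = sp, ancestral_gene = anc_ids[lost],
        subgenome = ifelse(on_b[lost], "B", "A"), stringsAsFactors = FALSE)
    }
  }
  loss_events <- if (length(loss_events)) do.call(rbind, loss_events) else
    data.frame(species = character(0), ancestral_gene = character(0),
               subgenome = character(0))

  species <- list()
  tandem_pairs <- list()
  gene_id_of <- function(sp, anc, sub = NULL) {
    if (is.null(sub)) paste0(sp, "_", anc) else paste0(sp, "_", anc, "_", sub)
  }

  add_tandems <- function(ids, cds_set, sp) {
    keep_ids <- character(0)
    out_cds <- list()
    tp <- list()
    for (id in ids) {
      keep_ids <- c(keep_ids, id)
      out_cds[[id]] <- cds_set[[id]]
      if (stats::runif(1) < cfg$tandem_prob) {
        tid <- paste0(id, "_t1")
        # both copies diverge from the duplication event
        out_cds[[id]] <- evolve_cds(cds_set[[id]], r * cfg$tandem_age,
                                    ka_r * cfg$tandem_age)
        out_cds[[tid]] <- evolve_cds(cds_set[[id]], r * cfg$tandem_age,
                                     ka_r * cfg$tandem_age)
        keep_ids <- c(keep_ids, tid)
        tp[[length(tp) + 1L]] <- data.frame(
          species = sp, gene_a = id, gene_b = tid,
          age = cfg$tandem_age, stringsAsFactors = FALSE)
      }
    }
    list(ids = keep_ids, cds = out_cds,
         tandem = if (length(tp)) do.call(rbind, tp) else NULL)
  }

  # outgroups: one copy per ancestral gene
  for (sp in c("outgroup1", "outgroup2")) {
    src <- if (sp == "outgroup1") out1_cds else out2_cds
    ids <- gene_id_of(sp, anc_ids)
    cds_set <- setNames(as.list(src), ids)
    td <- add_tandems(ids, cds_set, sp)
    if (!is.null(td$tandem)) tandem_pairs[[sp]] <- td$tandem
    ci <- chrom_index[match(sub("_t1$", "", sub(paste0("^", sp, "_"), "",
                                                td$ids)), anc_ids)]
    chrom_names <- sprintf("%s_chr%02d", sp, seq_len(cfg$n_chromosomes))
    species[[sp]] <- .assemble_genome(sp, td$ids, ci,
                                      unlist(td$cds), cfg, chrom_names)
  }

  # ingroups: subgenome A on chromosomes 1..n, B on n+1..2n
  for (sp in c("ingroupA", "ingroupB")) {
    ids <- character(0); ci <- integer(0); cds_set <- list()
    for (sub in c("A", "B")) {
      keep <- surv[[sp]][[sub]]
      sub_ids <- gene_id_of(sp, anc_ids[keep], sub)
      ids <- c(ids, sub_ids)
      off <- if (sub == "A") 0L else cfg$n_chromosomes
      ci <- c(ci, chrom_index[keep] + off)
      cds_set[sub_ids] <- tip[[sp]][[sub]][keep]
    }
    td <- add_tandems(ids, cds_set, sp)
    if (!is.null(td$tandem)) tandem_pairs[[sp]] <- td$tandem
    parent <- sub("_t1$", "", td$ids)
    ci_full <- ci[match(parent, ids)]
    chrom_names <- sprintf("%s_chr%02d", sp, seq_len(2 * cfg$n_chromosomes))
    species[[sp]] <- .assemble_genome(sp, td$ids, ci_full,
                                      unlist(td$cds), cfg, chrom_names)
  }
  tandem_pairs <- if (length(tandem_pairs)) do.call(rbind, tandem_pairs) else
    data.frame(species = character(0), gene_a = character(0),
               gene_b = character(0), age = numeric(0))

  # truth: WGD pairs (both homoeologs survive within an ingroup species)
  wgd_pairs <- list()
  for (sp in c("ingroupA", "ingroupB")) {
    both <- surv[[sp]]$A & surv[[sp]]$B
    if (any(both)) {
      wgd_pairs[[sp]] <- data.frame(
        species = sp,
        gene_a = gene_id_of(sp, anc_ids[both], "A"),
        gene_b = gene_id_of(sp, anc_ids[both], "B"),
        age = t_wgd, stringsAsFactors = FALSE)
    }
  }
  wgd_pairs <- if (length(wgd_pairs)) do.call(rbind, wgd_pairs) else
    data.frame(species = character(0), gene_a = character(0),
               gene_b = character(0), age = numeric(0))

  # truth: ingroup ortholog pairs (same subgenome copy in both species)
  orth <- list()
  for (sub in c("A", "B")) {
    both <- surv$ingroupA[[sub]] & surv$ingroupB[[sub]]
    if (any(both)) {
      orth[[sub]] <- data.frame(
        species_a = "ingroupA", species_b = "ingroupB",
        gene_a = gene_id_of("ingroupA", anc_ids[both], sub),
        gene_b = gene_id_of("ingroupB", anc_ids[both], sub),
        age = t_in, stringsAsFactors = FALSE)
    }
  }
  orth$out <- data.frame(
    species_a = "ingroupA", species_b = "outgroup1",
    gene_a = gene_id_of("ingroupA",
                        anc_ids[surv$ingroupA$A], "A"),
    gene_b = gene_id_of("outgroup1", anc_ids[surv$ingroupA$A]),
    age = t_out1, stringsAsFactors = FALSE)
  ortholog_pairs <- do.call(rbind, orth)
  rownames(ortholog_pairs) <- NULL

  telo <- do.call(rbind, lapply(names(species), function(sp) {
    chr <- species[[sp]]$chromosomes
    data.frame(species = sp, scaffold = names(chr),
               length = nchar(chr),
               units_per_end = cfg$telomere_repeats_per_end,
               stringsAsFactors = FALSE)
  }))

  structure(list(
    species = species,
    truth = list(wgd_pairs = wgd_pairs, ortholog_pairs = ortholog_pairs,
                 tandem_pairs = tandem_pairs, loss_events = loss_events,
                 telomeres = telo),
    config = cfg), class = "sim_clade")
}

#' @export
print.sim_clade <- function(x, ...) {
  cat("Simulated clade (2 outgroups + 2 WGD ingroups)\n")
  for (sp in names(x$species)) {
    cat(sprintf("  %-10s %4d genes on %d chromosomes\n", sp,
                nrow(x$species[[sp]]$genes),
                length(x$species[[sp]]$chromosomes)))
  }
  cat(sprintf("  truth: %d WGD pairs, %d ortholog pairs, %d tandem pairs, %d losses\n",
              nrow(x$truth$wgd_pairs), nrow(x$truth$ortholog_pairs),
              nrow(x$truth$tandem_pairs), nrow(x$truth$loss_events)))
  invisible(x)
}

#' Pangene copy-number table from a simulated clade
#'
#' One row per ancestral gene with the number of surviving copies (including
#' tandem duplicates) in each of the four species — the synthetic analogue
#' of a syntenic pangene table over two outgroups and two WGD ingroups.
#'
#' @param sim A `sim_clade` object.
#' @return Data frame: `pangene`, `outgroup1`, `outgroup2`, `ingroupA`,
#'   `ingroupB`.
#' @export
pangene_table <- function(sim) {
  stopifnot(inherits(sim, "sim_clade"))
  anc_ids <- sprintf("g%04d", seq_len(sim$config$n_genes))
  counts <- sapply(names(sim$species), function(sp) {
    ids <- sim$species[[sp]]$genes$gene_id
    anc_of <- sub("_t1$", "", sub(paste0("^", sp, "_"), "", ids))
    anc_of <- sub("_[AB]$", "", anc_of)
    tabulate(match(anc_of, anc_ids), nbins = length(anc_ids))
  })
  data.frame(pangene = anc_ids,
             outgroup1 = counts[, "outgroup1"],
             outgroup2 = counts[, "outgroup2"],
             ingroupA = counts[, "ingroupA"],
             ingroupB = counts[, "ingroupB"],
             stringsAsFactors = FALSE)
}
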