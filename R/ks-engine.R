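# Nei-Gojobori (1986) Ka/Ks estimation over protein-guided codon alignments.
#
# Site counts are fractional: each codon position contributes the fraction of
# possible single-nucleotide changes that are synonymous. Mutations to stop
# codons count as nonsynonymous so that S + N = 3 x compared columns exactly.
# Multi-substitution codons are resolved by averaging over all minimal
# substitution pathways, excluding pathways that pass through a stop codon.

.wgdkit_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

.all_codons <- function() {
  nts <- c("A", "C", "G", "T")
  as.vector(outer(outer(nts, nts, paste0), nts, paste0))
}

# Fractional synonymous site count per codon (vector of 64, named).
# Stop codons get NA (they never appear in valid input).
.syn_sites_table <- function() {
  if (!is.null(.wgdkit_env$syn_sites)) return(.wgdkit_env$syn_sites)
  gc <- .genetic_code()
  codons <- .all_codons()
  nts <- c("A", "C", "G", "T")
  s <- setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    aa <- gc[[cod]]
    if (aa == "*") { s[cod] <- NA_real_; next }
    tot <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- nt
        if (gc[[alt]] == aa) tot <- tot + 1  # change to stop counts nonsyn
      }
    }
    s[cod] <- tot / 3
  }
  .wgdkit_env$syn_sites <- s
  s
}

# Pathway-averaged (Sd, Nd) for every ordered codon pair, as two 64x64
# matrices. NA where all minimal pathways pass through a stop codon (or a
# codon itself is a stop).
.pathway_tables <- function() {
  if (!is.null(.wgdkit_env$sd_table)) {
    return(list(sd = .wgdkit_env$sd_table, nd = .wgdkit_env$nd_table))
  }
  gc <- .genetic_code()
  codons <- .all_codons()
  n <- length(codons)
  sd_tab <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd_tab <- sd_tab
  perms <- list(
    list(1L), list(2L), list(3L),
    NULL  # filled per diff set below
  )
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- codons[i]; b <- codons[j]
      if (gc[[a]] == "*" || gc[[b]] == "*") next
      diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      if (length(diffs) == 0) { sd_tab[i, j] <- 0; nd_tab[i, j] <- 0; next }
      orders <- .permutations(diffs)
      sds <- ndd <- numeric(0)
      for (ord in orders) {
        cur <- a
        s_cnt <- n_cnt <- 0
        ok <- TRUE
        for (pos in ord) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(b, pos, pos)
          if (gc[[nxt]] == "*") { ok <- FALSE; break }
          if (gc[[nxt]] == gc[[cur]]) s_cnt <- s_cnt + 1 else n_cnt <- n_cnt + 1
          cur <- nxt
        }
        if (ok) { sds <- c(sds, s_cnt); ndd <- c(ndd, n_cnt) }
      }
      if (length(sds) > 0) {
        sd_tab[i, j] <- mean(sds)
        nd_tab[i, j] <- mean(ndd)
      }
    }
  }
  .wgdkit_env$sd_table <- sd_tab
  .wgdkit_env$nd_table <- nd_tab
  list(sd = sd_tab, nd = nd_tab)
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

.split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length (", nchar(cds), ") is not a multiple of 3", call. = FALSE)
  }
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

.check_no_stops <- function(codons, label = "sequence") {
  gc <- .genetic_code()
  valid <- codons %in% names(gc)
  aa <- rep(NA_character_, length(codons))
  aa[valid] <- gc[codons[valid]]
  if (any(aa == "*", na.rm = TRUE)) {
    stop("internal stop codon in ", label, " at codon ",
         which(aa == "*")[1], call. = FALSE)
  }
  invisible(aa)
}

#' Align two coding sequences codon-by-codon via their proteins
#'
#' Translates both CDS, aligns the proteins globally (Needleman-Wunsch with
#' affine gaps via [Biostrings::pairwiseAlignment()]), and back-translates
#' the alignment to codons so that every gap is a whole triplet.
#'
#' @param cds_a,cds_b Coding sequences (character or `DNAString`), lengths
#'   divisible by 3, no internal stop codons.
#' @param substitution_matrix Protein scoring matrix name (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return An object of class `codon_alignment`: a list with character
#'   vectors `codons_a` and `codons_b` of equal length (gap codons `"---"`)
#'   and a logical `complete` flag per column (TRUE when neither side is a
#'   gap).
#' @export
align_codon_pair <- function(cds_a, cds_b, substitution_matrix = "BLOSUM62",
                             gap_opening = 10, gap_extension = 0.5) {
  ca <- .split_codons(cds_a)
  cb <- .split_codons(cds_b)
  aa_a <- .check_no_stops(ca, "cds_a")
  aa_b <- .check_no_stops(cb, "cds_b")
  aa_a[is.na(aa_a)] <- "X"  # ambiguous codons
  aa_b[is.na(aa_b)] <- "X"
  if (is.character(substitution_matrix) &&
      length(substitution_matrix) == 1) {
    key <- paste0("submat_", substitution_matrix)
    if (is.null(.wgdkit_env[[key]])) {
      e <- new.env()
      utils::data(list = substitution_matrix, package = "Biostrings",
                  envir = e)
      .wgdkit_env[[key]] <- e[[substitution_matrix]]
    }
    substitution_matrix <- .wgdkit_env[[key]]
  }
  aln <- Biostrings::pairwiseAlignment(
    paste(aa_a, collapse = ""), paste(aa_b, collapse = ""), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out_a <- character(length(sa))
  out_b <- character(length(sb))
  ia <- ib <- 0L
  for (k in seq_along(sa)) {
    if (sa[k] == "-") out_a[k] <- "---" else { ia <- ia + 1L; out_a[k] <- ca[ia] }
    if (sb[k] == "-") out_b[k] <- "---" else { ib <- ib + 1L; out_b[k] <- cb[ib] }
  }
  structure(list(codons_a = out_a, codons_b = out_b,
                 complete = out_a != "---" & out_b != "---"),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$codons_a), "columns,",
      sum(x$complete), "complete\n")
  invisible(x)
}

.as_codon_alignment <- function(aln) {
  if (inherits(aln, "codon_alignment")) return(aln)
  if (is.list(aln) && !is.null(aln$codons_a) && !is.null(aln$codons_b)) {
    aln$complete <- aln$codons_a != "---" & aln$codons_b != "---"
    class(aln) <- "codon_alignment"
    return(aln)
  }
  stop("not a codon_alignment", call. = FALSE)
}

#' Nei-Gojobori (1986) Ka/Ks from a codon alignment
#'
#' Counts fractional synonymous (S) and nonsynonymous (N) sites averaged
#' between the two sequences, pathway-averaged synonymous (Sd) and
#' nonsynonymous (Nd) differences (minimal substitution pathways through
#' stop codons excluded; columns where all pathways are blocked, or with a
#' gap or non-ACGT base, are dropped from the comparison), and applies the
#' Jukes-Cantor correction `d = -(3/4) log(1 - 4 p / 3)` to the proportions
#' `ps = Sd/S` and `pn = Nd/N`.
#'
#' @param aln A `codon_alignment` from [align_codon_pair()], or a list with
#'   `codons_a`/`codons_b`.
#' @return A list of class `ks_estimate` with fields `ka`, `ks`, `S`, `N`,
#'   `Sd`, `Nd`, `ps`, `pn`, `ncolumns` (compared columns) and `saturated`
#'   (TRUE when `ps >= 3/4` or `pn >= 3/4`; the affected rate is `NA`).
#' @export
ng86 <- function(aln) {
  aln <- .as_codon_alignment(aln)
  syn <- .syn_sites_table()
  pt <- .pathway_tables()
  a <- aln$codons_a
  b <- aln$codons_b
  keep <- aln$complete &
    !grepl("[^ACGT]", a) & !grepl("[^ACGT]", b)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop("no comparable codon columns", call. = FALSE)
  sd_col <- pt$sd[cbind(a, b)]
  nd_col <- pt$nd[cbind(a, b)]
  usable <- !is.na(sd_col)  # drops stop codons and all-blocked pathways
  a <- a[usable]; b <- b[usable]
  sd_col <- sd_col[usable]; nd_col <- nd_col[usable]
  L <- length(a)
  if (L == 0) stop("no comparable codon columns", call. = FALSE)
  S <- sum((syn[a] + syn[b]) / 2)
  N <- 3 * L - S
  Sd <- sum(sd_col)
  Nd <- sum(nd_col)
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  structure(list(
    ka = jc(pn), ks = jc(ps),
    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
    ncolumns = L,
    saturated = ps >= 3 / 4 || pn >= 3 / 4
  ), class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("NG86 estimate over %d codon columns\n", x$ncolumns))
  cat(sprintf("  Ks = %s  (Sd = %.2f / S = %.2f)\n",
              format(x$ks, digits = 4), x$Sd, x$S))
  cat(sprintf("  Ka = %s  (Nd = %.2f / N = %.2f)\n",
              format(x$ka, digits = 4), x$Nd, x$N))
  if (x$saturated) cat("  [saturated: Jukes-Cantor correction undefined]\n")
  invisible(x)
}

#' Batch Ka/Ks over a pair list
#'
#' Aligns and estimates each gene pair with [align_codon_pair()] + [ng86()].
#' Genes whose CDS length is not a multiple of 3, or that contain internal
#' stops, yield an `NA` row with a warning rather than aborting the batch.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param cds Named character vector (or `DNAStringSet`) of CDS, names
#'   matching gene ids.
#' @param ... Passed to [align_codon_pair()].
#' @return Data frame: `gene_a`, `gene_b`, `ka`, `ks`, `S`, `N`, `Sd`,
#'   `Nd`, `saturated`.
#' @export
ks_batch <- function(pairs, cds, ...) {
  cds <- setNames(as.character(cds), names(cds))
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!ga %in% names(cds) || !gb %in% names(cds)) {
      stop("unknown gene id in pair list: ",
           if (ga %in% names(cds)) gb else ga, call. = FALSE)
    }
    est <- tryCatch({
      ng86(align_codon_pair(cds[[ga]], cds[[gb]], ...))
    }, error = function(e) {
      warning("pair ", ga, "/", gb, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    res[[i]] <- if (is.null(est)) {
      data.frame(gene_a = ga, gene_b = gb, ka = NA_real_, ks = NA_real_,
                 S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                 saturated = NA)
    } else {
      data.frame(gene_a = ga, gene_b = gb, ka = est$ka, ks = est$ks,
                 S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
                 saturated = est$saturated)
    }
  }
  do.call(rbind, res)
}
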