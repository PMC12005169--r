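# Post-WGD gene retention and loss: fractionation profiles of a duplicated
# genome against an unduplicated reference in 100-gene windows, a sign test
# for fractionation bias between the two homoeologous scaffolds, retention
# classification of pangene copy-number rows over (2 outgroups, 2 WGD
# ingroups), and one-sided Fisher/hypergeometric GO over-representation.

#' Fractionation profile in gene windows against a reference
#'
#' For each reference scaffold, the two target scaffolds carrying the most
#' mapped syntenic copies are taken as the homoeologs (ties broken by
#' scaffold name); for each consecutive window of `window` reference genes
#' the retention percentage on each homoeolog is the fraction of window
#' genes with a mapped copy on that scaffold. A trailing window shorter
#' than `window` genes is reported and flagged `truncated`.
#'
#' @param ref_ranks [gene_ranks()] table of the (unduplicated) reference.
#' @param ortholog_map Data frame `ref_gene`, `target_scaffold`: one row
#'   per surviving syntenic copy of a reference gene in the duplicated
#'   genome.
#' @param window Window size in reference genes (default 100).
#' @return Data frame of class `fractionation_windows`: `ref_scaffold`,
#'   `window_index`, `n_genes`, `homoeolog1`, `homoeolog2`, `retention1`,
#'   `retention2` (percent), `truncated`.
#' @export
fractionation_profile <- function(ref_ranks, ortholog_map, window = 100) {
  stopifnot(all(c("ref_gene", "target_scaffold") %in% names(ortholog_map)))
  out <- list()
  for (scaf in unique(ref_ranks$scaffold)) {
    g <- ref_ranks[ref_ranks$scaffold == scaf, ]
    g <- g[order(g$rank), ]
    maps <- ortholog_map[ortholog_map$ref_gene %in% g$gene_id, ]
    if (nrow(maps) == 0) next
    tab <- sort(table(maps$target_scaffold), decreasing = TRUE)
    # top-2 by mapped-gene count, ties by name sort
    ord <- order(-as.vector(tab), names(tab))
    homs <- names(tab)[ord][seq_len(min(2, length(tab)))]
    if (length(homs) == 1) homs <- c(homs, NA_character_)
    n <- nrow(g)
    starts <- seq(1L, n, by = as.integer(window))
    for (wi in seq_along(starts)) {
      idx <- starts[wi]:min(starts[wi] + window - 1L, n)
      ids <- g$gene_id[idx]
      ret <- vapply(homs, function(h) {
        if (is.na(h)) return(NA_real_)
        on_h <- unique(maps$ref_gene[maps$target_scaffold == h])
        100 * sum(ids %in% on_h) / length(ids)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        ref_scaffold = scaf, window_index = wi - 1L, n_genes = length(idx),
        homoeolog1 = homs[1], homoeolog2 = homs[2],
        retention1 = ret[1], retention2 = ret[2],
        truncated = length(idx) < window, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fractionation_windows", "data.frame")
  res
}

#' Sign test for fractionation bias between homoeologs
#'
#' Two-sided exact sign test on the per-window retention differences
#' (`retention1 - retention2`); windows with zero difference are dropped.
#' A small p-value indicates biased fractionation (one subgenome losing
#' more genes), the signature of allopolyploidy.
#'
#' @param windows Output of [fractionation_profile()].
#' @return List of class `fractionation_bias`: `p_value`, `mean1`, `mean2`
#'   (mean retention percent per homoeolog), `n_windows`, `n_nonzero`,
#'   `n_positive`.
#' @export
fractionation_bias_test <- function(windows) {
  w <- windows[!is.na(windows$retention1) & !is.na(windows$retention2), ]
  if (nrow(w) < 5) stop("need at least 5 windows", call. = FALSE)
  d <- w$retention1 - w$retention2
  nz <- d[d != 0]
  p <- if (length(nz) == 0) 1 else
    stats::binom.test(sum(nz > 0), length(nz), p = 0.5,
                      alternative = "two.sided")$p.value
  structure(list(p_value = p, mean1 = mean(w$retention1),
                 mean2 = mean(w$retention2), n_windows = nrow(w),
                 n_nonzero = length(nz), n_positive = sum(nz > 0)),
            class = "fractionation_bias")
}

#' @export
print.fractionation_bias <- function(x, ...) {
  cat(sprintf("Fractionation bias sign test over %d windows\n", x$n_windows))
  cat(sprintf("  mean retention: homoeolog1 %.1f%%, homoeolog2 %.1f%%\n",
              x$mean1, x$mean2))
  cat(sprintf("  %d/%d non-zero differences positive; p = %.4g\n",
              x$n_positive, x$n_nonzero, x$p_value))
  invisible(x)
}

#' Classify pangene rows by post-WGD retention pattern
#'
#' Keeps pangenes that are single copy in both outgroups and single or
#' double copy in both WGD ingroups, then classifies: copy pattern (2,2)
#' in the ingroups is `retained_both`, (1,1) `single_both`, (2,1)
#' `retained_A_only`, (1,2) `retained_B_only`; rows failing the filter are
#' `filtered_out`. The class totals form an exact partition of the input.
#'
#' @param rows Data frame with integer copy-count columns `outgroup1`,
#'   `outgroup2`, `ingroupA`, `ingroupB` (extra columns carried through).
#' @return List of class `retention_classes`: `rows` (input plus `class`
#'   factor), `totals` (named vector over the five classes).
#' @export
classify_retention <- function(rows) {
  need <- c("outgroup1", "outgroup2", "ingroupA", "ingroupB")
  stopifnot(all(need %in% names(rows)))
  cc <- as.matrix(rows[, need])
  if (any(cc < 0) || any(cc != round(cc))) {
    stop("copy counts must be non-negative integers", call. = FALSE)
  }
  pass <- cc[, "outgroup1"] == 1 & cc[, "outgroup2"] == 1 &
    cc[, "ingroupA"] %in% c(1, 2) & cc[, "ingroupB"] %in% c(1, 2)
  cls <- rep("filtered_out", nrow(rows))
  a <- cc[, "ingroupA"]; b <- cc[, "ingroupB"]
  cls[pass & a == 2 & b == 2] <- "retained_both"
  cls[pass & a == 1 & b == 1] <- "single_both"
  cls[pass & a == 2 & b == 1] <- "retained_A_only"
  cls[pass & a == 1 & b == 2] <- "retained_B_only"
  lv <- c("retained_both", "single_both", "retained_A_only",
          "retained_B_only", "filtered_out")
  rows$class <- factor(cls, levels = lv)
  structure(list(rows = rows, totals = table(rows$class)),
            class = "retention_classes")
}

#' @export
print.retention_classes <- function(x, ...) {
  cat("Pangene retention classification:\n")
  print(x$totals)
  invisible(x)
}

#' GO over-representation by one-sided Fisher exact test
#'
#' Classic per-term Fisher test (hypergeometric upper tail) for
#' over-representation of each GO term in a gene group relative to a
#' universe, with no hierarchy weighting and no multiple-testing
#' correction (p-values are reported raw). Expected count per term is
#' `total * |group| / |universe|`.
#'
#' @param group Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of gene ids.
#' @param gene2go Data frame `gene_id`, `go_id` (optionally `term`).
#' @return Data frame sorted by p-value: `go_id`, `term`, `total` (genes
#'   annotated in universe), `count` (in group), `expected`, `p_value`.
#' @export
go_enrichment <- function(group, universe, gene2go) {
  stopifnot(all(c("gene_id", "go_id") %in% names(gene2go)))
  group <- unique(group)
  universe <- unique(universe)
  if (length(group) == 0) stop("empty gene group", call. = FALSE)
  if (!all(group %in% universe)) {
    stop("group must be a subset of the universe", call. = FALSE)
  }
  ann <- gene2go[gene2go$gene_id %in% universe, , drop = FALSE]
  if (nrow(ann) == 0) stop("annotation map covers no universe gene",
                           call. = FALSE)
  terms <- unique(ann$go_id)
  n_u <- length(universe)
  n_g <- length(group)
  res <- lapply(terms, function(go) {
    genes <- unique(ann$gene_id[ann$go_id == go])
    total <- length(genes)
    count <- sum(genes %in% group)
    # P(X >= count), X ~ Hypergeom(total annotated, n_u - total, n_g)
    p <- stats::phyper(count - 1, total, n_u - total, n_g,
                       lower.tail = FALSE)
    term <- if ("term" %in% names(ann))
      ann$term[match(go, ann$go_id)] else NA_character_
    data.frame(go_id = go, term = term, total = total, count = count,
               expected = total * n_g / n_u, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(res$p_value, res$go_id), ]
  rownames(res) <- NULL
  res
}
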