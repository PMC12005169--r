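# Collinearity-based classification of duplicate gene pairs. Anchors
# (similarity hits between genes with known gene-order ranks) are chained
# into collinear blocks per scaffold pair by dynamic programming; pairs in
# block anchor sets are WGD/syntenic duplicates, remaining same-scaffold
# pairs are tandem or proximal by rank distance, and the rest dispersed.
# Block depth over an unduplicated reference gives the syntenic quota
# (2:1 for a once-duplicated genome).

#' Gene-order ranks from a gene-model table
#'
#' @param genes Data frame with columns `gene_id`, `scaffold`, `start` (or
#'   a precomputed `rank`).
#' @return Data frame `gene_id`, `scaffold`, `rank` (0-based ordinal of the
#'   gene start within its scaffold, strand-ignorant).
#' @export
gene_ranks <- function(genes) {
  stopifnot(all(c("gene_id", "scaffold") %in% names(genes)))
  if (!"start" %in% names(genes) && "rank" %in% names(genes)) {
    return(genes[, c("gene_id", "scaffold", "rank")])
  }
  out <- do.call(rbind, lapply(split(genes, genes$scaffold), function(g) {
    g <- g[order(g$start), ]
    data.frame(gene_id = g$gene_id, scaffold = g$scaffold,
               rank = seq_len(nrow(g)) - 1L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Chain similarity hits into collinear blocks
#'
#' Within each scaffold pair, anchors (hits with gene-order ranks on both
#' sides) are chained by dynamic programming: chain score =
#' `anchor_reward` per anchor minus `gap_penalty` per skipped rank unit on
#' either scaffold, with consecutive anchors at most `max_gap` ranks apart
#' on each scaffold. Both orientations (rank order preserved or reversed on
#' the second scaffold) are chained; blocks are extracted greedily by
#' descending chain score, each anchor belonging to at most one block, and
#' chains shorter than `min_block` anchors are discarded. Ties between
#' equal-score chains are broken toward the smaller starting rank.
#'
#' @param hits Data frame with `gene_a`, `gene_b` (and optionally `score`).
#' @param ranks_a,ranks_b Rank tables from [gene_ranks()] for the two
#'   genomes (pass the same table twice for within-genome chaining).
#' @param min_block Minimum anchors per reported block (default 5; use 30
#'   for plotting-scale macro-synteny).
#' @param max_gap Maximum rank gap between consecutive anchors.
#' @param anchor_reward,gap_penalty DP scoring.
#' @param self If TRUE (within-genome mode), anchors of a scaffold against
#'   itself on the diagonal are ignored.
#' @return Data frame of class `synteny_blocks`: one row per anchor with
#'   `block`, `scaffold_a`, `scaffold_b`, `orientation` (`"same"` or
#'   `"inverted"`), `gene_a`, `gene_b`, `rank_a`, `rank_b`, `score`
#'   (block chain score).
#' @export
chain_anchors <- function(hits, ranks_a, ranks_b = ranks_a, min_block = 5,
                          max_gap = 25, anchor_reward = 10, gap_penalty = 1,
                          self = identical(ranks_a, ranks_b)) {
  stopifnot(min_block >= 2, max_gap >= 1)
  ia <- match(hits$gene_a, ranks_a$gene_id)
  ib <- match(hits$gene_b, ranks_b$gene_id)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- c(hits$gene_a[is.na(ia)], hits$gene_b[is.na(ib)])
    stop("hit references unknown gene(s): ",
         paste(utils::head(unique(bad), 5), collapse = ", "), call. = FALSE)
  }
  anc <- data.frame(gene_a = hits$gene_a, gene_b = hits$gene_b,
                    scaffold_a = ranks_a$scaffold[ia],
                    scaffold_b = ranks_b$scaffold[ib],
                    rank_a = ranks_a$rank[ia], rank_b = ranks_b$rank[ib],
                    stringsAsFactors = FALSE)
  if (self) {
    anc <- anc[!(anc$scaffold_a == anc$scaffold_b &
                   anc$rank_a == anc$rank_b), , drop = FALSE]
    # canonical orientation so each scaffold pair is chained once
    swap <- anc$scaffold_a > anc$scaffold_b |
      (anc$scaffold_a == anc$scaffold_b & anc$rank_a > anc$rank_b)
    if (any(swap)) {
      anc[swap, c("gene_a", "gene_b", "scaffold_a", "scaffold_b",
                  "rank_a", "rank_b")] <-
        anc[swap, c("gene_b", "gene_a", "scaffold_b", "scaffold_a",
                    "rank_b", "rank_a")]
    }
  }
  out <- list()
  block_id <- 0L
  for (key in unique(paste(anc$scaffold_a, anc$scaffold_b, sep = "\r"))) {
    sub <- anc[paste(anc$scaffold_a, anc$scaffold_b, sep = "\r") == key, ,
               drop = FALSE]
    sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
    used <- rep(FALSE, nrow(sub))
    repeat {
      avail <- which(!used)
      if (length(avail) < min_block) break
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- .best_chain(sub$rank_a[avail], sub$rank_b[avail],
                          orient, max_gap, anchor_reward, gap_penalty)
        if (!is.null(ch) &&
            (is.null(best) || ch$score > best$score ||
             (ch$score == best$score && min(sub$rank_a[avail][ch$idx]) <
                min(sub$rank_a[avail][best$idx])))) {
          best <- ch
          best$orientation <- orient
        }
      }
      if (is.null(best) || length(best$idx) < min_block) break
      take <- avail[best$idx]
      block_id <- block_id + 1L
      blk <- sub[take, , drop = FALSE]
      blk$block <- block_id
      blk$orientation <- best$orientation
      blk$score <- best$score
      out[[length(out) + 1L]] <- blk
      used[take] <- TRUE
    }
  }
  if (length(out) == 0) {
    res <- data.frame(block = integer(0), scaffold_a = character(0),
                      scaffold_b = character(0), orientation = character(0),
                      gene_a = character(0), gene_b = character(0),
                      rank_a = integer(0), rank_b = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[, c("block", "scaffold_a", "scaffold_b", "orientation",
                   "gene_a", "gene_b", "rank_a", "rank_b", "score")]
    rownames(res) <- NULL
  }
  class(res) <- c("synteny_blocks", "data.frame")
  res
}

# Best single chain over anchors (rank_a sorted ascending on input order).
# "same": rank_b strictly increasing; "inverted": strictly decreasing.
# O(n^2) DP; returns list(idx, score) in rank_a order, or NULL.
.best_chain <- function(ra, rb, orientation, max_gap, anchor_reward,
                        gap_penalty) {
  n <- length(ra)
  if (n == 0) return(NULL)
  rb_eff <- if (orientation == "inverted") -rb else rb
  score <- rep(anchor_reward, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- rb_eff[i] - rb_eff[j]
      if (da < 1 || db < 1 || da > max_gap || db > max_gap) next
      cand <- score[j] + anchor_reward - gap_penalty * ((da - 1) + (db - 1))
      if (cand > score[i] ||
          (cand == score[i] && !is.na(prev[i]) && j < prev[i])) {
        score[i] <- cand
        prev[i] <- j
      }
    }
  }
  end <- which.max(score)  # ties: first (smallest ending rank_a)
  idx <- end
  while (!is.na(prev[idx[1]])) idx <- c(prev[idx[1]], idx)
  list(idx = idx, score = score[end])
}

#' Classify duplicate gene pairs by mechanism
#'
#' Applies the precedence wgd > tandem > proximal > dispersed: a pair in a
#' collinear block's anchor set is `wgd`; otherwise a same-scaffold pair
#' with gene-rank distance at most `tandem_gap` is `tandem`, at most
#' `proximal_gap` is `proximal`; everything else is `dispersed`. Each
#' unordered pair is classified exactly once.
#'
#' @param hits Data frame with `gene_a`, `gene_b` (deduplicated pairs, e.g.
#'   from [read_hit_table()]).
#' @param ranks A [gene_ranks()] table covering all genes in `hits`.
#' @param blocks Blocks from [chain_anchors()] on the same hits/ranks.
#' @param tandem_gap,proximal_gap Rank-distance thresholds (defaults 1 and
#'   10).
#' @return Data frame `gene_a`, `gene_b`, `class` (factor with levels
#'   `wgd`, `tandem`, `proximal`, `dispersed`), `block` (NA unless `wgd`).
#' @export
classify_duplicates <- function(hits, ranks, blocks, tandem_gap = 1,
                                proximal_gap = 10) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  hk <- key(hits$gene_a, hits$gene_b)
  dup <- !duplicated(hk)
  hits <- hits[dup, , drop = FALSE]
  hk <- hk[dup]
  bk <- if (nrow(blocks)) key(blocks$gene_a, blocks$gene_b) else character(0)
  block_of <- if (nrow(blocks)) blocks$block[match(hk, bk)] else
    rep(NA_integer_, length(hk))
  ia <- match(hits$gene_a, ranks$gene_id)
  ib <- match(hits$gene_b, ranks$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("pair references unknown gene", call. = FALSE)
  same_scaf <- ranks$scaffold[ia] == ranks$scaffold[ib]
  dist <- abs(ranks$rank[ia] - ranks$rank[ib])
  cls <- rep("dispersed", nrow(hits))
  cls[same_scaf & dist <= proximal_gap] <- "proximal"
  cls[same_scaf & dist <= tandem_gap] <- "tandem"
  cls[!is.na(block_of)] <- "wgd"
  data.frame(gene_a = hits$gene_a, gene_b = hits$gene_b,
             class = factor(cls, levels = c("wgd", "tandem", "proximal",
                                            "dispersed")),
             block = ifelse(cls == "wgd", block_of, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Syntenic depth of a duplicated genome over a reference
#'
#' For each reference gene, depth = number of collinear blocks whose
#' reference-side rank span covers the gene's rank. The modal depth is the
#' syntenic quota (2 for a once-duplicated query against an unduplicated
#' reference, i.e. the 2:1 ratio).
#'
#' @param blocks Blocks from [chain_anchors()] with the reference genome on
#'   the `a` side.
#' @param ref_ranks [gene_ranks()] for the reference genome.
#' @return List of class `syntenic_depth`: `depth` (per reference gene),
#'   `histogram` (table of depths), `modal_depth`.
#' @export
syntenic_depth_ratio <- function(blocks, ref_ranks) {
  depth <- setNames(rep(0L, nrow(ref_ranks)), ref_ranks$gene_id)
  if (nrow(blocks)) {
    for (b in split(blocks, blocks$block)) {
      scaf <- b$scaffold_a[1]
      lo <- min(b$rank_a); hi <- max(b$rank_a)
      cover <- ref_ranks$scaffold == scaf & ref_ranks$rank >= lo &
        ref_ranks$rank <= hi
      depth[cover] <- depth[cover] + 1L
    }
  }
  hist <- table(depth)
  modal <- as.integer(names(hist)[which.max(hist)])
  structure(list(depth = depth, histogram = hist, modal_depth = modal),
            class = "syntenic_depth")
}

#' @export
print.syntenic_depth <- function(x, ...) {
  cat("Syntenic depth over reference genes (modal depth ",
      x$modal_depth, "):\n", sep = "")
  print(x$histogram)
  invisible(x)
}
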