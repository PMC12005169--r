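# Anchor chaining, duplicate classification, syntenic depth.

mk_ranks <- function(n, scaffold = "s1", prefix = "g") {
  data.frame(gene_id = paste0(prefix, seq_len(n)), scaffold = scaffold,
             rank = seq_len(n) - 1L, stringsAsFactors = FALSE)
}

test_that("perfectly collinear anchors form one block in the same
          orientation", {
  ra <- mk_ranks(10, "a1", "a")
  rb <- mk_ranks(10, "b1", "b")
  hits <- data.frame(gene_a = ra$gene_id, gene_b = rb$gene_id)
  blocks <- chain_anchors(hits, ra, rb, min_block = 5, self = FALSE)
  expect_equal(length(unique(blocks$block)), 1)
  expect_equal(nrow(blocks), 10)
  expect_equal(unique(blocks$orientation), "same")
})

test_that("an inversion yields two blocks of opposite orientation", {
  ra <- mk_ranks(12, "a1", "a")
  rb <- mk_ranks(12, "b1", "b")
  # first 6 collinear; last 6 reverse-ordered on scaffold b
  rb$rank <- c(0:5, 11:6)
  hits <- data.frame(gene_a = ra$gene_id, gene_b = rb$gene_id)
  # max_gap below the breakpoint jump so the two segments cannot merge
  blocks <- chain_anchors(hits, ra, rb, min_block = 5, max_gap = 3,
                          self = FALSE)
  expect_equal(length(unique(blocks$block)), 2)
  orient <- tapply(blocks$orientation, blocks$block, unique)
  expect_setequal(unname(orient), c("same", "inverted"))
  expect_equal(as.vector(table(blocks$block)), c(6L, 6L))
})

test_that("fewer anchors than min_block yields no blocks", {
  ra <- mk_ranks(3, "a1", "a")
  rb <- mk_ranks(3, "b1", "b")
  hits <- data.frame(gene_a = ra$gene_id, gene_b = rb$gene_id)
  blocks <- chain_anchors(hits, ra, rb, min_block = 5, self = FALSE)
  expect_equal(nrow(blocks), 0)
})

test_that("unknown gene ids are rejected with the offending id", {
  ra <- mk_ranks(5, "a1", "a")
  hits <- data.frame(gene_a = c("a1", "zz9"), gene_b = c("a2", "a3"))
  expect_error(chain_anchors(hits, ra, ra), "zz9")
})

test_that("chaining DP matches exhaustive enumeration on random anchor
          sets of size <= 10", {
  set.seed(5)
  for (case in 1:40) {
    n <- sample(4:10, 1)
    ra <- sample(0:14, n)
    rb <- sample(0:14, n)
    ranks_a <- data.frame(gene_id = paste0("a", 1:n), scaffold = "s1",
                          rank = ra)
    ranks_b <- data.frame(gene_id = paste0("b", 1:n), scaffold = "s2",
                          rank = rb)
    hits <- data.frame(gene_a = ranks_a$gene_id, gene_b = ranks_b$gene_id)
    max_gap <- sample(c(3, 8, 25), 1)
    blocks <- chain_anchors(hits, ranks_a, ranks_b, min_block = 2,
                            max_gap = max_gap, self = FALSE)
    oracle <- oracle_best_chain_score(ra, rb, max_gap = max_gap,
                                      min_block = 2)
    if (nrow(blocks) == 0) {
      expect_true(!is.finite(oracle) || oracle < 2 * 10)
    } else {
      top <- max(blocks$score)
      expect_equal(top, oracle)
    }
  }
})

test_that("no anchor belongs to two blocks and orientation matches anchor
          monotonicity", {
  sim <- shared_sim()
  cds <- sim$species$ingroupA$cds
  ranks <- gene_ranks(sim$species$ingroupA$genes)
  hits <- synthetic_hits(cds)
  pairs <- filter_hits(hits[, c("qseqid", "sseqid", "evalue", "bitscore")],
                       evalue_max = 1, top_n = 5)
  blocks <- chain_anchors(pairs, ranks, ranks, self = TRUE)
  anchor_key <- paste(pmin(blocks$gene_a, blocks$gene_b),
                      pmax(blocks$gene_a, blocks$gene_b))
  expect_false(any(duplicated(anchor_key)))
  for (b in split(blocks, blocks$block)) {
    b <- b[order(b$rank_a), ]
    expect_true(all(diff(b$rank_a) > 0))
    if (b$orientation[1] == "same") {
      expect_true(all(diff(b$rank_b) > 0))
    } else {
      expect_true(all(diff(b$rank_b) < 0))
    }
  }
  .fixture_cache$ingA_blocks <- blocks
  .fixture_cache$ingA_pairs <- pairs
})

test_that("classification is a partition and recovers truth labels", {
  sim <- shared_sim()
  ranks <- gene_ranks(sim$species$ingroupA$genes)
  pairs <- .fixture_cache$ingA_pairs
  blocks <- .fixture_cache$ingA_blocks
  dup <- classify_duplicates(pairs, ranks, blocks)
  expect_equal(nrow(dup), nrow(pairs))
  expect_false(any(is.na(dup$class)))

  truth_wgd <- sim$truth$wgd_pairs[sim$truth$wgd_pairs$species == "ingroupA", ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  dup_key <- key(dup$gene_a, dup$gene_b)
  wgd_called <- dup_key[dup$class == "wgd"]
  truth_key <- key(truth_wgd$gene_a, truth_wgd$gene_b)
  # truth WGD pairs that made it into blocks must be classified wgd
  present <- truth_key[truth_key %in% dup_key]
  recovered <- mean(present %in% wgd_called)
  expect_gte(recovered, 0.95)
  # no truth tandem pair may be called wgd
  tt <- sim$truth$tandem_pairs[sim$truth$tandem_pairs$species == "ingroupA", ]
  expect_equal(sum(key(tt$gene_a, tt$gene_b) %in% wgd_called), 0)
  # adjacent pair not in blocks -> tandem
  tandem_called <- dup_key[dup$class == "tandem"]
  expect_true(all(key(tt$gene_a, tt$gene_b) %in% dup_key ==
                    key(tt$gene_a, tt$gene_b) %in% c(tandem_called, wgd_called)))
})

test_that("tandem and dispersed fall out of rank distance and scaffolds", {
  ranks <- rbind(mk_ranks(20, "s1"), mk_ranks(20, "s2", "h"))
  no_blocks <- chain_anchors(data.frame(gene_a = character(0),
                                        gene_b = character(0)),
                             ranks, ranks, self = TRUE)
  pairs <- data.frame(gene_a = c("g5", "g3", "g1"),
                      gene_b = c("g6", "g9", "h1"))
  dup <- classify_duplicates(pairs, ranks, no_blocks)
  expect_equal(as.character(dup$class), c("tandem", "proximal", "dispersed"))
})

test_that("syntenic depth is 2:1 for the duplicated ingroup and 1:1 for an
          outgroup, and drops to 1 where a homoeolog region is deleted", {
  ra <- mk_ranks(30, "ref", "r")
  # duplicated query: two homoeolog scaffolds each collinear with ref
  rq <- rbind(mk_ranks(30, "qA", "x"), mk_ranks(30, "qB", "y"))
  hits <- data.frame(gene_a = rep(ra$gene_id, 2), gene_b = rq$gene_id)
  blocks <- chain_anchors(hits, ra, rq, min_block = 5, self = FALSE)
  d <- syntenic_depth_ratio(blocks, ra)
  expect_equal(d$modal_depth, 2)

  # unduplicated comparison
  blocks1 <- chain_anchors(data.frame(gene_a = ra$gene_id,
                                      gene_b = mk_ranks(30, "q1", "z")$gene_id),
                           ra, mk_ranks(30, "q1", "z"), min_block = 5,
                           self = FALSE)
  expect_equal(syntenic_depth_ratio(blocks1, ra)$modal_depth, 1)

  # delete one homoeolog's copy of ref genes 21..30 entirely
  keep <- !(rq$scaffold == "qB" & rq$rank >= 20)
  hits2 <- hits[keep, ]
  blocks2 <- chain_anchors(hits2, ra, rq[keep, ], min_block = 5,
                           self = FALSE)
  d2 <- syntenic_depth_ratio(blocks2, ra)
  expect_true(all(d2$depth[paste0("r", 22:30)] == 1))
  expect_true(all(d2$depth[paste0("r", 2:20)] == 2))
})
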