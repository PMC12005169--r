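# Fractionation windows, bias sign test, retention classes, GO enrichment.

test_that("fractionation windows recompute exactly on constructed losses", {
  ref <- data.frame(gene_id = paste0("r", 1:100), scaffold = "chr1",
                    rank = 0:99)
  # full retention on both homoeologs
  omap <- rbind(data.frame(ref_gene = ref$gene_id, target_scaffold = "hA"),
                data.frame(ref_gene = ref$gene_id, target_scaffold = "hB"))
  fw <- fractionation_profile(ref, omap, window = 100)
  expect_equal(nrow(fw), 1)
  expect_equal(c(fw$retention1, fw$retention2), c(100, 100))

  # delete 30 genes from homoeolog B inside the window
  omap2 <- omap[!(omap$target_scaffold == "hB" &
                    omap$ref_gene %in% paste0("r", 11:40)), ]
  fw2 <- fractionation_profile(ref, omap2, window = 100)
  expect_equal(c(fw2$retention1, fw2$retention2), c(100, 70))

  # a 50-gene scaffold yields one truncated window
  ref50 <- ref[1:50, ]
  fw3 <- fractionation_profile(ref50, omap, window = 100)
  expect_equal(nrow(fw3), 1)
  expect_true(fw3$truncated)
  expect_equal(fw3$n_genes, 50)
})

test_that("fractionation profile is invariant to gene id relabeling", {
  set.seed(12)
  ref <- data.frame(gene_id = paste0("r", 1:60), scaffold = "c", rank = 0:59)
  omap <- data.frame(
    ref_gene = rep(ref$gene_id, 2),
    target_scaffold = rep(c("hA", "hB"), each = 60))
  omap <- omap[runif(120) < 0.8, ]
  fw <- fractionation_profile(ref, omap, window = 20)
  relabel <- setNames(paste0("zz", 60:1), ref$gene_id)
  ref2 <- transform(ref, gene_id = unname(relabel[gene_id]))
  omap2 <- transform(omap, ref_gene = unname(relabel[ref_gene]))
  fw2 <- fractionation_profile(ref2, omap2, window = 20)
  expect_equal(fw$retention1, fw2$retention1)
  expect_equal(fw$retention2, fw2$retention2)
})

test_that("the bias sign test matches the exact binomial oracle", {
  set.seed(13)
  n_win <- 50
  # symmetric 20%/20% loss
  r1 <- 100 - rbinom(n_win, 25, 0.2) * 4
  r2 <- 100 - rbinom(n_win, 25, 0.2) * 4
  fw <- data.frame(retention1 = r1, retention2 = r2)
  bt <- fractionation_bias_test(fw)
  d <- r1 - r2
  nz <- d[d != 0]
  expect_equal(bt$p_value,
               binom.test(sum(nz > 0), length(nz), 0.5)$p.value)
  expect_gt(bt$p_value, 0.05)

  # strongly biased loss: 35% vs 5%
  r1b <- 100 - rbinom(n_win, 25, 0.05) * 4
  r2b <- 100 - rbinom(n_win, 25, 0.35) * 4
  btb <- fractionation_bias_test(data.frame(retention1 = r1b,
                                            retention2 = r2b))
  expect_lt(btb$p_value, 0.01)

  # identical retention everywhere
  expect_equal(fractionation_bias_test(
    data.frame(retention1 = rep(80, 10), retention2 = rep(80, 10)))$p_value,
    1)
  expect_error(fractionation_bias_test(
    data.frame(retention1 = 1:3, retention2 = 1:3)), "at least 5")
})

test_that("retention classification matches the brute-force rule over all
          copy counts 0..3", {
  grid <- expand.grid(outgroup1 = 0:3, outgroup2 = 0:3,
                      ingroupA = 0:3, ingroupB = 0:3)
  res <- classify_retention(grid)
  oracle <- mapply(oracle_retention_class, grid$outgroup1, grid$outgroup2,
                   grid$ingroupA, grid$ingroupB)
  expect_equal(as.character(res$rows$class), unname(oracle))
  # totals are an exact partition
  expect_equal(sum(res$totals), nrow(grid))
  expect_error(classify_retention(transform(grid, ingroupA = -1)),
               "non-negative")
})

test_that("simulated unbiased losses give balanced A-only/B-only classes
          and biased losses do not", {
  sim <- shared_sim()  # loss_bias = 0.5
  cls <- classify_retention(pangene_table(sim))
  a_only <- cls$totals[["retained_A_only"]]
  b_only <- cls$totals[["retained_B_only"]]
  expect_gt(binom.test(a_only, a_only + b_only, 0.5)$p.value, 0.01)

  simb <- simulate_clade(sim_config(n_genes = 150, loss_prob = 0.35,
                                    loss_bias = 0.9, tandem_prob = 0,
                                    codon_length = 30, seed = 23))
  # fractionation from the truth ortholog map must reject symmetry
  ranks_ref <- gene_ranks(simb$species$outgroup1$genes)
  ing <- simb$species$ingroupA$genes
  anc_of <- sub("_[AB]$", "", sub("^ingroupA_", "", ing$gene_id))
  omap <- data.frame(ref_gene = paste0("outgroup1_", anc_of),
                     target_scaffold = ing$scaffold)
  fw <- fractionation_profile(ranks_ref, omap, window = 15)
  expect_lt(fractionation_bias_test(fw)$p_value, 0.01)
})

test_that("GO over-representation equals the exact hypergeometric tail", {
  # constructed 2x2: term hits 8 of 50 group genes, 12 of the other 950
  universe <- paste0("u", 1:1000)
  group <- universe[1:50]
  term_genes <- c(universe[1:8], universe[101:112])
  g2g <- rbind(data.frame(gene_id = term_genes, go_id = "GO:0000001"),
               data.frame(gene_id = universe[30:500], go_id = "GO:0000002"))
  res <- go_enrichment(group, universe, g2g)
  row <- res[res$go_id == "GO:0000001", ]
  expect_equal(row$total, 20)
  expect_equal(row$count, 8)
  expect_equal(row$expected, 20 * 50 / 1000)
  expect_equal(row$p_value, oracle_hyper_tail(8, 20, 1000, 50))

  # identical proportions are unremarkable
  res2 <- go_enrichment(universe[1:100],
                        universe,
                        data.frame(gene_id = c(universe[1:10],
                                               universe[101:190]),
                                   go_id = "GO:0000009"))
  expect_gte(res2$p_value[1], 0.5)

  # group = universe forces p = 1 for every term
  res3 <- go_enrichment(universe, universe, g2g)
  expect_true(all(res3$p_value == 1))

  expect_error(go_enrichment(character(0), universe, g2g), "empty")
  expect_error(go_enrichment("not_there", universe, g2g), "subset")
})
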