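# Clade simulator: determinism, analytic Ks expectations, conservation.

test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(n_genes = 3, n_chromosomes = 5), "n_chromosomes")
  expect_error(sim_config(loss_prob = 1.5), "loss_prob")
  expect_error(sim_config(wgd_age = -1), "ages")
  expect_error(sim_config(speciation_ages = c(outgroup2 = 40, outgroup1 = 5,
                                              ingroup = 3), wgd_age = 7.4),
               "predate")
})

test_that("zero branch length leaves the sequence untouched and errors
          propagate", {
  cds <- paste(rep("GCTGGAACTCCG", 25), collapse = "")
  expect_identical(evolve_cds(cds, 0, 0), cds)
  expect_error(evolve_cds("GCTGA", 0.1), "multiple of 3")
  expect_error(evolve_cds("GCTTAAGCT", 0.1), "stop")
  expect_error(evolve_cds(cds, -0.1), ">= 0")
})

test_that("evolve_cds never introduces stop codons", {
  set.seed(21)
  for (i in 1:10) {
    cds <- paste0(sample(c("GC", "GG", "GT", "CC", "AC"), 100, TRUE),
                  sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    out <- evolve_cds(cds, branch_ks = 0.5, branch_ka = 0.5)
    aa <- vapply(codons_of(out), oracle_translate, character(1))
    expect_false(any(aa == "*"))
  }
})

test_that("NG86 over replicate evolved pairs recovers the branch Ks", {
  set.seed(31)
  n_rep <- 200
  ks_hat <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    anc <- paste0(sample(c("GC", "GG", "GT", "CC", "AC"), 300, TRUE),
                  sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    der <- evolve_cds(anc, branch_ks = 0.1, branch_ka = 0)
    ks_hat[i] <- ng86(list(codons_a = codons_of(anc),
                           codons_b = codons_of(der)))$ks
  }
  se <- sd(ks_hat) / sqrt(n_rep)
  expect_lt(abs(mean(ks_hat) - 0.1), 3 * se)
})

test_that("same seed gives byte-identical genomes and truth", {
  cfg <- sim_config(n_genes = 40, n_chromosomes = 2, codon_length = 60,
                    seed = 99)
  s1 <- simulate_clade(cfg)
  s2 <- simulate_clade(cfg)
  expect_identical(s1$species, s2$species)
  expect_identical(s1$truth, s2$truth)
  # evolve_cds with an explicit seed is deterministic too
  cds <- s1$species$outgroup1$cds[[1]]
  expect_identical(evolve_cds(cds, 0.2, 0.02, seed = 5),
                   evolve_cds(cds, 0.2, 0.02, seed = 5))
})

test_that("with no losses and no tandems every ingroup gene has two copies
          and every WGD pair is logged", {
  cfg <- sim_config(n_genes = 50, n_chromosomes = 2, codon_length = 30,
                    loss_prob = 0, tandem_prob = 0, seed = 17)
  sim <- simulate_clade(cfg)
  for (sp in c("ingroupA", "ingroupB")) {
    expect_equal(nrow(sim$species[[sp]]$genes), 2 * cfg$n_genes)
    expect_equal(sum(sim$truth$wgd_pairs$species == sp), cfg$n_genes)
  }
  # every simulated gene appears exactly once; truth pairs reference them
  for (sp in names(sim$species)) {
    ids <- sim$species[[sp]]$genes$gene_id
    expect_false(any(duplicated(ids)))
    expect_setequal(names(sim$species[[sp]]$cds), ids)
  }
  all_ids <- unlist(lapply(sim$species, function(s) s$genes$gene_id))
  expect_true(all(c(sim$truth$wgd_pairs$gene_a, sim$truth$wgd_pairs$gene_b,
                    sim$truth$ortholog_pairs$gene_a,
                    sim$truth$ortholog_pairs$gene_b) %in% all_ids))
})

test_that("ingroup gene counts satisfy 2 x n_genes - losses + tandems", {
  sim <- shared_sim()
  for (sp in c("ingroupA", "ingroupB")) {
    n_loss <- sum(sim$truth$loss_events$species == sp)
    n_tand <- sum(sim$truth$tandem_pairs$species == sp)
    expect_equal(nrow(sim$species[[sp]]$genes),
                 2 * sim$config$n_genes - n_loss + n_tand)
  }
})

test_that("mean Ks over truth WGD pairs is within 10% of 2 r T", {
  sim <- shared_sim()
  tp <- sim$truth$wgd_pairs
  cds <- c(sim$species$ingroupA$cds, sim$species$ingroupB$cds)
  set.seed(1)
  idx <- sample(nrow(tp), min(80, nrow(tp)))
  ks <- vapply(idx, function(i)
    ng86(list(codons_a = codons_of(cds[[tp$gene_a[i]]]),
              codons_b = codons_of(cds[[tp$gene_b[i]]])))$ks, numeric(1))
  expected <- 2 * sim$config$syn_rate * sim$config$wgd_age
  expect_lt(abs(mean(ks) - expected) / expected, 0.10)
})

test_that("unbiased loss splits evenly between subgenomes (exact binomial)", {
  sim <- shared_sim()  # loss_bias = 0.5
  le <- sim$truth$loss_events
  n_b <- sum(le$subgenome == "B")
  p <- binom.test(n_b, nrow(le), p = 0.5)$p.value
  expect_gt(p, 0.01)
})

test_that("chromosome ends carry the planted telomere arrays", {
  sim <- shared_sim()
  k <- sim$config$telomere_repeats_per_end
  fwd <- strrep("TTTAGGG", 3)
  for (chr in sim$species$outgroup1$chromosomes[1:2]) {
    head_seq <- substr(chr, 1, 7 * k)
    tail_seq <- substr(chr, nchar(chr) - 7 * k + 1, nchar(chr))
    expect_equal(oracle_motif_count(head_seq, fwd), k - 2)
    expect_equal(oracle_motif_count(tail_seq, oracle_revcomp(fwd)), k - 2)
  }
})

test_that("pangene copy counts equal per-species surviving copies", {
  sim <- shared_sim()
  pt <- pangene_table(sim)
  expect_equal(nrow(pt), sim$config$n_genes)
  expect_equal(sum(pt$ingroupA), nrow(sim$species$ingroupA$genes))
  expect_equal(sum(pt$outgroup1), nrow(sim$species$outgroup1$genes))
  # genes lost in ingroupA on subgenome B reduce its count to <= 1
  lost_b <- sim$truth$loss_events
  lost_b <- lost_b$ancestral_gene[lost_b$species == "ingroupA"]
  no_tandem <- setdiff(lost_b, sub("^ingroupA_(g[0-9]+).*$", "\\1",
                                   sim$truth$tandem_pairs$gene_a[
                                     sim$truth$tandem_pairs$species == "ingroupA"]))
  expect_true(all(pt$ingroupA[pt$pangene %in% no_tandem] == 1))
})
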