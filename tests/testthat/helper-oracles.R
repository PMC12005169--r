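# Independent oracles, written from first principles and kept separate from
# the package implementation they check.

.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})

oracle_translate <- function(codon) .oracle_code[[codon]]

# NG86 site count for one codon: fraction of the 9 possible single-base
# changes that are synonymous (changes to stops are nonsynonymous).
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  syn <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (oracle_translate(alt) == aa) syn <- syn + 1
    }
  }
  syn / 3
}

# Pathway-averaged (Sd, Nd) between two codons by explicit enumeration of
# every ordering of the differing positions; pathways through stop codons
# are dropped. Returns c(NA, NA) when every pathway is blocked.
oracle_pathway <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  sds <- nds <- numeric(0)
  for (ord in perms(diffs)) {
    cur <- a; s <- n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (oracle_translate(nxt) == "*") { ok <- FALSE; break }
      if (oracle_translate(nxt) == oracle_translate(cur)) s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, s); nds <- c(nds, n) }
  }
  if (length(sds) == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = mean(sds), nd = mean(nds))
}

# Naive overlapping-occurrence count of `query` (and its reverse
# complement) at every start position of `s`.
oracle_motif_count <- function(s, query) {
  n <- nchar(s); m <- nchar(query)
  if (n < m) return(0L)
  sum(substring(s, 1:(n - m + 1), m:n) == query)
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Best collinear chain score by exhaustive enumeration over ordered anchor
# subsets (both orientations), under the same scoring as the chaining DP.
oracle_best_chain_score <- function(ra, rb, max_gap = 25,
                                    anchor_reward = 10, gap_penalty = 1,
                                    min_block = 2) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  best <- -Inf
  extend <- function(idx, orient) {
    sc <- anchor_reward
    for (k in seq_along(idx)[-1]) {
      da <- ra[idx[k]] - ra[idx[k - 1]]
      db <- (rb[idx[k]] - rb[idx[k - 1]]) * orient
      if (da < 1 || db < 1 || da > max_gap || db > max_gap) return(NA_real_)
      sc <- sc + anchor_reward - gap_penalty * ((da - 1) + (db - 1))
    }
    sc
  }
  subsets <- function(v) {
    if (length(v) == 0) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (s in subsets(seq_len(n))) {
    if (length(s) < min_block) next
    for (orient in c(1, -1)) {
      sc <- extend(sort(s), orient)
      if (!is.na(sc) && sc > best) best <- sc
    }
  }
  best
}

# Hypergeometric upper-tail P(X >= k) by direct summation of choose().
oracle_hyper_tail <- function(k, n_annot, n_univ, n_group) {
  ks <- k:min(n_annot, n_group)
  sum(choose(n_annot, ks) * choose(n_univ - n_annot, n_group - ks)) /
    choose(n_univ, n_group)
}

# Retention rule re-implemented directly from its verbal definition.
oracle_retention_class <- function(o1, o2, a, b) {
  if (o1 != 1 || o2 != 1 || !(a %in% 1:2) || !(b %in% 1:2)) {
    return("filtered_out")
  }
  if (a == 2 && b == 2) return("retained_both")
  if (a == 1 && b == 1) return("single_both")
  if (a == 2) return("retained_A_only")
  "retained_B_only"
}

# Split a CDS string into codons (test-side convenience).
codons_of <- function(s) {
  substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
}

# --- shared expensive fixtures, computed once per test run ---------------

.fixture_cache <- new.env(parent = emptyenv())

# The reference simulation used across test files.
shared_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_clade(sim_config(n_genes = 120, seed = 7))
  }
  .fixture_cache$sim
}

# One full pipeline run with a calibration matched to the simulated rate.
shared_report <- function() {
  if (is.null(.fixture_cache$report)) {
    cfg <- sim_config(seed = 42)
    .fixture_cache$report <- run_wgd_pipeline(
      cfg, calib_peak_ks = 2 * cfg$syn_rate * 35, calib_age_my = 35,
      max_ks_pairs = 250)
  }
  .fixture_cache$report
}
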