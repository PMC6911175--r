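# Shared in-code fixtures; everything is generated, nothing is stored.

smallFixture <- function(nSites = 120, nGenes = 80, seed = 7) {
  simulateGenome(list(n_sites = nSites, n_genes = nGenes), seed = seed)
}

# A complete small screen: fixture, features, truth, library, counts.
smallScreen <- function(nSites = 300, guidesPerSite = 12, prevalence = 0.05,
                        nControls = 400, params = list(), seed = 7) {
  fx <- simulateGenome(list(n_sites = nSites, n_genes = 150), seed = seed)
  feats <- simulateFeatures(fx, prevalence = prevalence, seed = seed)
  truth <- simulateTruthFromEssential(feats, seed = seed)
  man <- designLibrary(fx, totalGuides = nSites * guidesPerSite, seed = seed)
  man <- addControls(man, sprintf("ctrl_gene_%02d", 1:20), 5, nControls)
  sc <- simulateCounts(man, truth, fx, params, seed = seed)
  list(fx = fx, feats = feats, truth = truth, man = man, sc = sc)
}

# DataFrame of site results built directly (for label/model tests that
# do not need a screen behind them).
syntheticResults <- function(n = 1000, seed = 1) {
  set.seed(seed)
  beta <- rnorm(n, 0, 0.1)
  S4Vectors::DataFrame(
    site_id = sprintf("s%04d", seq_len(n)),
    beta = beta, beta_cnv_adjusted = beta, mean_lfc = beta * 10,
    p_value = runif(n), fdr = runif(n),
    neg_rank = rank(beta, ties.method = "first"),
    n_guides = rep(10L, n))
}

grFromDf <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  for (nm in setdiff(names(df), c("chrom", "start", "end")))
    S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  gr
}
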