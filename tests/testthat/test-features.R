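test_that("window signal equals per-base brute-force averaging", {
  ## constant track
  const <- data.frame(chrom = "chr1", start = 0L, end = 10000L, value = 2)
  expect_equal(extractWindowSignal(const, "chr1", 5000, "tf"), 2)
  expect_equal(extractWindowSignal(const, "chr1", 5000,
                                   "histone_modification"), 2)
  ## impulse of value 150 covering one base at the summit: mean 1.0
  imp <- data.frame(chrom = "chr1", start = 4999L, end = 5000L, value = 150)
  expect_equal(extractWindowSignal(imp, "chr1", 5000, "tf"), 1.0)
  ## random step track vs per-base oracle
  set.seed(30)
  for (i in 1:5) {
    bp <- sort(sample(0:2000, 20))
    steps <- data.frame(chrom = "chr1", start = head(bp, -1), end = bp[-1],
                        value = round(runif(19, 0, 5), 2))
    summit <- sample(100:1900, 1)
    for (cls in c("tf", "histone_modification")) {
      w <- if (cls == "tf") 150L else 300L
      win <- (summit - w %/% 2):(summit + w %/% 2 - 1)
      perBase <- vapply(win, function(p) {
        row <- which(steps$start + 1 <= p & steps$end >= p)
        if (length(row)) steps$value[row[1]] else 0
      }, numeric(1))
      expect_equal(extractWindowSignal(steps, "chr1", summit, cls),
                   mean(perBase))
    }
  }
  ## clipped at the chromosome start: mean over the clipped window
  expect_equal(extractWindowSignal(const, "chr1", 10, "tf"),
               2)
  expect_equal(extractWindowSignal(const, "chr2", 5000, "tf"), 0)
})

test_that("assembled feature tables carry annotations and impute zeros", {
  fx <- smallFixture(nSites = 40, seed = 31)
  tr <- list(DNase = list(
    data = data.frame(chrom = names(chromSizes(fx))[1], start = 0L,
                      end = chromSizes(fx)[[1]], value = 3),
    class = "tf"))
  ft <- assembleFeatureTable(fx, tracks = tr)
  st <- sites(fx)
  onChr1 <- as.character(seqnames(st)) == names(chromSizes(fx))[1]
  expect_equal(ft$DNase[onChr1], rep(3, sum(onChr1)))
  expect_equal(ft$DNase[!onChr1], rep(0, sum(!onChr1)))
  expect_true(all(!is.na(as.matrix(as.data.frame(ft[, -1])))))
  ## nearest-gene bookkeeping: distance is the minimum over all genes
  gn <- genes(fx)
  i <- 1L
  sameChr <- as.character(seqnames(gn)) == as.character(seqnames(st))[i]
  expect_equal(ft$distance_to_nearest_tss[i],
               min(abs(start(gn)[sameChr] - st$summit[i])))
})

test_that("feature ranking recovers the simulated effect ordering", {
  spec <- defaultEffectSpec()[c("DNase", "H3K27ac", "FOXA1_signal")]
  nS <- 2000
  hits <- 0L
  for (s in 1:3) {
    fx <- simulateGenome(list(n_sites = nS, n_genes = 300), seed = s)
    mkLine <- function(off) {
      ft <- simulateFeatures(fx, effectSpec = spec, prevalence = 0.05,
                             seed = s + off)
      truth <- simulateTruthFromEssential(ft, seed = s + off)
      res <- syntheticResults(nS, seed = s + off)
      res$site_id <- ft$site_id
      res$beta_cnv_adjusted <- truth$beta_true +
        rnorm(nS, 0, 0.02)
      list(ft = ft, res = res)
    }
    set.seed(s)
    a <- mkLine(0); b <- mkLine(100)
    rk <- rankFeatures(list(cellA = a$ft, cellB = b$ft),
                       list(cellA = a$res, cellB = b$res))
    ord <- match(names(spec), rk$feature)
    if (all(diff(ord) > 0) && rk$feature[1] == "DNase") hits <- hits + 1L
    expect_equal(rk$p_avg,
                 unname(rowMeans(cbind(rk$p_cellA, rk$p_cellB))))
    expect_true(all(rk$direction[ord[1:2]] == "higher_in_essential"))
  }
  expect_gte(hits, 3L)
})

test_that("feature ranking is invariant to monotone feature transforms", {
  fx <- smallFixture(nSites = 200, seed = 33)
  ft <- simulateFeatures(fx, prevalence = 0.1, seed = 33)
  res <- syntheticResults(200, seed = 33)
  res$site_id <- ft$site_id
  rk1 <- rankFeatures(list(a = ft), list(a = res))
  ft2 <- ft
  ft2$DNase <- exp(ft2$DNase)
  ft2$H3K27ac <- 5 * ft2$H3K27ac + 100
  rk2 <- rankFeatures(list(a = ft2), list(a = res))
  expect_equal(rk1$p_avg[match(rk1$feature, rk1$feature)],
               rk2$p_avg[match(rk1$feature, rk2$feature)])
})

test_that("shuffled essentiality gives no significant features", {
  fx <- smallFixture(nSites = 300, seed = 34)
  ft <- simulateFeatures(fx, prevalence = 0.05, seed = 34)
  res <- syntheticResults(300, seed = 34)   # betas unrelated to features
  res$site_id <- ft$site_id
  rk <- rankFeatures(list(a = ft), list(a = res))
  expect_gt(min(rk$p_avg), 0.001)
})

test_that("constant features are flagged with p = 1", {
  fx <- smallFixture(nSites = 60, seed = 35)
  ft <- simulateFeatures(fx, prevalence = 0.1, seed = 35)
  ft$motif_score <- 1
  res <- syntheticResults(60, seed = 35)
  res$site_id <- ft$site_id
  rk <- rankFeatures(list(a = ft), list(a = res))
  row <- rk[rk$feature == "motif_score", ]
  expect_equal(row$p_avg, 1)
  expect_true(row$flagged)
})

test_that("proximity enrichment detects engineered colocalisation", {
  fx <- simulateGenome(list(n_sites = 300, n_genes = 200,
                            prox_fraction = 0.3), seed = 36)
  gn <- genes(fx)
  essTss <- gn[gn$beta_gene <= quantile(gn$beta_gene, 0.1, type = 1)]
  st <- sites(fx)
  nearEss <- vapply(seq_along(st), function(i) {
    j <- as.character(seqnames(essTss)) == as.character(seqnames(st))[i]
    any(j) && min(abs(start(essTss)[j] - st$summit[i])) <= 1e5
  }, logical(1))
  ## call exactly the proximal sites essential: maximal enrichment
  pe <- proximityEnrichment(fx, st$site_id[nearEss], distance = 1e5)
  expect_lt(pe$site_p, 0.001)
  expect_gt(pe$site_pct[["essential"]], pe$site_pct[["all"]])
  ## random essential set: no signal
  set.seed(36)
  pe0 <- proximityEnrichment(fx, sample(st$site_id, 60), distance = 1e5)
  expect_gt(pe0$site_p, 0.05)
  expect_error(proximityEnrichment(fx, character(0)), "empty")
})

test_that("KS class comparisons match expectations at both extremes", {
  set.seed(37)
  x <- rnorm(300)
  betas <- setNames(c(x, x), sprintf("s%03d", 1:600))
  cls <- setNames(rep(c("a", "b"), each = 300), names(betas))
  same <- compareSiteClasses(betas, cls)
  expect_equal(same$stats$ks_stat, 0)
  expect_equal(same$stats$p, 1)
  shifted <- setNames(c(rnorm(500), rnorm(500) - 1),
                      sprintf("t%04d", 1:1000))
  cls2 <- setNames(rep(c("a", "b"), each = 500), names(shifted))
  sh <- compareSiteClasses(shifted, cls2)
  expect_lt(sh$stats$p, 1e-10)
  expect_error(compareSiteClasses(setNames(1:3, c("x", "y", "z")),
                                  setNames(c("a", "a", "b"),
                                           c("x", "y", "z"))),
               "fewer than 2")
})

test_that("cell-specific sites show depletion in their own cell line", {
  ## constructed: cellA-specific sites drawn more negative in cell A
  set.seed(38)
  n <- 400
  own <- rep(c(TRUE, FALSE), each = n / 2)
  betaA <- ifelse(own, rnorm(n, -0.3, 0.15), rnorm(n, 0, 0.15))
  ids <- sprintf("s%04d", 1:n)
  cmp <- compareSiteClasses(setNames(betaA, ids),
                            setNames(ifelse(own, "cellA_specific",
                                            "cellB_specific"), ids))
  expect_lt(cmp$stats$p, 1e-6)
  ## the own-cell-line CDF sits to the left (lower beta)
  q <- -0.2
  expect_gt(cmp$ecdfs$cellA_specific(q), cmp$ecdfs$cellB_specific(q))
})

test_that("TAD-boundary and anchor contrasts detect injected depletion", {
  fx <- smallFixture(nSites = 500, seed = 39)
  st <- sites(fx)
  sp <- GenomicRanges::GRanges(seqnames(st),
                               IRanges::IRanges(st$summit, width = 1))
  padded <- GenomicRanges::resize(tadBoundaries(fx), width = 2e4 + 1,
                                  fix = "center")
  inB <- GenomicRanges::countOverlaps(sp, padded) > 0
  h2h <- anchors(fx)[anchors(fx)$head_to_head]
  inA <- GenomicRanges::countOverlaps(sp, h2h) > 0
  set.seed(39)
  res <- syntheticResults(500, seed = 39)
  res$site_id <- st$site_id
  res$beta_cnv_adjusted <- rnorm(500, 0, 0.1) - 0.25 * inB - 0.25 * inA
  res$fdr <- runif(500)
  h3k <- setNames(rnorm(500, 2), st$site_id)
  ta <- tadAnchorAnalysis(res, fx, h3k27ac = h3k)
  if (sum(inB) >= 5) {
    expect_lt(ta$boundary$p, 0.01)
    expect_lt(ta$boundary$median_in, ta$boundary$median_out)
  }
  ## null betas: no boundary signal
  res0 <- syntheticResults(500, seed = 40)
  res0$site_id <- st$site_id
  ta0 <- tadAnchorAnalysis(res0, fx, h3k27ac = h3k)
  expect_gt(ta0$boundary$p, 0.01)
})

test_that("anchor-essential sites can show weaker H3K27ac than other essentials", {
  fx <- smallFixture(nSites = 500, seed = 41)
  st <- sites(fx)
  sp <- GenomicRanges::GRanges(seqnames(st),
                               IRanges::IRanges(st$summit, width = 1))
  h2h <- anchors(fx)[anchors(fx)$head_to_head]
  inA <- GenomicRanges::countOverlaps(sp, h2h) > 0
  set.seed(41)
  res <- syntheticResults(500, seed = 41)
  res$site_id <- st$site_id
  ess <- logical(500); ess[sample(500, 80)] <- TRUE
  ess[inA] <- TRUE
  res$fdr <- ifelse(ess, 0.01, 0.9)
  res$beta_cnv_adjusted <- ifelse(ess, -0.4, 0.01)
  ## anchor essentials at baseline H3K27ac, other essentials shifted +1
  h3k <- setNames(rnorm(500, 0), st$site_id)
  h3k[ess & !inA] <- h3k[ess & !inA] + 1
  ta <- tadAnchorAnalysis(res, fx, h3k27ac = h3k)
  expect_lt(ta$h3k27ac$median_anchor_essential,
            ta$h3k27ac$median_other_essential)
  expect_gt(ta$h3k27ac$median_other_essential, ta$h3k27ac$median_all)
})
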