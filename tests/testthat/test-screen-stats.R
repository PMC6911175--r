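# In-code ScreenCounts builder for arithmetic tests.
mkCounts <- function(cnt, siteOf, classOf = NULL) {
  if (is.null(classOf)) classOf <- rep("site", nrow(cnt))
  gid <- sprintf("g%03d", seq_len(nrow(cnt)))
  rownames(cnt) <- gid
  R <- ncol(cnt) / 2
  cols <- c(paste0("day0_r", 1:R), paste0("endpoint_r", 1:R))
  colnames(cnt) <- cols
  se <- SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = S4Vectors::DataFrame(guide_id = gid, site_id = siteOf,
                                   class = classOf, row.names = gid),
    colData = S4Vectors::DataFrame(sample = cols,
                                   timepoint = rep(c("day0", "endpoint"),
                                                   each = R),
                                   replicate = rep(1:R, 2),
                                   row.names = cols))
  new("ScreenCounts", se)
}

test_that("median-ratio size factors match construction and an oracle", {
  x <- matrix(rep(c(10L, 20L, 40L, 80L), 4), ncol = 4)
  sc <- mkCounts(x, rep("s1", 4))
  sc <- normalizeCounts(sc)
  expect_equal(unname(sc$size_factor), rep(1, 4))
  x2 <- x; x2[, 3] <- x[, 3] * 2L
  sc2 <- normalizeCounts(mkCounts(x2, rep("s1", 4)))
  expect_equal(unname(sc2$size_factor[3]), 2)
  set.seed(10)
  xr <- matrix(rnbinom(400, mu = 300, size = 5), ncol = 4)
  scr <- normalizeCounts(mkCounts(xr, rep("s", 100)))
  ## independent median-of-ratios oracle
  ok <- rowSums(xr == 0) == 0
  oracle <- apply(xr[ok, ], 2, function(col) median(col / xr[ok, 1]))
  expect_equal(unname(scr$size_factor), unname(oracle))
  xz <- xr; xz[, 2] <- 0L
  expect_error(normalizeCounts(mkCounts(xz, rep("s", 100))), "all-zero")
})

test_that("guide LFC is the log2 ratio of normalized arm means", {
  x <- matrix(c(100L, 50L, 100L, 50L, 100L, 50L, 100L, 50L), ncol = 4)
  sc <- normalizeCounts(mkCounts(x, c("s1", "s2")), pseudocount = 0.5)
  expect_equal(unname(guideLfc(sc)), c(0, 0))
  ## doubled endpoint with unit size factors: LFC exactly 1
  sc2 <- mkCounts(matrix(c(100L, 40L, 100L, 40L, 200L, 80L, 200L, 80L),
                         ncol = 4), c("s1", "s2"))
  assay(sc2, "normalized") <- assay(sc2, "counts") + 0
  sc2$size_factor <- rep(1, 4)
  expect_equal(unname(guideLfc(sc2)), c(1, 1))
})

test_that("simulated selection shows up at the generative LFC scale", {
  fx <- smallFixture(nSites = 40, seed = 14)
  truth <- S4Vectors::DataFrame(site_id = sites(fx)$site_id,
                                beta_true = rep(-0.5, 40))
  man <- addControls(designLibrary(fx, totalGuides = 640, seed = 14),
                     character(0), 5, 300)
  sc <- simulateCounts(man, truth, fx,
                       list(generations = 2, cnv_effect = 0), seed = 14)
  res <- scoreScreen(sc, NULL, generations = 2, nPermutations = 200,
                     seed = 14)
  expect_equal(mean(res$mean_lfc), -1.0, tolerance = 0.1)
  expect_equal(mean(res$beta), -0.5, tolerance = 0.05)
})

test_that("degenerate all-zero LFCs give beta 0 and p about 1", {
  lfc <- setNames(rep(0, 40), sprintf("g%03d", 1:40))
  gm <- data.frame(guide_id = names(lfc),
                   site_id = rep(c("s1", "s2", "AAVS1", "AAVS1"), each = 10),
                   class = rep(c("site", "site", "AAVS1", "AAVS1"),
                               each = 10))
  res <- estimateBeta(lfc, gm, nPermutations = 200, seed = 1)
  expect_equal(res$beta, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
})

test_that("beta estimates recover simulated truth", {
  s <- smallScreen(nSites = 300, guidesPerSite = 16, nControls = 500,
                   params = list(cnv_effect = 0), seed = 15)
  res <- scoreScreen(s$sc, NULL, nPermutations = 500, seed = 15)
  m <- match(res$site_id, s$truth$site_id)
  expect_gte(cor(res$beta, s$truth$beta_true[m], method = "spearman"), 0.8)
  ## essential sites dominate the top negative ranks
  ess <- s$truth$is_essential[m]
  expect_gt(mean(ess[res$neg_rank <= sum(ess)]), 0.8)
})

test_that("permutation machinery is deterministic and BH-monotone", {
  s <- smallScreen(nSites = 80, guidesPerSite = 8, nControls = 200,
                   seed = 16)
  lfc <- guideLfc(normalizeCounts(s$sc))
  r1 <- estimateBeta(lfc, rowData(s$sc), nPermutations = 300, seed = 5)
  r2 <- estimateBeta(lfc, rowData(s$sc), nPermutations = 300, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  o <- order(r1$p_value)
  expect_true(all(diff(r1$fdr[o]) >= -1e-12))
  expect_true(all(r1$fdr >= r1$p_value))
  expect_setequal(r1$neg_rank, seq_len(nrow(r1)))
})

## closed-form order-statistic oracle:
## P(U_(j) <= r) = sum_{i=j}^{k} choose(k, i) r^i (1-r)^(k-i)
rraOracle <- function(ranks, alpha) {
  r <- sort(ranks)
  k <- length(r)
  sel <- which(r < alpha)
  if (!length(sel)) return(1)
  min(vapply(sel, function(j) {
    sum(vapply(j:k, function(i)
      choose(k, i) * r[j]^i * (1 - r[j])^(k - i), numeric(1)))
  }, numeric(1)))
}

test_that("alpha-RRA equals the exhaustive order-statistic computation", {
  ## fixed example: ranks (0.01, 0.02, 0.03), alpha 0.05
  n <- 100
  lfc <- setNames(seq(-2, 2, length.out = n), sprintf("g%03d", 1:n))
  gm <- data.frame(guide_id = names(lfc), site_id = "bg", class = "site")
  gm$site_id[1:3] <- "sTop"        # ranks 1,2,3 -> r = .01,.02,.03
  gm$site_id[4:100] <- paste0("s", 4:100)
  rr <- rraScore(lfc, gm, alphaCutoff = 0.05, nPermutations = 50, seed = 1)
  top <- rr[rr$site_id == "sTop", ]
  expect_equal(top$rra_score, rraOracle(c(0.01, 0.02, 0.03), 0.05),
               tolerance = 1e-12)
  ## random small sites vs the oracle
  set.seed(20)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    r <- sort(runif(k, 0, 0.2))
    expect_equal(cistromeScreen:::.rraSiteScore(r, 0.1),
                 rraOracle(r, 0.1), tolerance = 1e-10)
  }
})

test_that("stronger negative selection lowers the RRA score", {
  n <- 200
  set.seed(21)
  lfc <- setNames(rnorm(n), sprintf("g%03d", 1:n))
  gm <- data.frame(guide_id = names(lfc),
                   site_id = rep(sprintf("s%02d", 1:20), each = 10),
                   class = "site")
  ## force site s01 guides into the global bottom
  lfc[gm$site_id == "s01"] <- min(lfc) - seq_len(10)
  rr <- rraScore(lfc, gm, nPermutations = 100, seed = 2)
  expect_equal(rr$site_id[which.min(rr$rra_score)], "s01")
  expect_lt(rr$rra_score[rr$site_id == "s01"],
            min(rr$rra_score[rr$site_id != "s01"]))
})

test_that("CNV correction removes an injected copy-number trend", {
  s <- smallScreen(nSites = 400, guidesPerSite = 10, nControls = 600,
                   params = list(cnv_effect = -0.1), seed = 17)
  s$truth$beta_true <- 0  # isolate the confounder
  sc <- simulateCounts(s$man, s$truth, s$fx, list(cnv_effect = -0.1),
                       seed = 17)
  res <- scoreScreen(sc, s$fx, nPermutations = 200, seed = 17)
  if (length(unique(res$copy_number)) > 1) {
    expect_gt(abs(cor(res$beta, res$copy_number)), 0.5)
    expect_lt(abs(cor(res$beta_cnv_adjusted, res$copy_number)), 0.1)
  }
  ## no injected effect: adjustment is numerically small
  sc0 <- simulateCounts(s$man, s$truth, s$fx, list(cnv_effect = 0),
                        seed = 18)
  res0 <- scoreScreen(sc0, s$fx, nPermutations = 200, seed = 18)
  expect_lt(max(abs(res0$beta_cnv_adjusted - res0$beta)), 0.02)
})

test_that("a single amplified site is pulled back toward its true beta", {
  ## constructed results: diploid nulls plus one 4-copy site whose raw
  ## beta carries the confounder
  set.seed(22)
  n <- 200
  res <- syntheticResults(n)
  res$beta <- rnorm(n, 0, 0.02)
  cnEffect <- -0.25
  res$beta[1] <- 0 + cnEffect          # true beta 0, confounded raw
  fx <- smallFixture(nSites = n, seed = 22)
  ## force the fixture copy state: site 1 amplified, rest diploid
  cs <- copySegments(fx)
  cs$copy_number <- rep(2L, length(cs))
  st <- sites(fx)
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(seqnames(st)[1],
                           IRanges::IRanges(st$summit[1], width = 1)),
    cs, select = "first")
  cs$copy_number[hit] <- 4L
  fx@copySegments <- cs
  res$site_id <- st$site_id
  ## other sites sharing the amplified segment also get the confounder
  sp <- GenomicRanges::GRanges(seqnames(st), IRanges::IRanges(st$summit, width = 1))
  cn <- cs$copy_number[GenomicRanges::findOverlaps(sp, cs, select = "first")]
  res$beta[cn == 4] <- rnorm(sum(cn == 4), 0, 0.02) + cnEffect
  adj <- cnvCorrect(res, fx)
  expect_lt(abs(adj$beta_cnv_adjusted[1]), abs(res$beta[1]))
  expect_lt(abs(adj$beta_cnv_adjusted[1] - 0), 0.1)
})
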