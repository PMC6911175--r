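# A labeled benchmark with informative and pure-noise features built in
# code: labels follow a linear score on the informative columns.
labeledBenchmark <- function(n = 500, nNoise = 10, seed = 1,
                             strength = 1.5) {
  set.seed(seed)
  inf <- matrix(rnorm(n * 3), n,
                dimnames = list(NULL, c("DNase", "H3K27ac", "gene_ess")))
  noise <- if (nNoise > 0)
    matrix(rnorm(n * nNoise), n,
           dimnames = list(NULL, paste0("noise", seq_len(nNoise))))
  score <- strength * (inf[, 1] + 0.8 * inf[, 2] + 0.6 * inf[, 3]) +
    rnorm(n)
  lab <- ifelse(score > median(score), "essential", "nonessential")
  ids <- sprintf("s%04d", seq_len(n))
  features <- S4Vectors::DataFrame(site_id = ids,
                                   as.data.frame(cbind(inf, noise)))
  labels <- S4Vectors::DataFrame(site_id = ids, label = lab,
                                 source_rule = "benchmark")
  list(features = features, labels = labels)
}

test_that("labeling applies the rank, null-p and LFC rules exactly", {
  res <- syntheticResults(1000, seed = 50)
  res$p_value <- rep(1, 1000)
  res$mean_lfc <- rep(0, 1000)
  labs <- labelSites(res, rankThreshold = 300, seed = 1)
  meta <- S4Vectors::metadata(labs)
  expect_identical(unname(meta$n_before_balancing["essential"]), 299L)
  ## balancing only removes members, never flips a label
  essIds <- res$site_id[res$neg_rank < 300]
  expect_true(all(labs$site_id[labs$label == "essential"] %in% essIds))
  ratio <- sum(labs$label == "essential") /
    sum(labs$label == "nonessential")
  expect_gte(ratio, 0.85)
  expect_lte(ratio, 1.1)
  ## all sites neutral: essential rule selects nothing
  resNull <- res
  resNull$neg_rank <- seq_len(1000) + 1000L
  expect_error(labelSites(resNull, rankThreshold = 1, seed = 1),
               "neg_rank")
})

test_that("screen-derived labels agree with ground truth", {
  s <- smallScreen(nSites = 300, guidesPerSite = 16, prevalence = 0.1,
                   nControls = 500, params = list(cnv_effect = 0),
                   seed = 51)
  res <- scoreScreen(s$sc, NULL, nPermutations = 500, seed = 51)
  nTrue <- sum(s$truth$is_essential)
  labs <- labelSites(res, rankThreshold = nTrue + 1, seed = 51)
  m <- match(labs$site_id, s$truth$site_id)
  agree <- mean((labs$label == "essential") == s$truth$is_essential[m])
  expect_gte(agree, 0.9)
})

test_that("trapezoid AUC equals the rank-statistic identity", {
  set.seed(52)
  for (i in 1:20) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    scores <- c(rnorm(n1, 1), rnorm(n0))
    if (i %% 3 == 0) scores <- round(scores)   # force ties
    y <- rep(c(TRUE, FALSE), c(n1, n0))
    u <- unname(wilcox.test(scores[y], scores[!y],
                            exact = FALSE)$statistic)
    expect_equal(aucValue(scores, y), u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("ROC/PR endpoints and the pROC cross-check agree", {
  set.seed(53)
  scores <- rnorm(200)
  y <- runif(200) < plogis(2 * scores)
  rc <- rocCurve(scores, y)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_equal(aucValue(scores, y),
               as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE))),
               tolerance = 1e-10)
  expect_equal(aucValue(scores == 1e9, y), 0.5)  # constant scores
  ## random scores at n = 2000: AUC near 1/2
  s2 <- rnorm(2000); y2 <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(aucValue(s2, y2) - 0.5), 0.03)
})

test_that("GA-SVM search is seeded, monotone and boundary-safe", {
  b <- labeledBenchmark(n = 240, nNoise = 4, seed = 54)
  g1 <- gaSvmSelect(b$features, b$labels, popSize = 8, nIterations = 4,
                    seed = 9)
  g2 <- gaSvmSelect(b$features, b$labels, popSize = 8, nIterations = 4,
                    seed = 9)
  expect_identical(g1$selected, g2$selected)
  expect_identical(g1$trace, g2$trace)
  expect_true(all(diff(g1$trace) >= 0))
  g0 <- gaSvmSelect(b$features, b$labels, popSize = 8, nIterations = 0,
                    seed = 9)
  expect_length(g0$trace, 1)
  expect_error(gaSvmSelect(b$features[, 1:2], b$labels),
               "at least 2 features")
})

test_that("a single informative feature among constants is found", {
  b <- labeledBenchmark(n = 200, nNoise = 0, seed = 55, strength = 3)
  f <- b$features
  f$H3K27ac <- 1; f$gene_ess <- 2     # constants
  g <- gaSvmSelect(f, b$labels, popSize = 10, nIterations = 10, seed = 1)
  expect_true("DNase" %in% g$selected)
})

test_that("cross-validation scores essential sites out of fold", {
  b <- labeledBenchmark(n = 300, nNoise = 3, seed = 56, strength = 3)
  mod <- crossValidate(b$features, b$labels, folds = 5, seed = 2)
  expect_gt(mod$cv_auc, 0.85)
  expect_gt(mod$cv_aupr, 0.8)
  expect_length(mod$per_site_score, 300)
  ## AUC equals the trapezoid of its own ROC points
  rc <- mod$roc_points
  expect_equal(mod$cv_auc,
               sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2))
  ## label-free feature = perfect separation
  f2 <- b$features
  f2$oracle <- as.numeric(b$labels$label == "essential")
  mod2 <- crossValidate(f2, b$labels, selected = "oracle", folds = 5,
                        seed = 2, kernel = "linear")
  expect_gte(mod2$cv_auc, 0.999)
})

test_that("prediction is deterministic, schema-checked and finite", {
  b <- labeledBenchmark(n = 200, nNoise = 2, seed = 57)
  mod <- crossValidate(b$features, b$labels, folds = 5, seed = 3)
  p1 <- predictScores(mod, b$features)
  p2 <- predictScores(mod, b$features)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  zero <- b$features[1, ]
  for (nm in setdiff(names(zero), "site_id")) zero[[nm]] <- 0
  expect_true(is.finite(predictScores(mod, zero)))
  broken <- b$features[, setdiff(names(b$features), "DNase")]
  expect_error(predictScores(mod, broken), "missing feature")
})

test_that("held-out scoring generalizes near the CV estimate", {
  b <- labeledBenchmark(n = 600, nNoise = 3, seed = 58, strength = 2)
  trainIdx <- 1:400; testIdx <- 401:600
  mod <- crossValidate(b$features[trainIdx, ], b$labels[trainIdx, ],
                       folds = 5, seed = 4)
  sc <- predictScores(mod, b$features[testIdx, ])
  aucHold <- aucValue(sc, b$labels$label[testIdx] == "essential")
  expect_lt(abs(aucHold - mod$cv_auc), 0.1)
})

test_that("error analysis profiles FP/FN groups and skips empty cells", {
  b <- labeledBenchmark(n = 300, nNoise = 2, seed = 59)
  y <- b$labels$label == "essential"
  ## perfect classifier: no FP/FN
  perfect <- setNames(as.numeric(y), b$labels$site_id)
  expect_message(ea <- errorAnalysis(perfect, b$labels, b$features),
                 "skipped")
  expect_true(all(c("FP", "FN") %in% ea$skipped))
  ## nonessential sites with essential-like DNase become FPs with
  ## elevated DNase medians
  sc <- setNames(b$features$DNase, b$labels$site_id)
  ea2 <- errorAnalysis(sc, b$labels, b$features)
  expect_gt(ea2$medians["DNase", "FP"], ea2$medians["DNase", "TN"])
  fpTn <- ea2$tests[ea2$tests$contrast == "FP vs TN" &
                      ea2$tests$feature == "DNase", ]
  expect_lt(fpTn$p, 0.01)
  ## shuffled scores: no significant contrasts on noise features
  set.seed(59)
  shuf <- setNames(sample(sc), b$labels$site_id)
  ea3 <- errorAnalysis(shuf, b$labels, b$features)
  noiseRows <- grepl("noise", ea3$tests$feature)
  expect_gt(min(ea3$tests$p[noiseRows]), 0.001)
})
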