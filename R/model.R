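## Fit an SVM and return a scoring closure. Decision values are oriented
## so that higher always means more essential; zero-variance columns are
## dropped before fitting (svm cannot scale them).
.fitSvm <- function(x, y, kernel = "radial") {
  keep <- apply(x, 2, function(v) sd(v) > 0)
  if (!any(keep)) {
    return(list(score = function(newx) rep(0, nrow(newx)), features = character(0)))
  }
  x <- x[, keep, drop = FALSE]
  y <- factor(y, levels = c("nonessential", "essential"))
  fit <- e1071::svm(x, y, kernel = kernel, scale = TRUE)
  ## decision values are signed towards the first label of the colname "A/B"
  orient <- NULL
  score <- function(newx) {
    dv <- attr(predict(fit, newx[, colnames(x), drop = FALSE],
                       decision.values = TRUE), "decision.values")
    if (is.null(orient)) {
      nmA <- strsplit(colnames(dv)[1], "/")[[1]][1]
      orient <<- if (nmA == "essential") 1 else -1
    }
    as.numeric(dv[, 1]) * orient
  }
  list(score = score, features = colnames(x))
}

.stratifiedFolds <- function(y, folds) {
  fold <- integer(length(y))
  for (lv in unique(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

#' Label sites as essential / nonessential from screen results
#'
#' Essential sites are those with negative-selection rank below
#' `rankThreshold`; nonessential sites are neither negatively nor
#' positively selected (`p_value > nullP`) and nearly unchanged
#' (`|mean LFC| < maxAbsLfc`). The larger class is then downsampled
#' (uniform, seeded) until the essential-to-nonessential ratio lies in
#' `ratioBounds`.
#'
#' @param results site-result `DataFrame` from
#'   [estimateBeta()]/[cnvCorrect()].
#' @param rankThreshold essential if `neg_rank <` this (default 300, an
#'   absolute count tied to a ~6,000-site library; pass
#'   `0.05 * nrow(results)` to scale it to other library sizes).
#' @param nullP minimum p-value for the nonessential rule (default 0.5).
#' @param maxAbsLfc maximum absolute site mean LFC for the nonessential
#'   rule (default 0.1).
#' @param ratioBounds admissible essential:nonessential ratio after
#'   balancing (default `c(0.85, 1.1)`).
#' @param seed integer seed for the downsampling.
#' @return `DataFrame` with `site_id`, `label`, `source_rule`; class
#'   sizes before balancing are kept in `metadata()`.
#' @export
labelSites <- function(results, rankThreshold = 300, nullP = 0.5,
                       maxAbsLfc = 0.1, ratioBounds = c(0.85, 1.1),
                       seed = 1) {
  ess <- results$site_id[results$neg_rank < rankThreshold]
  non <- results$site_id[results$p_value > nullP &
                           abs(results$mean_lfc) < maxAbsLfc &
                           !(results$site_id %in% ess)]
  if (!length(ess))
    stop("no essential sites: rule 'neg_rank < ", rankThreshold,
         "' selected nothing")
  if (!length(non))
    stop("no nonessential sites: rule 'p > ", nullP, " & |LFC| < ",
         maxAbsLfc, "' selected nothing")
  nBefore <- c(essential = length(ess), nonessential = length(non))
  withSeed(opSeed(seed, "label_sites"), {
    ratio <- length(ess) / length(non)
    if (ratio > ratioBounds[2])
      ess <- sample(ess, floor(ratioBounds[2] * length(non)))
    else if (ratio < ratioBounds[1])
      non <- sample(non, floor(length(ess) / ratioBounds[1]))
    out <- DataFrame(
      site_id = c(ess, non),
      label = rep(c("essential", "nonessential"),
                  c(length(ess), length(non))),
      source_rule = rep(c(sprintf("neg_rank<%g", rankThreshold),
                          sprintf("p>%g & |lfc|<%g", nullP, maxAbsLfc)),
                        c(length(ess), length(non))))
    metadata(out) <- list(n_before_balancing = nBefore,
                          ratio = length(ess) / length(non))
    out
  })
}

.featureMatrix <- function(features, labels) {
  m <- match(labels$site_id, features$site_id)
  if (anyNA(m)) stop("labeled sites missing from the feature table")
  cols <- setdiff(names(features), c("site_id", "is_essential"))
  x <- as.matrix(as.data.frame(features[m, cols, drop = FALSE]))
  rownames(x) <- labels$site_id
  x
}

#' Genetic-algorithm feature selection wrapped around an SVM
#'
#' Searches feature subsets by an evolutionary loop: a population of
#' subsets is scored by the validation AUROC of an SVM trained on a
#' fixed, seeded train/validation split; each generation keeps an elite
#' fraction and fills the rest with mutants of fitness-rank-weighted
#' parents, where a mutation randomly adds, removes or swaps exactly one
#' feature. The best combination ever seen is returned; the best-so-far
#' trace is non-decreasing by construction and the whole search is
#' deterministic per seed.
#'
#' @param features feature `DataFrame` (`site_id` + numeric columns).
#' @param labels `DataFrame` from [labelSites()].
#' @param popSize population size (default 30).
#' @param nIterations generations (default 50); 0 returns the best of
#'   the initial random population.
#' @param eliteFrac fraction carried over unchanged (default 0.2).
#' @param splitFrac training share of the internal split (default 0.7).
#' @param kernel SVM kernel (default `"radial"`).
#' @param seed integer seed.
#' @return list with `selected` (character vector), `best_auc`,
#'   `trace` (best-so-far AUROC per generation), `split` (indices used
#'   for training).
#' @export
gaSvmSelect <- function(features, labels, popSize = 30, nIterations = 50,
                        eliteFrac = 0.2, splitFrac = 0.7,
                        kernel = "radial", seed = 1) {
  x <- .featureMatrix(features, labels)
  if (ncol(x) < 2L) stop("need at least 2 features to search over")
  y <- labels$label
  withSeed(opSeed(seed, "ga_svm_select"), {
    trainIdx <- sort(unlist(lapply(unique(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, round(splitFrac * length(idx)))
    })))
    valIdx <- setdiff(seq_along(y), trainIdx)
    fitness <- function(mask) {
      if (!any(mask)) return(0.5)
      f <- .fitSvm(x[trainIdx, mask, drop = FALSE], y[trainIdx], kernel)
      if (!length(f$features)) return(0.5)
      aucValue(f$score(x[valIdx, mask, drop = FALSE]),
               y[valIdx] == "essential")
    }
    nF <- ncol(x)
    pop <- lapply(seq_len(popSize), function(i) {
      m <- runif(nF) < 0.5
      if (!any(m)) m[sample.int(nF, 1)] <- TRUE
      m
    })
    fit <- vapply(pop, fitness, numeric(1))
    best <- pop[[which.max(fit)]]
    bestFit <- max(fit)
    trace <- bestFit
    nElite <- max(1L, round(eliteFrac * popSize))
    mutate <- function(m) {
      op <- sample(c("add", "remove", "swap"), 1)
      on <- which(m); off <- which(!m)
      if (op == "add" && length(off)) m[sample(off, 1)] <- TRUE
      else if (op == "remove" && length(on) > 1) m[sample(on, 1)] <- FALSE
      else if (length(on) >= 1 && length(off) >= 1) {
        m[sample(on, 1)] <- FALSE
        m[sample(off, 1)] <- TRUE
      }
      m
    }
    iter <- 0L
    while (iter < nIterations) {
      iter <- iter + 1L
      o <- order(fit, decreasing = TRUE)
      elites <- pop[o[seq_len(nElite)]]
      w <- rank(fit)                       # fitter parents reproduce more
      children <- lapply(seq_len(popSize - nElite), function(i)
        mutate(pop[[sample.int(popSize, 1, prob = w)]]))
      pop <- c(elites, children)
      fit <- c(fit[o[seq_len(nElite)]],
               vapply(children, fitness, numeric(1)))
      if (max(fit) > bestFit) {
        bestFit <- max(fit)
        best <- pop[[which.max(fit)]]
      }
      trace <- c(trace, bestFit)
    }
    list(selected = colnames(x)[best], best_auc = bestFit, trace = trace,
         split = list(train = trainIdx, validation = valIdx))
  })
}

#' Stratified k-fold cross-validation of the essentiality SVM
#'
#' Scores every labeled site out-of-fold, assembles pooled ROC and PR
#' curves, and refits a final model on all labeled data for scoring new
#' sites with [predictScores()].
#'
#' @inheritParams gaSvmSelect
#' @param selected optional feature subset (e.g. from [gaSvmSelect()]);
#'   default: all feature columns.
#' @param folds number of folds (default 5), stratified by label.
#' @return object of class `"essentialityModel"`: list with `selected`,
#'   `cv_auc`, `cv_aupr`, `roc_points`, `pr_points`, `per_site_score`
#'   (named, out-of-fold), `fit` (final model closure), `labels`.
#' @export
crossValidate <- function(features, labels, selected = NULL, folds = 5,
                          kernel = "radial", seed = 1) {
  x <- .featureMatrix(features, labels)
  if (is.null(selected)) selected <- colnames(x)
  stopifnot(all(selected %in% colnames(x)))
  x <- x[, selected, drop = FALSE]
  y <- labels$label
  if (min(table(y)) < folds)
    stop("cannot stratify ", folds, " folds: smallest class has ",
         min(table(y)), " sites")
  withSeed(opSeed(seed, "cross_validate"), {
    fold <- .stratifiedFolds(y, folds)
    score <- numeric(length(y))
    for (k in seq_len(folds)) {
      tr <- fold != k
      f <- .fitSvm(x[tr, , drop = FALSE], y[tr], kernel)
      score[!tr] <- f$score(x[!tr, , drop = FALSE])
    }
    names(score) <- labels$site_id
    final <- .fitSvm(x, y, kernel)
    out <- list(selected = selected,
                cv_auc = aucValue(score, y == "essential"),
                cv_aupr = auprValue(score, y == "essential"),
                roc_points = rocCurve(score, y == "essential"),
                pr_points = prCurve(score, y == "essential"),
                per_site_score = score,
                fit = final, kernel = kernel, labels = labels)
    class(out) <- "essentialityModel"
    out
  })
}

#' @export
print.essentialityModel <- function(x, ...) {
  cat("essentialityModel (SVM,", x$kernel, "kernel)\n")
  cat("  features:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  CV AUROC %.3f, AUPR %.3f over %d labeled sites\n",
              x$cv_auc, x$cv_aupr, length(x$per_site_score)))
  invisible(x)
}

#' Per-feature AUROCs (single-feature baselines)
#'
#' Uses each feature directly as a ranking score; orientation-free
#' (`max(auc, 1 - auc)` is reported), matching how single epigenomic
#' signals are used as essentiality baselines.
#'
#' @inheritParams gaSvmSelect
#' @return named numeric vector of AUROCs.
#' @export
singleFeatureAucs <- function(features, labels) {
  x <- .featureMatrix(features, labels)
  y <- labels$label == "essential"
  vapply(colnames(x), function(f) {
    a <- aucValue(x[, f], y)
    max(a, 1 - a)
  }, numeric(1))
}

#' Score new sites with a trained essentiality model
#'
#' @param model an `"essentialityModel"` from [crossValidate()].
#' @param features feature `DataFrame` sharing the training schema.
#' @return named numeric vector of decision scores (higher = more
#'   likely essential).
#' @export
predictScores <- function(model, features) {
  cols <- setdiff(names(features), c("site_id", "is_essential"))
  miss <- setdiff(model$selected, cols)
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(as.data.frame(
    features[, model$selected, drop = FALSE]))
  rownames(x) <- features$site_id
  setNames(model$fit$score(x), features$site_id)
}

#' Feature profile of false positives and false negatives
#'
#' Calls predicted-essential at a score threshold (default: the score
#' quantile matching label prevalence), splits sites into TP/FP/TN/FN,
#' and reports per-feature medians plus Mann-Whitney contrasts of FP vs
#' TN and FN vs TP — the diagnostic that shows, e.g., false positives
#' carrying essential-like chromatin.
#'
#' @param scores named numeric prediction scores.
#' @param labels `DataFrame` from [labelSites()].
#' @param features feature `DataFrame`.
#' @param threshold optional score cutoff; default matches prevalence.
#' @return list with `threshold`, `medians` (features x groups),
#'   `tests` (`DataFrame` of contrasts), `skipped` (empty groups).
#' @export
errorAnalysis <- function(scores, labels, features, threshold = NULL) {
  y <- setNames(labels$label == "essential", labels$site_id)
  s <- scores[names(y)]
  if (is.null(threshold))
    threshold <- quantile(s, 1 - mean(y), type = 1)
  pred <- s > threshold
  groups <- list(TP = y & pred, FP = !y & pred,
                 TN = !y & !pred, FN = y & !pred)
  skipped <- names(groups)[vapply(groups, sum, integer(1)) == 0]
  if (length(skipped))
    message("empty group(s) skipped: ", paste(skipped, collapse = ", "))
  cols <- setdiff(names(features), c("site_id", "is_essential"))
  m <- match(names(y), features$site_id)
  med <- sapply(groups, function(g) {
    if (!any(g)) return(rep(NA_real_, length(cols)))
    vapply(cols, function(f) median(features[[f]][m][g]), numeric(1))
  })
  rownames(med) <- cols
  contrast <- function(a, b) {
    if (!any(groups[[a]]) || !any(groups[[b]])) return(NULL)
    DataFrame(contrast = paste(a, "vs", b), feature = cols,
              p = vapply(cols, function(f)
                suppressWarnings(wilcox.test(
                  features[[f]][m][groups[[a]]],
                  features[[f]][m][groups[[b]]]))$p.value, numeric(1)))
  }
  tests <- do.call(rbind, Filter(Negate(is.null),
                                 list(contrast("FP", "TN"),
                                      contrast("FN", "TP"))))
  list(threshold = unname(threshold), medians = med, tests = tests,
       skipped = skipped)
}
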