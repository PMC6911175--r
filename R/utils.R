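#' @import methods
#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom stats rnorm runif rnbinom lm predict quantile median
#'   p.adjust pbeta wilcox.test ks.test fisher.test chisq.test
#'   setNames ecdf sd cor rlnorm
#' @importFrom utils modifyList head read.delim write.table
NULL

# Derive a 32-bit sub-seed for an operation from the master seed, so each
# simulate_*/estimate_* stage has its own reproducible RNG stream.
opSeed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(op)
  h <- sum(codes * seq_along(codes)) %% 100003
  as.integer((abs(seed) %% 1000003) * 2011 + h) %% 2147483562L
}

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Largest-remainder allocation of n items to proportions p (sums to n,
# each count within 1 of n*p).
allocateCounts <- function(n, p) {
  stopifnot(all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

trimmedMean <- function(x, trim = 0.1) mean(x, trim = trim)

#' Area under the ROC curve from scores and binary labels
#'
#' Assembles an ROC curve by sweeping score thresholds from high to low
#' (ties grouped) and integrates it by the trapezoid rule. Higher scores
#' are expected for the positive class.
#'
#' @param scores numeric vector of prediction scores.
#' @param labels logical (or factor coercible to logical via
#'   `labels == positive`) vector; `TRUE` marks the positive class.
#' @param positive positive-class label when `labels` is not logical.
#' @return For [rocCurve()] a `data.frame` with columns `fpr`, `tpr`;
#'   for [aucValue()] the scalar area under that curve.
#' @examples
#' aucValue(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
rocCurve <- function(scores, labels, positive = "essential") {
  y <- if (is.logical(labels)) labels else labels == positive
  stopifnot(length(scores) == length(y), any(y), any(!y))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- cumsum(!duplicated(s))                 # tie groups share a threshold
  tp <- tapply(as.numeric(y), grp, sum)
  fp <- tapply(as.numeric(!y), grp, sum)
  tpr <- c(0, cumsum(tp) / sum(y))
  fpr <- c(0, cumsum(fp) / sum(!y))
  data.frame(fpr = fpr, tpr = tpr)
}

#' @rdname rocCurve
#' @export
aucValue <- function(scores, labels, positive = "essential") {
  rc <- rocCurve(scores, labels, positive)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' Precision-recall curve and its area
#'
#' @inheritParams rocCurve
#' @return For [prCurve()] a `data.frame` with columns `recall`,
#'   `precision`; for [auprValue()] the trapezoidal area under it.
#' @export
prCurve <- function(scores, labels, positive = "essential") {
  y <- if (is.logical(labels)) labels else labels == positive
  stopifnot(length(scores) == length(y), any(y))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tapply(as.numeric(y), grp, sum))
  n <- cumsum(tapply(rep(1, length(y)), grp, sum))
  recall <- tp / sum(y)
  precision <- tp / n
  data.frame(recall = c(0, recall), precision = c(precision[1], precision))
}

#' @rdname prCurve
#' @export
auprValue <- function(scores, labels, positive = "essential") {
  pc <- prCurve(scores, labels, positive)
  sum(diff(pc$recall) * (head(pc$precision, -1) + pc$precision[-1]) / 2)
}
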