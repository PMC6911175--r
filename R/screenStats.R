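#' Median-ratio normalization of screen counts
#'
#' Size factors are medians of per-guide count ratios to a reference
#' sample (the first day-0 sample by default), computed over guides with
#' nonzero counts in all samples; the reference sample's factor is 1 by
#' construction. The `normalized` assay holds
#' `raw / size_factor + pseudocount`.
#'
#' @param sc a [ScreenCounts-class].
#' @param reference column name or index of the reference sample;
#'   default: first `day0` sample.
#' @param pseudocount added after scaling (default 0.5) so log fold
#'   changes are always finite.
#' @param controlGuides optional guide ids over which the medians are
#'   taken (e.g. AAVS1 negative controls). When a large library
#'   fraction is genuinely depleted — strong selection or copy-number
#'   amplification — the global median absorbs part of the signal;
#'   restricting the ratios to neutral controls avoids that.
#' @return the object with a `normalized` assay and `size_factor` in
#'   `colData()`.
#' @export
normalizeCounts <- function(sc, reference = NULL, pseudocount = 0.5,
                            controlGuides = NULL) {
  stopifnot(pseudocount > 0)
  cnt <- assay(sc, "counts")
  if (any(colSums(cnt) == 0))
    stop("sample with all-zero counts: ",
         paste(colnames(cnt)[colSums(cnt) == 0], collapse = ", "))
  if (is.null(reference)) reference <- which(sc$timepoint == "day0")[1]
  ok <- rowSums(cnt == 0) == 0
  if (!is.null(controlGuides))
    ok <- ok & rownames(cnt) %in% controlGuides
  if (!any(ok)) stop("no guide has nonzero counts in all samples")
  ref <- cnt[ok, reference]
  sf <- apply(cnt[ok, , drop = FALSE], 2, function(x) median(x / ref))
  assay(sc, "normalized") <- sweep(cnt, 2, sf, "/") + pseudocount
  sc$size_factor <- sf
  metadata(sc)$pseudocount <- pseudocount
  sc
}

#' Per-guide log2 fold change (endpoint vs day 0)
#'
#' @param sc a normalized [ScreenCounts-class] (see [normalizeCounts()]).
#' @return named numeric vector,
#'   `log2(mean endpoint) - log2(mean day0)` per guide.
#' @export
guideLfc <- function(sc) {
  if (!"normalized" %in% assayNames(sc))
    stop("run normalizeCounts() first")
  nc <- assay(sc, "normalized")
  d0 <- rowMeans(nc[, sc$timepoint == "day0", drop = FALSE])
  d1 <- rowMeans(nc[, sc$timepoint == "endpoint", drop = FALSE])
  setNames(log2(d1) - log2(d0), rownames(nc))
}

#' Estimate per-site selection (beta-scores) with a control permutation null
#'
#' The beta-score of a site is the trimmed mean of its guides' log2 fold
#' changes divided by `generations`, putting it on a per-generation
#' selection scale (negative = depleted/essential). Two-sided p-values
#' come from a null built by resampling site-sized guide sets from the
#' AAVS1 negative-control guides; FDR is Benjamini-Hochberg and
#' `neg_rank` orders sites by ascending beta (1 = most depleted).
#'
#' @param lfc named per-guide log2 fold changes from [guideLfc()].
#' @param guideMap `DataFrame`/`data.frame` with `guide_id`, `site_id`,
#'   `class` (e.g. `rowData()` of a [ScreenCounts-class]).
#' @param generations effective population doublings of the screen
#'   (default 10); beta = trimmed-mean LFC / generations.
#' @param trim trim fraction of the trimmed mean (default 0.1).
#' @param nPermutations control resamples per site size (default 1000).
#' @param controlClass `class` value identifying negative-control guides
#'   (default `"AAVS1"`).
#' @param seed integer seed for the permutation null.
#' @return `DataFrame` with `site_id`, `beta`, `beta_cnv_adjusted`
#'   (initialized to `beta`; see [cnvCorrect()]), `mean_lfc`, `p_value`,
#'   `fdr`, `neg_rank`, `n_guides`.
#' @export
estimateBeta <- function(lfc, guideMap, generations = 10, trim = 0.1,
                         nPermutations = 1000, controlClass = "AAVS1",
                         seed = 1) {
  gm <- as.data.frame(guideMap)
  stopifnot(all(c("guide_id", "site_id", "class") %in% names(gm)))
  gm$lfc <- lfc[gm$guide_id]
  if (any(is.na(gm$lfc))) stop("guides without an LFC value")
  siteLfc <- split(gm$lfc[gm$class == "site"], gm$site_id[gm$class == "site"])
  if (any(lengths(siteLfc) == 0L)) stop("site with zero guides")
  ctrl <- gm$lfc[gm$class == controlClass]
  if (!length(ctrl)) stop("no control guides of class ", controlClass)
  nG <- lengths(siteLfc)
  if (length(ctrl) < max(nG))
    warning("fewer control guides than the largest site; ",
            "resampling with replacement")
  beta <- vapply(siteLfc, trimmedMean, numeric(1), trim = trim) / generations
  meanLfc <- beta * generations

  withSeed(opSeed(seed, "estimate_beta"), {
    pv <- numeric(length(beta))
    for (sizeN in unique(nG)) {
      draws <- matrix(sample(ctrl, nPermutations * sizeN, replace = TRUE),
                      nrow = nPermutations)
      null <- apply(draws, 1, mean, trim = trim) / generations
      sel <- which(nG == sizeN)
      lower <- (1 + colSums(outer(null, beta[sel], "<="))) / (1 + nPermutations)
      upper <- (1 + colSums(outer(null, beta[sel], ">="))) / (1 + nPermutations)
      pv[sel] <- pmin(1, 2 * pmin(lower, upper))
    }
    out <- DataFrame(site_id = names(beta), beta = unname(beta),
                     beta_cnv_adjusted = unname(beta),
                     mean_lfc = unname(meanLfc),
                     p_value = pv, fdr = p.adjust(pv, "BH"),
                     neg_rank = rank(beta, ties.method = "first"),
                     n_guides = unname(nG))
    metadata(out) <- list(generations = generations, trim = trim,
                          n_permutations = nPermutations)
    out
  })
}

## alpha-RRA score of one site: guides' normalized ranks r (sorted), site
## size k; score = min_j P(Beta(j, k-j+1) <= r_(j)) over j with r_(j) < alpha.
.rraSiteScore <- function(r, alpha) {
  r <- sort(r)
  k <- length(r)
  j <- which(r < alpha)
  if (!length(j)) return(1)
  min(pbeta(r[j], j, k - j + 1))
}

#' Alpha-RRA rank-aggregation score per site
#'
#' Guide LFCs are converted to normalized ranks in (0, 1] (most depleted
#' first). For each site, guides below `alphaCutoff` are compared against
#' uniform order statistics: the score is the minimum over j of
#' `P(Beta(j, k-j+1) <= r_(j))`, so smaller scores indicate stronger
#' negative selection. Permutation p-values come from re-drawing
#' site-sized guide sets from the rank pool (guide-to-site shuffling),
#' pooled by site size.
#'
#' The RRA score distribution has atoms (every site without a guide
#' below `alphaCutoff` scores exactly 1), so permutation p-values are
#' computed with randomized tie-breaking — the standard construction
#' that makes p exactly uniform under the null despite the discrete
#' score. The randomization is part of the seeded stream, so results
#' are reproducible per seed.
#'
#' @inheritParams estimateBeta
#' @param alphaCutoff consider only guides with normalized rank below
#'   this (default 0.05); must be in (0, 1].
#' @param nPermutations null shuffles per site size (default 1000).
#' @return `DataFrame` with `site_id`, `rra_score`, `permutation_p`,
#'   `n_guides`.
#' @export
rraScore <- function(lfc, guideMap, alphaCutoff = 0.05,
                     nPermutations = 1000, seed = 1) {
  if (alphaCutoff <= 0 || alphaCutoff > 1)
    stop("alphaCutoff must be in (0, 1]")
  gm <- as.data.frame(guideMap)
  gm$lfc <- lfc[gm$guide_id]
  r <- rank(gm$lfc, ties.method = "average") / nrow(gm)
  siteR <- split(r[gm$class == "site"], gm$site_id[gm$class == "site"])
  obs <- vapply(siteR, .rraSiteScore, numeric(1), alpha = alphaCutoff)
  nG <- lengths(siteR)
  withSeed(opSeed(seed, "rra_score"), {
    pv <- numeric(length(obs))
    for (sizeN in unique(nG)) {
      null <- vapply(seq_len(nPermutations), function(b)
        .rraSiteScore(sample(r, sizeN), alphaCutoff), numeric(1))
      sel <- which(nG == sizeN)
      below <- colSums(outer(null, obs[sel], "<"))
      ties <- colSums(outer(null, obs[sel], "=="))
      pv[sel] <- (below + runif(length(sel)) * (ties + 1)) /
        (1 + nPermutations)
    }
    out <- DataFrame(site_id = names(obs), rra_score = unname(obs),
                     permutation_p = pv, n_guides = unname(nG))
    metadata(out) <- list(alpha_cutoff = alphaCutoff,
                          n_permutations = nPermutations)
    out
  })
}

#' Copy-number correction of beta-scores
#'
#' Fits `beta ~ copy_number` by least squares over all sites (linear
#' trend by default, the simplest monotone removal of multi-cut
#' toxicity) and subtracts the fitted trend re-anchored at the diploid
#' state: `beta_adj = beta - f(cn) + f(2)`. Sites are matched to the
#' copy segment containing their summit. `neg_rank` is recomputed on the
#' adjusted beta. When all sites share one copy state the adjustment is
#' the identity.
#'
#' @param results `DataFrame` from [estimateBeta()].
#' @param fixture a [GenomeFixture-class] supplying site summits and
#'   copy segments.
#' @return `results` with `beta_cnv_adjusted`, `copy_number` filled and
#'   `neg_rank` recomputed.
#' @export
cnvCorrect <- function(results, fixture) {
  st <- sites(fixture)
  m <- match(results$site_id, st$site_id)
  if (any(is.na(m))) stop("results contain sites absent from the fixture")
  sp <- GRanges(as.character(seqnames(st))[m],
                IRanges(st$summit[m], width = 1L))
  hit <- GenomicRanges::findOverlaps(sp, copySegments(fixture),
                                     select = "first")
  cn <- copySegments(fixture)$copy_number[hit]
  if (length(unique(cn)) < 2L) {
    results$beta_cnv_adjusted <- results$beta
  } else {
    fit <- lm(beta ~ copy_number,
              data = data.frame(beta = results$beta, copy_number = cn))
    trend <- predict(fit, data.frame(copy_number = cn))
    at2 <- predict(fit, data.frame(copy_number = 2))
    results$beta_cnv_adjusted <- results$beta - trend + at2
  }
  results$copy_number <- cn
  results$neg_rank <- rank(results$beta_cnv_adjusted, ties.method = "first")
  results$fdr <- p.adjust(results$p_value, "BH")
  results
}

#' One-call screen scoring
#'
#' Convenience wrapper: normalize (median ratios over the AAVS1
#' negative-control guides when present), compute guide LFCs, estimate
#' betas, and CNV-correct against the fixture.
#'
#' @inheritParams estimateBeta
#' @param sc a [ScreenCounts-class].
#' @param fixture optional [GenomeFixture-class]; when supplied,
#'   [cnvCorrect()] is applied.
#' @param controlClass guide class used for normalization and the
#'   permutation null (default `"AAVS1"`).
#' @param ... passed to [estimateBeta()].
#' @return `DataFrame` of site results.
#' @export
scoreScreen <- function(sc, fixture = NULL, controlClass = "AAVS1", ...) {
  ctrl <- rowData(sc)$guide_id[rowData(sc)$class == controlClass]
  sc <- normalizeCounts(sc, controlGuides = if (length(ctrl)) ctrl)
  lfc <- guideLfc(sc)
  res <- estimateBeta(lfc, rowData(sc), controlClass = controlClass, ...)
  if (!is.null(fixture)) res <- cnvCorrect(res, fixture)
  res
}
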