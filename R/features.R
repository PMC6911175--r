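#' Mean signal in a summit-centered window
#'
#' Averages a bedGraph-style coverage track over a 150-bp window centered
#' on the site summit (300 bp for histone-modification tracks, whose
#' broader marks need the wider window). Positions not covered by the
#' track read as 0; the window is clipped at chromosome ends and the
#' mean is taken over the clipped length.
#'
#' @param track `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open, bedGraph convention) and `value`.
#' @param chrom chromosome of the site.
#' @param summit 1-based summit position.
#' @param featureClass `"tf"` (150 bp) or `"histone_modification"`
#'   (300 bp).
#' @param chromSize optional chromosome length for end clipping.
#' @return scalar mean signal.
#' @export
extractWindowSignal <- function(track, chrom, summit,
                                featureClass = c("tf", "histone_modification"),
                                chromSize = NULL) {
  featureClass <- match.arg(featureClass)
  w <- if (featureClass == "histone_modification") 300L else 150L
  ## 1-based closed window [summit - w/2, summit + w/2 - 1]
  lo <- summit - w %/% 2L
  hi <- summit + w %/% 2L - 1L
  lo <- max(lo, 1L)
  if (!is.null(chromSize)) hi <- min(hi, chromSize)
  winLen <- hi - lo + 1L
  if (winLen <= 0L) return(0)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (!nrow(tr)) return(0)
  ## bedGraph rows cover 1-based positions (start+1)..end
  ov <- pmin(tr$end, hi) - pmax(tr$start + 1L, lo) + 1L
  sum(tr$value * pmax(ov, 0L)) / winLen
}

#' Assemble a per-site feature table from tracks and annotations
#'
#' Computes summit-window signal means for each supplied track, the
#' distance to the nearest gene TSS, the expression and gene-level beta
#' of that nearest gene (ties broken by lower gene coordinate), the
#' copy number at the summit, and motif presence. Missing values are
#' imputed as 0 (absence of coverage) and the affected columns reported
#' via a message.
#'
#' @param fixture a [GenomeFixture-class].
#' @param tracks named list; each element a list with `data` (bedGraph
#'   `data.frame`, see [extractWindowSignal()]) and `class` (`"tf"` or
#'   `"histone_modification"`).
#' @param motifs optional `GRanges` of motif matches; a site scores 1
#'   when its interval overlaps one.
#' @return `DataFrame` with `site_id`, one column per track,
#'   `distance_to_nearest_tss`, `nearby_gene_expression`,
#'   `nearby_gene_beta`, `copy_number`, `motif_presence`.
#' @export
assembleFeatureTable <- function(fixture, tracks = list(), motifs = NULL) {
  st <- sites(fixture)
  gn <- genes(fixture)
  out <- DataFrame(site_id = st$site_id)
  sz <- chromSizes(fixture)
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    out[[nm]] <- vapply(seq_along(st), function(i) {
      extractWindowSignal(tr$data, as.character(seqnames(st))[i],
                          st$summit[i], tr$class,
                          sz[[as.character(seqnames(st))[i]]])
    }, numeric(1))
  }
  ## nearest gene by |TSS - summit|, tie -> lower gene coordinate
  nearest <- vapply(seq_along(st), function(i) {
    same <- which(as.character(seqnames(gn)) ==
                    as.character(seqnames(st))[i])
    if (!length(same)) return(NA_integer_)
    d <- abs(start(gn)[same] - st$summit[i])
    same[order(d, start(gn)[same])][1]
  }, integer(1))
  out$distance_to_nearest_tss <- ifelse(
    is.na(nearest), NA_real_, abs(start(gn)[nearest] - st$summit))
  out$nearby_gene_expression <- gn$expression[nearest]
  out$nearby_gene_beta <- gn$beta_gene[nearest]
  sp <- GRanges(as.character(seqnames(st)), IRanges(st$summit, width = 1L))
  hit <- GenomicRanges::findOverlaps(sp, copySegments(fixture),
                                     select = "first")
  out$copy_number <- copySegments(fixture)$copy_number[hit]
  out$motif_presence <- if (is.null(motifs)) 0L else
    as.integer(GenomicRanges::countOverlaps(st, motifs) > 0)
  imputed <- character(0)
  for (nm in setdiff(names(out), "site_id")) {
    if (anyNA(out[[nm]])) {
      out[[nm]][is.na(out[[nm]])] <- 0
      imputed <- c(imputed, nm)
    }
  }
  if (length(imputed))
    message("imputed missing values as 0 in: ",
            paste(imputed, collapse = ", "))
  metadata(out) <- list(imputed_columns = imputed)
  out
}

#' Rank features by association with site essentiality
#'
#' For each cell line, sites in the lowest `topFrac` of
#' `beta_cnv_adjusted` form the essential group; every feature is
#' compared between that group and all remaining sites with a two-sided
#' Mann-Whitney U test. Per-feature p-values are averaged across cell
#' lines (arithmetic mean) and features are ranked ascending by the
#' average. Direction reports whether the feature runs higher or lower
#' in the essential group (median difference, first cell line with a
#' defined difference).
#'
#' @param tables list of per-cell-line feature `DataFrame`s
#'   (`site_id` + numeric feature columns, identical schemas).
#' @param results list of matching per-cell-line site-result
#'   `DataFrame`s from [estimateBeta()]/[cnvCorrect()].
#' @param topFrac essential fraction, in (0, 0.5] (default 0.05).
#' @return `DataFrame` with `feature`, one `p_<cellline>` column per
#'   input, `p_avg`, `direction`, `flagged` (constant feature), sorted
#'   by `p_avg`.
#' @export
rankFeatures <- function(tables, results, topFrac = 0.05) {
  stopifnot(topFrac > 0, topFrac <= 0.5, length(tables) == length(results))
  if (is.null(names(tables)))
    names(tables) <- paste0("cell", seq_along(tables))
  featNames <- setdiff(names(tables[[1]]), c("site_id", "is_essential"))
  pMat <- matrix(NA_real_, length(featNames), length(tables),
                 dimnames = list(featNames, names(tables)))
  dirMat <- matrix(NA_real_, length(featNames), length(tables),
                   dimnames = dimnames(pMat))
  for (k in seq_along(tables)) {
    tab <- tables[[k]]
    res <- results[[k]]
    m <- match(tab$site_id, res$site_id)
    b <- res$beta_cnv_adjusted[m]
    ess <- b <= quantile(b, topFrac, type = 1)
    for (f in featNames) {
      x <- tab[[f]][ess]; y <- tab[[f]][!ess]
      if (length(unique(c(x, y))) < 2L) {
        pMat[f, k] <- 1
      } else {
        pMat[f, k] <- suppressWarnings(wilcox.test(x, y))$p.value
        dirMat[f, k] <- median(x) - median(y)
      }
    }
  }
  dirFirst <- apply(dirMat, 1, function(d) {
    d <- d[!is.na(d)]; if (length(d)) d[1] else NA_real_
  })
  out <- DataFrame(feature = featNames, as.data.frame(pMat))
  names(out)[-1] <- paste0("p_", names(tables))
  out$p_avg <- unname(rowMeans(pMat))
  out$direction <- unname(ifelse(is.na(dirFirst), NA_character_,
                                 ifelse(dirFirst > 0, "higher_in_essential",
                                        "lower_in_essential")))
  out$flagged <- unname(is.na(dirFirst))
  out[order(out$p_avg), ]
}

#' Proximity enrichment of essential sites and essential genes
#'
#' Tests (Fisher's exact, two-sided) whether essential sites are closer
#' to essential genes than sites at large, and whether essential genes
#' are more often near essential sites than genes at large. Essential
#' genes are the lowest `geneDecile` of `beta_gene`; proximity means
#' TSS-to-summit distance at most `distance`.
#'
#' @param fixture a [GenomeFixture-class].
#' @param essentialSiteIds character vector of essential `site_id`s
#'   (e.g. `fdr < 0.25 & beta < 0` from screen results).
#' @param distance proximity window in bp (default 1e5).
#' @param geneDecile essential-gene quantile of `beta_gene`
#'   (default 0.1).
#' @return list with `site_pct` (percent of all / essential sites near
#'   essential genes), `site_table`, `site_p`, `site_odds_ratio`, and
#'   the mirrored `gene_pct`, `gene_table`, `gene_p`,
#'   `gene_odds_ratio`.
#' @export
proximityEnrichment <- function(fixture, essentialSiteIds, distance = 1e5,
                                geneDecile = 0.1) {
  if (!length(essentialSiteIds)) stop("empty essential site set")
  st <- sites(fixture)
  gn <- genes(fixture)
  essGene <- gn$beta_gene <= quantile(gn$beta_gene, geneDecile, type = 1)
  essSite <- st$site_id %in% essentialSiteIds
  near <- function(posA, chrA, posB, chrB) {
    vapply(seq_along(posA), function(i) {
      j <- chrB == chrA[i]
      any(j) && min(abs(posB[j] - posA[i])) <= distance
    }, logical(1))
  }
  siteNear <- near(st$summit, as.character(seqnames(st)),
                   start(gn)[essGene], as.character(seqnames(gn))[essGene])
  geneNear <- near(start(gn), as.character(seqnames(gn)),
                   st$summit[essSite], as.character(seqnames(st))[essSite])
  siteTab <- table(essential_site = factor(essSite, c(TRUE, FALSE)),
                   near_essential_gene = factor(siteNear, c(TRUE, FALSE)))
  geneTab <- table(essential_gene = factor(essGene, c(TRUE, FALSE)),
                   near_essential_site = factor(geneNear, c(TRUE, FALSE)))
  sampleOR <- function(tab) (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(
    site_pct = c(all = 100 * mean(siteNear),
                 essential = 100 * mean(siteNear[essSite])),
    site_table = siteTab, site_p = fisher.test(siteTab)$p.value,
    site_odds_ratio = sampleOR(siteTab),
    gene_pct = c(all = 100 * mean(geneNear),
                 essential = 100 * mean(geneNear[essGene])),
    gene_table = geneTab, gene_p = fisher.test(geneTab)$p.value,
    gene_odds_ratio = sampleOR(geneTab))
}

#' Compare beta-score distributions between site classes
#'
#' Two-sample Kolmogorov-Smirnov tests between every pair of classes,
#' plus empirical CDFs for plotting cumulative beta distributions.
#'
#' @param betas named numeric vector of per-site (adjusted) beta-scores.
#' @param classMap named character vector mapping `site_id` to class.
#' @return list with `stats` (`DataFrame`: `class1`, `class2`,
#'   `ks_stat`, `p`) and `ecdfs` (named list of `ecdf` functions).
#' @export
compareSiteClasses <- function(betas, classMap) {
  cls <- classMap[names(betas)]
  groups <- split(betas, cls)
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small))
    stop("class with fewer than 2 members: ", paste(small, collapse = ", "))
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  stats <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    kt <- suppressWarnings(ks.test(groups[[a]], groups[[b]]))
    DataFrame(class1 = a, class2 = b,
              ks_stat = unname(kt$statistic), p = kt$p.value)
  }))
  list(stats = stats, ecdfs = lapply(groups, ecdf))
}

#' TAD-boundary and loop-anchor beta comparisons
#'
#' Tests whether sites at TAD boundaries (summit within `pad` of a
#' boundary) and sites inside head-to-head-oriented loop anchors are
#' more depleted than the remaining sites (one Mann-Whitney U test per
#' grouping, two-sided). When an H3K27ac vector is supplied, also
#' contrasts the H3K27ac signal of anchor essential sites, other
#' essential sites, and all sites — the three-way comparison that
#' separates structural from enhancer-like essential CTCF sites.
#'
#' @param results site-result `DataFrame` (needs `site_id`,
#'   `beta_cnv_adjusted`, `fdr`).
#' @param fixture a [GenomeFixture-class].
#' @param h3k27ac optional named numeric vector of H3K27ac signal per
#'   site.
#' @param pad boundary pad in bp (default 1e4).
#' @param essentialFdr FDR threshold defining essential sites for the
#'   H3K27ac contrast (default 0.25).
#' @return list with `boundary` and `anchor` elements (`n_in`, medians,
#'   `p`) and, when `h3k27ac` is given, `h3k27ac` (group medians and
#'   pairwise p-values).
#' @export
tadAnchorAnalysis <- function(results, fixture, h3k27ac = NULL, pad = 1e4,
                              essentialFdr = 0.25) {
  st <- sites(fixture)
  m <- match(results$site_id, st$site_id)
  sp <- GRanges(as.character(seqnames(st))[m],
                IRanges(st$summit[m], width = 1L))
  beta <- results$beta_cnv_adjusted
  padded <- suppressWarnings(GenomicRanges::resize(
    tadBoundaries(fixture), width = 2 * pad + 1, fix = "center"))
  inBoundary <- GenomicRanges::countOverlaps(sp, padded) > 0
  h2h <- anchors(fixture)[anchors(fixture)$head_to_head]
  inAnchor <- GenomicRanges::countOverlaps(sp, h2h) > 0
  grp <- function(sel, what) {
    if (!any(sel) || all(sel)) stop("no sites in ", what, " contrast group")
    list(n_in = sum(sel),
         median_in = median(beta[sel]), median_out = median(beta[!sel]),
         p = suppressWarnings(wilcox.test(beta[sel], beta[!sel]))$p.value)
  }
  out <- list(boundary = grp(inBoundary, "boundary"),
              anchor = grp(inAnchor, "anchor"))
  if (!is.null(h3k27ac)) {
    sig <- h3k27ac[results$site_id]
    ess <- results$fdr < essentialFdr & beta < 0
    gAnchorEss <- sig[ess & inAnchor]
    gOtherEss <- sig[ess & !inAnchor]
    pw <- function(a, b) if (length(a) > 1 && length(b) > 1)
      suppressWarnings(wilcox.test(a, b))$p.value else NA_real_
    out$h3k27ac <- list(
      median_anchor_essential = median(gAnchorEss),
      median_other_essential = median(gOtherEss),
      median_all = median(sig),
      p_anchor_vs_other_essential = pw(gAnchorEss, gOtherEss),
      p_other_essential_vs_all = pw(gOtherEss, sig))
  }
  out
}
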