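#' Assign SNPs to enhancers by the overlap fallback hierarchy
#'
#' Each SNP is assigned the first matching enhancer tier: a DNase I peak
#' overlapping the SNP; failing that, a transcription-factor peak
#' (FOXA1/ER/GATA3-style); failing both, a 150-bp window centered on the
#' SNP. Within a tier, a SNP overlapping several peaks takes the peak
#' whose midpoint is nearest. Input positions are 1-based
#' (GWAS-catalog convention).
#'
#' @param snps `data.frame`/`DataFrame` with `snp_id`, `chrom`, `pos`
#'   (1-based), `trait`.
#' @param dnasePeaks,tfPeaks `GRanges` of peaks; names (or an `id`
#'   mcol) become enhancer ids, otherwise ids are generated.
#' @param windowSize fallback window width in bp (default 150).
#' @return `DataFrame` with `snp_id`, `trait`, `tier` (`"dnase"`,
#'   `"tf_peak"` or `"window150"`), `enhancer_id`, `enh_chrom`,
#'   `enh_start`, `enh_end` (1-based closed coordinates).
#' @export
assignSnpEnhancers <- function(snps, dnasePeaks, tfPeaks,
                               windowSize = 150L) {
  snps <- as.data.frame(snps)
  stopifnot(all(c("snp_id", "chrom", "pos", "trait") %in% names(snps)))
  pk <- function(gr, prefix) {
    if (is.null(gr)) gr <- GRanges()
    ids <- if (!is.null(names(gr)) && all(nzchar(names(gr)))) names(gr)
      else if ("id" %in% names(mcols(gr))) gr$id
      else sprintf("%s_%04d", prefix, seq_along(gr))
    list(gr = gr, ids = ids)
  }
  dn <- pk(dnasePeaks, "dnase")
  tf <- pk(tfPeaks, "tf")
  sp <- GRanges(snps$chrom, IRanges(snps$pos, width = 1L))
  pickNearest <- function(tier) {
    hits <- GenomicRanges::findOverlaps(sp, tier$gr)
    if (!length(hits)) return(rep(NA_integer_, length(sp)))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    mid <- (start(tier$gr)[sh] + end(tier$gr)[sh]) / 2
    d <- abs(mid - snps$pos[qh])
    best <- rep(NA_integer_, length(sp))
    o <- order(qh, d, sh)
    keep <- !duplicated(qh[o])
    best[qh[o][keep]] <- sh[o][keep]
    best
  }
  dnHit <- pickNearest(dn)
  tfHit <- pickNearest(tf)
  n <- nrow(snps)
  tier <- ifelse(!is.na(dnHit), "dnase",
                 ifelse(!is.na(tfHit), "tf_peak", "window150"))
  half <- windowSize %/% 2L
  enhId <- character(n); chrom <- character(n)
  st <- integer(n); en <- integer(n)
  for (i in seq_len(n)) {
    if (tier[i] == "dnase") {
      j <- dnHit[i]
      enhId[i] <- dn$ids[j]; chrom[i] <- as.character(seqnames(dn$gr))[j]
      st[i] <- start(dn$gr)[j]; en[i] <- end(dn$gr)[j]
    } else if (tier[i] == "tf_peak") {
      j <- tfHit[i]
      enhId[i] <- tf$ids[j]; chrom[i] <- as.character(seqnames(tf$gr))[j]
      st[i] <- start(tf$gr)[j]; en[i] <- end(tf$gr)[j]
    } else {
      enhId[i] <- paste0("win150_", snps$snp_id[i])
      chrom[i] <- snps$chrom[i]
      ## 0-based half-open [pos0 - 75, pos0 + 75) => 1-based closed:
      st[i] <- snps$pos[i] - half
      en[i] <- snps$pos[i] + half - 1L
    }
  }
  DataFrame(snp_id = snps$snp_id, trait = snps$trait, tier = tier,
            enhancer_id = enhId, enh_chrom = chrom,
            enh_start = st, enh_end = en)
}

#' Per-trait SNP enrichment over predicted essential enhancers
#'
#' For each trait, builds the 2x2 table of trait SNPs inside/outside the
#' essential enhancer set against background enhancer counts
#' inside/outside, tests it with a chi-squared test (continuity
#' correction off by default; Fisher's exact test is substituted and
#' logged when an expected cell drops below 1), and adjusts across
#' traits by Benjamini-Hochberg. Fold enrichment is the observed
#' in-essential SNP rate over the background essential-enhancer rate.
#'
#' @param assignments `DataFrame` from [assignSnpEnhancers()].
#' @param essentialEnhancers character vector of essential enhancer ids
#'   (must be a subset of `backgroundEnhancers`).
#' @param backgroundEnhancers character vector of all enhancer ids of
#'   the relevant class.
#' @param alpha BH-FDR significance line (default 0.2).
#' @param continuity apply Yates continuity correction (default FALSE).
#' @return `DataFrame` with `trait`, `n_snps`, `n_in_essential`,
#'   `fold_enrichment`, `p`, `adjusted_p`, `method`, `significant`.
#' @export
traitEnrichment <- function(assignments, essentialEnhancers,
                            backgroundEnhancers, alpha = 0.2,
                            continuity = FALSE) {
  if (!all(essentialEnhancers %in% backgroundEnhancers))
    stop("essential set must be a subset of the background")
  nE <- length(unique(essentialEnhancers))
  nB <- length(unique(backgroundEnhancers))
  traits <- unique(assignments$trait)
  rows <- lapply(traits, function(tr) {
    a <- assignments[assignments$trait == tr, , drop = FALSE]
    nIn <- sum(a$enhancer_id %in% essentialEnhancers)
    tab <- matrix(c(nIn, nrow(a) - nIn, nE, nB - nE), nrow = 2,
                  byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      p <- fisher.test(tab)$p.value
      method <- "fisher"
    } else {
      p <- suppressWarnings(chisq.test(tab, correct = continuity)$p.value)
      method <- "chisq"
    }
    DataFrame(trait = tr, n_snps = nrow(a), n_in_essential = nIn,
              fold_enrichment = (nIn / nrow(a)) / (nE / nB),
              p = p, method = method)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p, "BH")
  out$significant <- out$adjusted_p < alpha
  out[, c("trait", "n_snps", "n_in_essential", "fold_enrichment", "p",
          "adjusted_p", "method", "significant")]
}

#' Compare predicted scores of trait-carrying enhancers against all
#'
#' Two-sided Wilcoxon rank-sum test of the predicted essentiality scores
#' of enhancers carrying a trait's SNPs against the scores of all
#' enhancers, per trait.
#'
#' @param assignments `DataFrame` from [assignSnpEnhancers()].
#' @param scores named numeric vector of predicted scores for all
#'   enhancers (names = enhancer ids).
#' @return `DataFrame` with `trait`, `n_enhancers`, `median_trait`,
#'   `median_all`, `p`.
#' @export
scoreComparison <- function(assignments, scores) {
  traits <- unique(assignments$trait)
  rows <- lapply(traits, function(tr) {
    ids <- unique(assignments$enhancer_id[assignments$trait == tr])
    s <- scores[intersect(ids, names(scores))]
    if (length(s) < 2L)
      stop("trait '", tr, "' has fewer than 2 scored enhancers")
    p <- if (identical(sort(unname(s)), sort(unname(scores))) &&
             length(s) == length(scores)) 1 else
      suppressWarnings(wilcox.test(s, scores))$p.value
    DataFrame(trait = tr, n_enhancers = length(s),
              median_trait = median(s), median_all = median(scores), p = p)
  })
  do.call(rbind, rows)
}
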