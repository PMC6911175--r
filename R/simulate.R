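#' Simulate a genome fixture for a binding-site screen
#'
#' Generates a fully specified synthetic annotation context: chromosomes,
#' gene TSSs with gene-level selection scores, binding sites of FOXA1 and
#' CTCF with summits and selection classes, TAD boundaries, loop anchors
#' and a copy-number segmentation. A configurable fraction of sites is
#' placed within `prox_distance` of genes in the lowest decile of
#' `beta_gene` (the "near essential gene" selection class); all remaining
#' sites are placed away from that neighbourhood so the proximal count is
#' exact.
#'
#' @param config named list overriding any of the defaults:
#'   `n_chroms` (3), `chrom_length` (2e7 bp each), `n_genes` (400),
#'   `n_sites` (1000), `class_props` (named proportions over
#'   `strong_signal`, `near_essential_gene`, `constitutive`,
#'   `cell_specific`; the first two map to FOXA1, the last two to CTCF),
#'   `prox_fraction` (fraction of sites placed near bottom-decile genes;
#'   default = the `near_essential_gene` share), `prox_distance` (5e4),
#'   `site_width` (c(200, 600)), `n_tads` (24), `n_anchors` (30),
#'   `segments_per_chrom` (6), `copy_state_probs` (named probabilities of
#'   copy numbers, default c(`1`=.05, `2`=.70, `3`=.15, `4`=.10)).
#' @param seed integer master seed; each simulate stage derives its own
#'   stream from (seed, operation name), so results are reproducible
#'   per stage.
#' @return a [GenomeFixture-class].
#' @examples
#' fx <- simulateGenome(list(n_sites = 100, n_genes = 60), seed = 1)
#' fx
#' @export
simulateGenome <- function(config = list(), seed = 1) {
  cfg <- modifyList(list(
    n_chroms = 3L, chrom_length = 2e7, n_genes = 400L, n_sites = 1000L,
    class_props = c(strong_signal = 0.42, near_essential_gene = 0.10,
                    constitutive = 0.33, cell_specific = 0.15),
    prox_fraction = NULL, prox_distance = 5e4,
    site_width = c(200L, 600L),
    n_tads = 24L, n_anchors = 30L, segments_per_chrom = 6L,
    copy_state_probs = c(`1` = 0.05, `2` = 0.70, `3` = 0.15, `4` = 0.10)
  ), config)

  sz <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms),
                 paste0("chr", seq_len(cfg$n_chroms)))
  if (max(cfg$site_width) >= min(sz))
    stop("requested site widths cannot fit in chrom_sizes")
  if (cfg$n_genes < 1L && cfg$n_sites > 0L)
    stop("need at least one gene to anchor site placement")

  withSeed(opSeed(seed, "simulate_genome"), {
    ## genes: TSS positions, strand, gene-level beta and expression
    chrOfGene <- sample(names(sz), cfg$n_genes, replace = TRUE)
    tss <- floor(runif(cfg$n_genes, 1, sz[chrOfGene]))
    genes <- GRanges(chrOfGene, IRanges(tss, width = 1L),
                     strand = sample(c("+", "-"), cfg$n_genes, TRUE))
    genes$gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    genes$beta_gene <- rnorm(cfg$n_genes, 0, 0.25)
    genes$expression <- pmax(rnorm(cfg$n_genes, 4, 2), 0)
    essTss <- genes[genes$beta_gene <=
                      quantile(genes$beta_gene, 0.1, type = 1)]

    ## binding sites: exact class allocation, then placement
    props <- cfg$class_props[cfg$class_props > 0]
    classCounts <- allocateCounts(cfg$n_sites, props)
    classes <- rep(names(props), classCounts)
    factorOf <- ifelse(classes %in% c("strong_signal", "near_essential_gene"),
                       "FOXA1", "CTCF")
    proxN <- if (is.null(cfg$prox_fraction)) {
      sum(classes == "near_essential_gene")
    } else round(cfg$prox_fraction * cfg$n_sites)
    if (proxN > 0L && length(essTss) == 0L)
      stop("no bottom-decile genes available for proximal site placement")
    ## proximal placement first for the near_essential_gene class
    ord <- order(classes != "near_essential_gene")
    isProx <- logical(cfg$n_sites)
    isProx[ord[seq_len(min(proxN, cfg$n_sites))]] <- TRUE

    widths <- as.integer(round(runif(cfg$n_sites, cfg$site_width[1],
                                     cfg$site_width[2])))
    chrom <- character(cfg$n_sites)
    summit <- integer(cfg$n_sites)
    essByChr <- split(start(essTss), as.character(seqnames(essTss)))
    for (i in seq_len(cfg$n_sites)) {
      if (isProx[i]) {
        j <- sample.int(length(essTss), 1L)
        chrom[i] <- as.character(seqnames(essTss))[j]
        off <- round(runif(1, -0.9, 0.9) * cfg$prox_distance)
        summit[i] <- min(max(start(essTss)[j] + off, widths[i] + 1L),
                         sz[chrom[i]] - widths[i])
      } else {
        for (try in 1:1000) {
          ch <- sample(names(sz), 1L)
          s <- floor(runif(1, widths[i] + 1, sz[ch] - widths[i]))
          near <- essByChr[[ch]]
          if (is.null(near) || all(abs(near - s) > cfg$prox_distance)) break
          if (try == 1000) stop("could not place site away from essential genes")
        }
        chrom[i] <- ch; summit[i] <- as.integer(s)
      }
    }
    offL <- as.integer(floor(runif(cfg$n_sites, 0.2, 0.8) * widths))
    startPos <- pmax(summit - offL, 1L)
    endPos <- pmin(startPos + widths - 1L, sz[chrom])
    summit <- pmin(pmax(summit, startPos), endPos)
    sites <- GRanges(chrom, IRanges(startPos, endPos))
    idx <- ave(seq_along(classes), factorOf, FUN = seq_along)
    sites$site_id <- sprintf("%s_P%04d", factorOf, idx)
    sites$summit <- summit
    sites$factor <- factorOf
    sites$selection_class <- classes
    sites$cell_specificity <- ifelse(
      classes == "cell_specific",
      sample(c("cellA_specific", "cellB_specific"), cfg$n_sites, TRUE),
      ifelse(classes == "constitutive", "shared",
             sample(c("shared", "cellA_specific", "cellB_specific"),
                    cfg$n_sites, TRUE, prob = c(0.6, 0.2, 0.2))))
    sites$context <- sample(c("intronic", "intergenic"), cfg$n_sites, TRUE)

    ## TAD boundaries and loop anchors
    tadChr <- sample(names(sz), cfg$n_tads, replace = TRUE)
    tads <- GRanges(tadChr,
                    IRanges(floor(runif(cfg$n_tads, 1, sz[tadChr])), width = 1L))
    ancChr <- sample(names(sz), cfg$n_anchors, replace = TRUE)
    ancW <- as.integer(round(runif(cfg$n_anchors, 5e3, 2e4)))
    ancS <- floor(runif(cfg$n_anchors, 1, sz[ancChr] - ancW))
    anchors <- GRanges(ancChr, IRanges(ancS, width = ancW))
    anchors$head_to_head <- runif(cfg$n_anchors) < 0.7

    ## copy-number segmentation tiling each chromosome
    segParts <- lapply(names(sz), function(ch) {
      bp <- sort(unique(floor(runif(cfg$segments_per_chrom - 1L, 2, sz[ch]))))
      data.frame(chrom = ch, start = c(1L, as.integer(bp)),
                 end = c(as.integer(bp) - 1L, sz[[ch]]))
    })
    segDf <- do.call(rbind, segParts)
    segs <- GRanges(segDf$chrom, IRanges(segDf$start, segDf$end))
    segs$copy_number <- as.integer(sample(
      names(cfg$copy_state_probs), length(segs), TRUE,
      prob = cfg$copy_state_probs))

    new("GenomeFixture", chromSizes = sz, genes = genes, sites = sites,
        tadBoundaries = tads, anchors = anchors, copySegments = segs)
  })
}

#' Default essential-site feature shifts
#'
#' Log-scale mean shifts applied to essential sites by
#' [simulateFeatures()]. The ordering (DNase accessibility strongest,
#' then nearby-gene essentiality and expression, then H3K27ac and
#' cooperating-factor binding, with the targeted factor's own binding
#' weakly informative) emulates the qualitative feature-relevance
#' ordering observed in binding-site fitness screens.
#'
#' @return named numeric vector of per-feature shifts.
#' @export
defaultEffectSpec <- function() {
  c(DNase = 1.0, nearby_gene_essentiality = 0.9,
    nearby_gene_expression = 0.8, H3K27ac = 0.6, ER_signal = 0.5,
    H3K4me2 = 0.4, FOXA1_signal = 0.2)
}

#' Default feature names emitted by the simulator
#' @return character vector of feature column names.
#' @export
defaultFeatureNames <- function() {
  c("DNase", "H3K27ac", "H3K4me2", "FOXA1_signal", "CTCF_signal",
    "ER_signal", "nearby_gene_expression", "nearby_gene_essentiality",
    "motif_score")
}

#' Simulate per-site features with essential-site shifts
#'
#' Non-essential sites draw every feature from a common Gaussian baseline
#' on the log-signal scale; essential sites are shifted by `effectSpec`.
#' Features with shift 0 are exchangeable between the groups.
#'
#' @param fixture a [GenomeFixture-class].
#' @param effectSpec named numeric vector of log-scale mean shifts for
#'   essential sites; names must be a subset of `features`.
#' @param essential optional logical vector (one per site) marking the
#'   essential group; if `NULL`, drawn Bernoulli(`prevalence`).
#' @param prevalence essential fraction used when `essential` is `NULL`.
#' @param baselineSd baseline standard deviation of each log feature.
#' @param features feature universe (column names).
#' @param seed integer master seed.
#' @return `DataFrame` with `site_id`, generative `is_essential`
#'   indicator and one numeric column per feature; the effect spec is in
#'   `metadata()`.
#' @export
simulateFeatures <- function(fixture, effectSpec = defaultEffectSpec(),
                             essential = NULL, prevalence = 0.05,
                             baselineSd = 1, features = defaultFeatureNames(),
                             seed = 1) {
  bad <- setdiff(names(effectSpec), features)
  if (length(bad))
    stop("unknown feature name in effectSpec: ", paste(bad, collapse = ", "))
  st <- sites(fixture)
  n <- length(st)
  withSeed(opSeed(seed, "simulate_features"), {
    if (is.null(essential)) essential <- runif(n) < prevalence
    stopifnot(length(essential) == n)
    m <- matrix(rnorm(n * length(features), 0, baselineSd), nrow = n,
                dimnames = list(st$site_id, features))
    for (f in names(effectSpec))
      m[essential, f] <- m[essential, f] + effectSpec[[f]]
    out <- DataFrame(site_id = st$site_id, is_essential = essential,
                     as.data.frame(m))
    metadata(out) <- list(effect_spec = effectSpec,
                          baseline_sd = baselineSd)
    out
  })
}

#' Assign ground-truth site selection scores from features
#'
#' Computes a linear score `intercept + sum(weight * feature)` plus
#' Gaussian noise. When `essentialFraction` is given, the score is
#' centred on its `essentialFraction` quantile and values above zero are
#' truncated to zero, so that the requested fraction of sites ends up
#' with `beta_true < 0` (negatively selected). With
#' `essentialFraction = NULL` the raw linear score is returned
#' unmodified.
#'
#' @param features `DataFrame` from [simulateFeatures()] (or any table
#'   with the weighted columns).
#' @param weights named numeric vector over feature columns.
#' @param intercept scalar offset.
#' @param noiseSd Gaussian noise standard deviation.
#' @param essentialFraction target fraction of sites with negative
#'   `beta_true`, or `NULL` for no truncation.
#' @param seed integer master seed.
#' @return `DataFrame` with `site_id`, `beta_true` and `is_essential`
#'   (`beta_true < 0`); generative weights kept in `metadata()`.
#' @export
assignSiteEssentiality <- function(features, weights, intercept = 0,
                                   noiseSd = 0, essentialFraction = NULL,
                                   seed = 1) {
  stopifnot(all(is.finite(weights)))
  miss <- setdiff(names(weights), names(features))
  if (length(miss))
    stop("weights reference unknown features: ", paste(miss, collapse = ", "))
  x <- as.matrix(as.data.frame(features[names(weights)]))
  n <- nrow(x)
  withSeed(opSeed(seed, "assign_site_essentiality"), {
    raw <- as.numeric(intercept + x %*% weights + rnorm(n, 0, noiseSd))
    beta <- if (is.null(essentialFraction)) raw else
      pmin(raw - quantile(raw, essentialFraction, type = 1), 0)
    out <- DataFrame(site_id = features$site_id, beta_true = beta,
                     is_essential = beta < 0)
    metadata(out) <- list(generative_weights = weights,
                          intercept = intercept, noise_sd = noiseSd)
    out
  })
}

#' Ground-truth selection scores from an essential-site indicator
#'
#' Convenience generator: sites flagged essential draw
#' `beta_true ~ Normal(betaMean, betaSd)` (truncated below 0);
#' non-essential sites draw small near-neutral fitness noise
#' `Normal(0, nullSd)` — real elements are rarely exactly neutral, and
#' the residual variation is what a well-powered screen should track.
#'
#' @param features `DataFrame` from [simulateFeatures()] (uses its
#'   `site_id` and `is_essential` columns).
#' @param betaMean,betaSd essential-site selection distribution
#'   (defaults -0.6 and 0.1 per generation).
#' @param nullSd near-neutral spread of non-essential sites
#'   (default 0.05).
#' @param seed integer master seed.
#' @return `DataFrame` with `site_id`, `beta_true`, `is_essential` (the
#'   generative indicator, not a sign test on `beta_true`).
#' @export
simulateTruthFromEssential <- function(features, betaMean = -0.6,
                                       betaSd = 0.1, nullSd = 0.05,
                                       seed = 1) {
  withSeed(opSeed(seed, "simulate_truth"), {
    n <- nrow(features)
    beta <- ifelse(features$is_essential,
                   pmin(rnorm(n, betaMean, betaSd), 0),
                   rnorm(n, 0, nullSd))
    DataFrame(site_id = features$site_id, beta_true = beta,
              is_essential = features$is_essential)
  })
}

#' Simulate guide counts for a designed library
#'
#' Day-0 counts are negative binomial around log-normally spread
#' library-representation means; endpoint means follow exponential growth,
#' `mu_end = mu_0 * 2^(beta_eff * G)` with `G` the effective number of
#' population doublings. The effective selection of a guide is its site's
#' `beta_true` plus an additive copy-number confounder
#' `cnv_effect * (copy_number - 2)` read from the fixture's segmentation.
#' AAVS1 negative-control guides have `beta_eff = 0`; gene-targeting
#' positive controls draw a strongly negative per-gene beta.
#'
#' @param manifest a [LibraryManifest-class].
#' @param truth `DataFrame` with `site_id`, `beta_true` (e.g. from
#'   [assignSiteEssentiality()]); every site-targeting guide must map to
#'   a row.
#' @param fixture a [GenomeFixture-class] supplying copy segments and
#'   site summits.
#' @param params named list overriding defaults: `depth` (500 expected
#'   reads/guide), `dispersion` (0.2; NB variance = mu + dispersion*mu^2),
#'   `replicates` (2 per arm), `generations` (10 doublings over the
#'   screen), `cnv_effect` (-0.1 per extra copy), `posctrl_beta_mean`
#'   (-0.5), `posctrl_beta_sd` (0.1), `libsize_sdlog` (0.3 log-normal
#'   spread of guide representation).
#' @param seed integer master seed.
#' @return a [ScreenCounts-class]; the parameter list used (including
#'   defaults) is stored in its `metadata()`.
#' @export
simulateCounts <- function(manifest, truth, fixture, params = list(),
                           seed = 1) {
  p <- modifyList(list(
    depth = 500, dispersion = 0.2, replicates = 2L, generations = 10,
    cnv_effect = -0.1, posctrl_beta_mean = -0.5, posctrl_beta_sd = 0.1,
    libsize_sdlog = 0.3
  ), params)
  g <- guides(manifest)
  siteRows <- g$class == "site"
  beta <- setNames(truth$beta_true, truth$site_id)
  unk <- setdiff(unique(g$site_id[siteRows]), names(beta))
  if (length(unk))
    stop("guide with no site mapping: ", paste(head(unk, 3), collapse = ", "))

  ## copy number per site (segment containing the summit; tiling => unique)
  st <- sites(fixture)
  sp <- GRanges(as.character(seqnames(st)), IRanges(st$summit, width = 1L))
  hit <- GenomicRanges::findOverlaps(sp, copySegments(fixture),
                                     select = "first")
  cnOfSite <- setNames(copySegments(fixture)$copy_number[hit], st$site_id)

  withSeed(opSeed(seed, "simulate_counts"), {
    n <- nrow(g)
    betaEff <- numeric(n)
    betaEff[siteRows] <- beta[g$site_id[siteRows]] +
      p$cnv_effect * (cnOfSite[g$site_id[siteRows]] - 2)
    ctrlGenes <- unique(g$site_id[g$class == "gene_targeting"])
    if (length(ctrlGenes)) {
      gBeta <- setNames(rnorm(length(ctrlGenes), p$posctrl_beta_mean,
                              p$posctrl_beta_sd), ctrlGenes)
      sel <- g$class == "gene_targeting"
      betaEff[sel] <- gBeta[g$site_id[sel]]
    }
    mu0 <- p$depth * rlnorm(n, -p$libsize_sdlog^2 / 2, p$libsize_sdlog)
    mu1 <- mu0 * 2^(betaEff * p$generations)
    sizeNB <- 1 / p$dispersion
    R <- p$replicates
    cols <- c(paste0("day0_r", seq_len(R)), paste0("endpoint_r", seq_len(R)))
    cnt <- matrix(0L, n, 2L * R, dimnames = list(g$guide_id, cols))
    for (r in seq_len(R)) {
      cnt[, r] <- as.integer(rnbinom(n, mu = mu0, size = sizeNB))
      cnt[, R + r] <- as.integer(rnbinom(n, mu = mu1, size = sizeNB))
    }
    se <- SummarizedExperiment(
      assays = list(counts = cnt),
      rowData = DataFrame(guide_id = g$guide_id, site_id = g$site_id,
                          class = g$class, row.names = g$guide_id),
      colData = DataFrame(sample = cols,
                          timepoint = rep(c("day0", "endpoint"), each = R),
                          replicate = rep(seq_len(R), 2L),
                          row.names = cols))
    out <- new("ScreenCounts", se)
    metadata(out) <- list(params = p, seed = seed)
    out
  })
}

#' Simulate a GWAS-style SNP catalog over the fixture's enhancers
#'
#' SNPs of a trait with enrichment fold 1 land uniformly over enhancer
#' space (binding sites, weighted by width); a fold-f trait places SNPs in
#' essential enhancers at f times the background per-bp rate.
#'
#' @param fixture a [GenomeFixture-class]; its sites are the enhancer
#'   space.
#' @param essentialSites character vector of essential `site_id`s.
#' @param traitSpec `data.frame` with columns `trait`, `n_snps`, `fold`.
#' @param seed integer master seed.
#' @return `DataFrame` with `snp_id`, `chrom`, `pos` (1-based), `trait`
#'   and bookkeeping column `source_site` (the enhancer each SNP was
#'   placed in); the trait spec is kept in `metadata()`.
#' @export
simulateSnpCatalog <- function(fixture, essentialSites, traitSpec, seed = 1) {
  stopifnot(all(c("trait", "n_snps", "fold") %in% names(traitSpec)))
  if (any(traitSpec$fold < 0)) stop("enrichment fold must be >= 0")
  st <- sites(fixture)
  isEss <- st$site_id %in% essentialSites
  withSeed(opSeed(seed, "simulate_snp_catalog"), {
    recs <- lapply(seq_len(nrow(traitSpec)), function(i) {
      w <- width(st) * ifelse(isEss, traitSpec$fold[i], 1)
      k <- traitSpec$n_snps[i]
      j <- sample.int(length(st), k, replace = TRUE, prob = w)
      pos <- floor(runif(k, start(st)[j], end(st)[j] + 1))
      DataFrame(snp_id = sprintf("snp_t%02d_%04d", i, seq_len(k)),
                chrom = as.character(seqnames(st))[j],
                pos = as.integer(pos),
                trait = traitSpec$trait[i],
                source_site = st$site_id[j])
    })
    out <- do.call(rbind, recs)
    metadata(out) <- list(trait_spec = traitSpec,
                          essential_sites = essentialSites)
    out
  })
}
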