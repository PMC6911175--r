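#' Default demo configuration for the end-to-end pipeline
#'
#' A small but complete run: a 500-site fixture, an 8-guide-per-site
#' library with controls, a 2-replicate screen, beta estimation with a
#' control permutation null and CNV correction, feature ranking, a
#' 5-fold-CV SVM (GA feature search off by default for speed), and a
#' two-trait SNP enrichment (one trait injected at 3-fold enrichment,
#' one null).
#'
#' @param nSites fixture size (default 500).
#' @param guidesPerSite guides per site (default 8).
#' @return nested configuration list accepted by [runPipeline()]; it
#'   round-trips through [yaml::as.yaml()] unchanged.
#' @export
demoConfig <- function(nSites = 500, guidesPerSite = 8) {
  list(
    stages = list(simulate = TRUE, design = TRUE, stats = TRUE,
                  features = TRUE, model = TRUE, snp = TRUE),
    simulate = list(n_sites = nSites, n_genes = 200, prevalence = 0.05,
                    beta_mean = -0.6, beta_sd = 0.1),
    design = list(k = guidesPerSite, n_control_genes = 25,
                  guides_per_gene = 5, n_negative = 100),
    stats = list(generations = 10, n_permutations = 500),
    features = list(top_frac = 0.05),
    model = list(folds = 5, use_ga = FALSE,
                 ga = list(pop = 20, iterations = 15)),
    snp = list(traits = list(
      list(trait = "trait_enriched", n_snps = 300, fold = 3),
      list(trait = "trait_null", n_snps = 300, fold = 1)))
  )
}

.need <- function(path, stage, from) {
  if (!file.exists(path))
    stop("stage '", stage, "' requires output of stage '", from,
         "' (", basename(path), "): not found in the run directory")
  path
}

#' Run the simulate-to-SNP pipeline from one configuration
#'
#' Executes the enabled stages in dependency order, handing data between
#' stages as files on disk (TSV/BED/JSON) so any stage can be re-run or
#' inspected independently. A disabled stage's outputs are read back
#' from `outDir` when a later stage needs them; a missing dependency
#' aborts with an error naming the stage that should have produced it.
#' The run manifest (parameters actually used, per-file md5 hashes,
#' failure point if any) is written to `manifest.json`; identical
#' configuration and seed reproduce identical hashes.
#'
#' @param config nested list (see [demoConfig()]), or a path to a YAML
#'   file with the same structure.
#' @param seed integer master seed; stages derive their own streams.
#' @param outDir run directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = demoConfig(), seed = 1,
                        outDir = tempfile("cistrome_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(demoConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outDir, ...)
  manifest <- list(seed = seed, config = cfg, stages = list())
  files <- character(0)
  record <- function(stage, out) {
    manifest$stages[[stage]] <<- list(outputs = basename(out))
    files <<- c(files, out)
  }
  finish <- function(failedStage = NULL, err = NULL) {
    manifest$files <<- lapply(setNames(files, basename(files)),
                              function(f) unname(tools::md5sum(f)))
    if (!is.null(failedStage))
      manifest$failure <<- list(stage = failedStage,
                                message = conditionMessage(err))
    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- "validate"
  res <- tryCatch({
    if (isTRUE(cfg$stages$simulate)) {
      stage <- "simulate"
      fx <- simulateGenome(cfg$simulate[c("n_sites", "n_genes")], seed)
      writeFixture(fx, pth("fixture"))
      feats <- simulateFeatures(fx, prevalence = cfg$simulate$prevalence,
                                seed = seed)
      truth <- simulateTruthFromEssential(
        feats, betaMean = cfg$simulate$beta_mean,
        betaSd = cfg$simulate$beta_sd, seed = seed)
      writeTable(feats, pth("features.tsv"))
      writeTable(truth, pth("truth.tsv"))
      record("simulate", pth(c(file.path("fixture",
        c("chrom_sizes.tsv", "genes.tsv", "sites.bed", "tads.bed",
          "anchors.bed", "copy_number.tsv")),
        "features.tsv", "truth.tsv")))
    }
    getFixture <- function(stg) {
      readFixture(dirname(.need(pth("fixture", "sites.bed"), stg,
                                "simulate")))
    }
    if (isTRUE(cfg$stages$design)) {
      stage <- "design"
      fx <- getFixture("design")
      truth <- readTable(.need(pth("truth.tsv"), "design", "simulate"))
      man <- designLibrary(fx, k = cfg$design$k, seed = seed)
      ctrlGenes <- head(genes(fx)$gene_id[order(genes(fx)$beta_gene)],
                        cfg$design$n_control_genes)
      man <- addControls(man, ctrlGenes, cfg$design$guides_per_gene,
                         cfg$design$n_negative)
      writeManifest(man, pth("library.tsv"))
      writeTable(summarizeLibrary(man), pth("library_summary.tsv"))
      sc <- simulateCounts(man, truth, fx,
                           list(generations = cfg$stats$generations),
                           seed)
      writeCounts(sc, pth("counts.tsv"))
      record("design", pth(c("library.tsv", "library_summary.tsv",
                             "counts.tsv")))
    }
    if (isTRUE(cfg$stages$stats)) {
      stage <- "stats"
      fx <- getFixture("stats")
      sc <- readCounts(.need(pth("counts.tsv"), "stats", "design"))
      res <- scoreScreen(sc, fx, generations = cfg$stats$generations,
                         nPermutations = cfg$stats$n_permutations,
                         seed = seed)
      writeTable(res, pth("site_results.tsv"))
      record("stats", pth("site_results.tsv"))
    }
    if (isTRUE(cfg$stages$features)) {
      stage <- "features"
      fx <- getFixture("features")
      res <- readTable(.need(pth("site_results.tsv"), "features", "stats"))
      feats <- readTable(.need(pth("features.tsv"), "features", "simulate"))
      rk <- rankFeatures(list(cellA = feats), list(cellA = res),
                         topFrac = cfg$features$top_frac)
      writeTable(rk, pth("feature_ranking.tsv"))
      essIds <- res$site_id[res$fdr < 0.25 & res$beta_cnv_adjusted < 0]
      prox <- if (length(essIds)) proximityEnrichment(fx, essIds) else NULL
      ## small fixtures may have no site in a boundary/anchor group;
      ## record the analysis as unavailable rather than failing the run
      ta <- tryCatch(
        tadAnchorAnalysis(res, fx,
                          h3k27ac = setNames(feats$H3K27ac,
                                             feats$site_id)),
        error = function(e) list(unavailable = conditionMessage(e)))
      report <- list(
        proximity = if (is.null(prox)) NULL else
          list(site_pct = as.list(prox$site_pct), site_p = prox$site_p,
               gene_pct = as.list(prox$gene_pct), gene_p = prox$gene_p),
        tad_boundary = ta$boundary, anchor = ta$anchor,
        tad_anchor_note = ta$unavailable)
      jsonlite::write_json(report, pth("association_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      record("features", pth(c("feature_ranking.tsv",
                               "association_report.json")))
    }
    if (isTRUE(cfg$stages$model)) {
      stage <- "model"
      res <- readTable(.need(pth("site_results.tsv"), "model", "stats"))
      feats <- readTable(.need(pth("features.tsv"), "model", "simulate"))
      labs <- labelSites(res,
                         rankThreshold = max(0.05 * nrow(res), 10),
                         seed = seed)
      writeTable(labs, pth("labels.tsv"))
      sel <- if (isTRUE(cfg$model$use_ga)) {
        gaSvmSelect(feats, labs, popSize = cfg$model$ga$pop,
                    nIterations = cfg$model$ga$iterations,
                    seed = seed)$selected
      } else NULL
      mod <- crossValidate(feats, labs, selected = sel,
                           folds = cfg$model$folds, seed = seed)
      scores <- predictScores(mod, feats)
      writeTable(DataFrame(site_id = names(scores), score = scores),
                 pth("scores.tsv"))
      jsonlite::write_json(
        list(selected_features = mod$selected, cv_auc = mod$cv_auc,
             cv_aupr = mod$cv_aupr,
             single_feature_auc = as.list(singleFeatureAucs(feats, labs)),
             roc_points = mod$roc_points, pr_points = mod$pr_points),
        pth("model_report.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      record("model", pth(c("labels.tsv", "scores.tsv",
                            "model_report.json")))
    }
    if (isTRUE(cfg$stages$snp)) {
      stage <- "snp"
      fx <- getFixture("snp")
      truth <- readTable(.need(pth("truth.tsv"), "snp", "simulate"))
      sc <- readTable(.need(pth("scores.tsv"), "snp", "model"))
      traitSpec <- do.call(rbind, lapply(cfg$snp$traits, as.data.frame))
      snps <- simulateSnpCatalog(
        fx, truth$site_id[truth$is_essential], traitSpec, seed)
      writeTable(snps[, c("snp_id", "chrom", "pos", "trait")],
                 pth("snps.tsv"))
      peaks <- sites(fx)
      names(peaks) <- peaks$site_id
      asg <- assignSnpEnhancers(snps, peaks, GRanges())
      writeTable(asg, pth("snp_assignments.tsv"))
      scores <- setNames(sc$score, sc$site_id)
      prevalence <- mean(truth$is_essential)
      essPred <- names(scores)[scores >=
                                 quantile(scores, 1 - prevalence, type = 1)]
      enr <- traitEnrichment(asg, essPred, names(scores))
      writeTable(enr, pth("snp_enrichment.tsv"))
      record("snp", pth(c("snps.tsv", "snp_assignments.tsv",
                          "snp_enrichment.tsv")))
    }
    finish()
    invisible(manifest)
  }, error = function(e) {
    finish(failedStage = stage, err = e)
    stop("pipeline failed in stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  res
}
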