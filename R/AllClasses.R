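#' GenomeFixture: a self-contained synthetic genome annotation
#'
#' Container for everything a binding-site screen needs to know about its
#' genome: chromosome sizes, gene annotations with gene-level selection
#' scores (beta), the targeted binding sites with their summits and
#' selection classes, TAD boundaries, chromatin-loop (CTCF) anchors, and a
#' tiling of copy-number segments.
#'
#' All intervals are held as `GRanges` (1-based, closed); files written by
#' [writeFixture()] use BED conventions (0-based, half-open).
#'
#' @slot chromSizes named integer vector of chromosome lengths (bp).
#' @slot genes `GRanges` of width-1 TSS positions with mcols `gene_id`,
#'   `beta_gene` (gene-level selection score; negative = essential) and
#'   `expression` (log-scale abundance, >= 0).
#' @slot sites `GRanges` of binding-site intervals with mcols `site_id`,
#'   `summit` (1-based position inside the site), `factor`
#'   (`"FOXA1"`/`"CTCF"`), `cell_specificity`, `selection_class`
#'   and `context` (`"intronic"`/`"intergenic"`).
#' @slot tadBoundaries `GRanges` of TAD boundary positions (width 1).
#' @slot anchors `GRanges` of loop-anchor intervals with logical mcol
#'   `head_to_head` (convergent CTCF motif orientation).
#' @slot copySegments `GRanges` tiling each chromosome without overlap,
#'   with integer mcol `copy_number` (>= 0; 2 = diploid).
#'
#' @seealso [simulateGenome()]
#' @export
setClass("GenomeFixture",
  representation(
    chromSizes   = "integer",
    genes        = "GRanges",
    sites        = "GRanges",
    tadBoundaries = "GRanges",
    anchors      = "GRanges",
    copySegments = "GRanges"
  )
)

.checkWithin <- function(gr, sizes, what) {
  if (length(gr) == 0L) return(NULL)
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chr %in% names(sizes)))
    return(sprintf("%s on unknown chromosome", what))
  if (any(GenomicRanges::start(gr) < 1L) ||
      any(GenomicRanges::end(gr) > sizes[chr]))
    return(sprintf("%s outside chromosome bounds", what))
  NULL
}

setValidity("GenomeFixture", function(object) {
  msgs <- character()
  sz <- object@chromSizes
  if (is.null(names(sz)) || any(!nzchar(names(sz))) || any(sz <= 0L))
    msgs <- c(msgs, "chromSizes must be a named positive integer vector")
  for (m in list(.checkWithin(object@genes, sz, "genes"),
                 .checkWithin(object@sites, sz, "sites"),
                 .checkWithin(object@tadBoundaries, sz, "TAD boundaries"),
                 .checkWithin(object@anchors, sz, "anchors"),
                 .checkWithin(object@copySegments, sz, "copy segments")))
    if (!is.null(m)) msgs <- c(msgs, m)
  st <- object@sites
  if (length(st)) {
    need <- c("site_id", "summit", "factor", "selection_class")
    if (!all(need %in% names(mcols(st)))) {
      msgs <- c(msgs, "sites must carry site_id, summit, factor, selection_class")
    } else {
      if (anyDuplicated(st$site_id)) msgs <- c(msgs, "site_id not unique")
      if (any(st$summit < GenomicRanges::start(st)) ||
          any(st$summit > GenomicRanges::end(st)))
        msgs <- c(msgs, "summit outside its site interval")
    }
  }
  cs <- object@copySegments
  if (length(cs)) {
    if (!"copy_number" %in% names(mcols(cs)))
      msgs <- c(msgs, "copy segments need a copy_number column")
    for (chr in unique(as.character(GenomicRanges::seqnames(cs)))) {
      s <- cs[as.character(GenomicRanges::seqnames(cs)) == chr]
      s <- s[order(GenomicRanges::start(s))]
      ok <- GenomicRanges::start(s)[1] == 1L &&
        GenomicRanges::end(s)[length(s)] == sz[chr] &&
        (length(s) == 1L ||
           all(GenomicRanges::start(s)[-1] == GenomicRanges::end(s)[-length(s)] + 1L))
      if (!ok) msgs <- c(msgs, sprintf("copy segments do not tile %s", chr))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' LibraryManifest: a designed guide library
#'
#' Holds the single-guide (and optionally paired-guide) records of a
#' binding-site-targeting CRISPR library, including gene-targeting
#' positive controls and AAVS1 safe-harbor negative controls.
#'
#' @slot guides `DataFrame` with columns `guide_id`, `class`
#'   (`"site"`, `"gene_targeting"`, `"AAVS1"`), `site_id` (the targeted
#'   site, the control gene, or `"AAVS1"`), `factor`, `chrom`, `cut`
#'   (1-based coordinate of the base immediately 3' of the Cas9 blunt
#'   cut), `strand`, `efficiency`, `specificity`.
#' @slot pairs `DataFrame` of paired guides with columns `pair_id`,
#'   `site_id`, `left_cut`, `right_cut` (may have zero rows).
#'
#' @seealso [designLibrary()], [addControls()], [summarizeLibrary()]
#' @export
setClass("LibraryManifest",
  representation(guides = "DataFrame", pairs = "DataFrame")
)

setValidity("LibraryManifest", function(object) {
  g <- object@guides
  msgs <- character()
  need <- c("guide_id", "class", "site_id")
  if (!all(need %in% names(g)))
    msgs <- c(msgs, "guides must carry guide_id, class, site_id")
  else {
    if (anyDuplicated(g$guide_id)) msgs <- c(msgs, "duplicate guide_id")
    if (!all(g$class %in% c("site", "gene_targeting", "AAVS1")))
      msgs <- c(msgs, "unknown guide class")
    if (any(g$class == "site" & (is.na(g$site_id) | !nzchar(g$site_id))))
      msgs <- c(msgs, "site-targeting guide without a site_id")
  }
  p <- object@pairs
  if (nrow(p) && !all(c("pair_id", "site_id", "left_cut", "right_cut") %in% names(p)))
    msgs <- c(msgs, "pairs must carry pair_id, site_id, left_cut, right_cut")
  if (nrow(p) && any(p$left_cut >= p$right_cut))
    msgs <- c(msgs, "left_cut must be < right_cut")
  if (length(msgs)) msgs else TRUE
})

#' ScreenCounts: guide-level counts of a pooled screen
#'
#' A `SummarizedExperiment` whose `counts` assay holds non-negative
#' integer guide abundances. `rowData` carries the guide-to-site map
#' (`guide_id`, `site_id`, `class`); `colData` carries `timepoint`
#' (`"day0"`/`"endpoint"`) and `replicate`. [normalizeCounts()] adds a
#' `normalized` assay and per-sample size factors.
#'
#' @seealso [simulateCounts()], [normalizeCounts()], [guideLfc()]
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  msgs <- character()
  if (!"counts" %in% assayNames(object))
    msgs <- c(msgs, "needs a 'counts' assay")
  else {
    cnt <- assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msgs <- c(msgs, "counts must be non-negative integers")
  }
  if (!all(c("guide_id", "site_id", "class") %in% names(rowData(object))))
    msgs <- c(msgs, "rowData needs guide_id, site_id, class")
  cd <- colData(object)
  if (!"timepoint" %in% names(cd) ||
      !all(cd$timepoint %in% c("day0", "endpoint")))
    msgs <- c(msgs, "colData$timepoint must be 'day0' or 'endpoint'")
  if (length(msgs)) msgs else TRUE
})
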