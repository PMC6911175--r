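#' Scan a binding site for candidate sgRNAs
#'
#' In sequence mode, both strands of the supplied sequence are scanned
#' for SpCas9 NGG protospacer-adjacent motifs with a full 20-nt
#' protospacer, and the blunt cut is placed 3 bp 5' of the PAM. The cut
#' coordinate convention is the 1-based genomic position of the base
#' immediately 3' (plus strand) of the cut: for a plus-strand PAM whose N
#' is at position q the cut is at `q - 3`; for a minus-strand PAM (CCN on
#' the plus strand starting at p) the cut is at `p + 6`. In synthetic
#' mode a candidate table is passed through unchanged apart from the
#' within-site filter.
#'
#' @param site `GRanges` of length 1 with a `summit` and `site_id` mcol.
#' @param sequence optional `DNAString` (or character) covering the
#'   region around the site; its first base has genomic coordinate
#'   `seqOffset`.
#' @param candidates optional `data.frame`/`DataFrame` with columns
#'   `cut`, `strand` and optionally `efficiency`, `specificity`
#'   (synthetic mode).
#' @param seqOffset 1-based genomic coordinate of `sequence[1]`;
#'   defaults to `start(site)`.
#' @param scorer optional `function(candidates)` returning a
#'   `data.frame` with `efficiency` and `specificity` in `[0, 1]`;
#'   by default unscored candidates get 1 for both.
#' @return `DataFrame` of guide candidates (`guide_id`, `site_id`,
#'   `cut`, `strand`, `efficiency`, `specificity`), all cutting within
#'   the site interval. Empty (zero-row) when no PAM is found.
#' @examples
#' site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 60))
#' site$site_id <- "s1"; site$summit <- 30L
#' scanGuides(site, sequence = paste(rep("A", 60), collapse = ""))
#' @export
scanGuides <- function(site, sequence = NULL, candidates = NULL,
                       seqOffset = NULL, scorer = NULL) {
  stopifnot(length(site) == 1L)
  if (width(site) < 1L) stop("empty site interval")
  lo <- start(site); hi <- end(site)
  if (!is.null(candidates)) {
    cand <- DataFrame(candidates)
    if (!"efficiency" %in% names(cand)) cand$efficiency <- rep(1, nrow(cand))
    if (!"specificity" %in% names(cand)) cand$specificity <- rep(1, nrow(cand))
    keep <- cand$cut >= lo & cand$cut <= hi
    cand <- cand[keep, , drop = FALSE]
  } else {
    if (is.null(sequence)) stop("need either a sequence or candidates")
    seq <- Biostrings::DNAString(as.character(sequence))
    if (is.null(seqOffset)) seqOffset <- lo
    len <- length(seq)
    ## plus strand: GG at (p, p+1), PAM N at p-1, 20-nt protospacer 5' of it
    gg <- start(Biostrings::matchPattern("GG", seq))
    gg <- gg[gg - 1 >= 21]                       # protospacer fits
    plusCut <- (gg - 1) - 3 + (seqOffset - 1)
    ## minus strand: CC at (p, p+1) on plus strand, protospacer 3' of PAM
    cc <- start(Biostrings::matchPattern("CC", seq))
    cc <- cc[cc + 22 <= len]
    minusCut <- cc + 6 + (seqOffset - 1)
    cand <- DataFrame(
      cut = c(plusCut, minusCut),
      strand = rep(c("+", "-"), c(length(plusCut), length(minusCut))))
    cand <- cand[cand$cut >= lo & cand$cut <= hi, , drop = FALSE]
    if (nrow(cand)) {
      sc <- if (is.null(scorer)) {
        data.frame(efficiency = rep(1, nrow(cand)),
                   specificity = rep(1, nrow(cand)))
      } else scorer(cand)
      cand$efficiency <- sc$efficiency
      cand$specificity <- sc$specificity
    } else {
      cand$efficiency <- numeric(0)
      cand$specificity <- numeric(0)
    }
  }
  if (nrow(cand)) {
    cand <- cand[order(cand$cut, cand$strand != "+"), , drop = FALSE]
    cand$site_id <- site$site_id
    cand$guide_id <- sprintf("%s_sg%02d", site$site_id, seq_len(nrow(cand)))
  } else {
    cand$site_id <- character(0)
    cand$guide_id <- character(0)
  }
  rownames(cand) <- NULL
  cand[, c("guide_id", "site_id", "cut", "strand", "efficiency",
           "specificity")]
}

#' Filter guide candidates on predicted efficiency and specificity
#'
#' @param candidates `DataFrame` from [scanGuides()].
#' @param minEfficiency,minSpecificity thresholds in `[0, 1]`; a
#'   candidate is kept when both scores meet their threshold. Order is
#'   preserved.
#' @return the filtered `DataFrame`.
#' @export
filterGuides <- function(candidates, minEfficiency = 0, minSpecificity = 0) {
  stopifnot(minEfficiency >= 0, minEfficiency <= 1,
            minSpecificity >= 0, minSpecificity <= 1)
  keep <- candidates$efficiency >= minEfficiency &
    candidates$specificity >= minSpecificity
  candidates[keep, , drop = FALSE]
}

#' Select up to k guides nearest the binding-site summit
#'
#' Candidates are ranked by `|cut - summit|`; ties are broken by lower
#' coordinate, then plus strand. If fewer than `k` candidates remain
#' after filtering, all are returned.
#'
#' @param candidates `DataFrame` with a `cut` column.
#' @param summit 1-based summit position.
#' @param k maximum number of guides (default 20).
#' @return the selected `DataFrame`, nearest first.
#' @export
selectGuides <- function(candidates, summit, k = 20) {
  stopifnot(k >= 1)
  if (nrow(candidates) == 0L) return(candidates)
  d <- abs(candidates$cut - summit)
  o <- order(d, candidates$cut, candidates$strand != "+")
  candidates[o[seq_len(min(k, length(o)))], , drop = FALSE]
}

#' Design paired guides whose deletion spans a binding site
#'
#' Combines left-flank and right-flank cut candidates into pairs whose
#' deletion interval `(left_cut, right_cut)` contains the site interval,
#' ranked by total flanking distance (smallest deletion first) and
#' deduplicated; at most `k` pairs are returned.
#'
#' @param site `GRanges` of length 1 with `site_id`.
#' @param candidatesLeft,candidatesRight `DataFrame`s with a `cut`
#'   column (e.g. from [scanGuides()] on the flanks).
#' @param flankWindow maximum cut-to-site distance in bp (default 1000).
#' @param k maximum number of pairs (default 25).
#' @return `DataFrame` with `pair_id`, `site_id`, `left_cut`,
#'   `right_cut`; zero rows when no valid pair exists.
#' @export
designPgRNAs <- function(site, candidatesLeft, candidatesRight,
                         flankWindow = 1000, k = 25) {
  stopifnot(length(site) == 1L, k >= 1)
  lo <- start(site); hi <- end(site)
  lc <- unique(candidatesLeft$cut)
  rc <- unique(candidatesRight$cut)
  lc <- lc[lc < lo & lc >= lo - flankWindow]
  rc <- rc[rc > hi & rc <= hi + flankWindow]
  if (!length(lc) || !length(rc))
    return(DataFrame(pair_id = character(0), site_id = character(0),
                     left_cut = integer(0), right_cut = integer(0)))
  grid <- expand.grid(left_cut = lc, right_cut = rc)
  dist <- (lo - grid$left_cut) + (grid$right_cut - hi)
  o <- order(dist, grid$left_cut, grid$right_cut)
  grid <- grid[o[seq_len(min(k, nrow(grid)))], , drop = FALSE]
  DataFrame(pair_id = sprintf("%s_pg%02d", site$site_id,
                              seq_len(nrow(grid))),
            site_id = site$site_id,
            left_cut = as.integer(grid$left_cut),
            right_cut = as.integer(grid$right_cut))
}

#' Design a site-targeting sgRNA library over a fixture
#'
#' For every binding site, candidate guides are generated (synthetic
#' candidate model: positions uniform over the site, efficiency and
#' specificity uniform on `[0, 1]`), filtered on the score thresholds,
#' and the up-to-`k` candidates nearest the summit are selected. When
#' `totalGuides` is given the stochastic attrition is replaced by an
#' exact per-site allocation (floor/ceil of `totalGuides / n_sites`), so
#' a manifest reproduces a prescribed library size precisely.
#'
#' @param fixture a [GenomeFixture-class] (all its sites are targeted).
#' @param k maximum guides per site (default 20).
#' @param candidateRange integer range of raw candidates drawn per site
#'   before filtering (default 18-40).
#' @param minEfficiency,minSpecificity filtering thresholds (default 0.2
#'   each; these are configuration, not constants of the method).
#' @param totalGuides optional exact total number of site-targeting
#'   guides to emit.
#' @param seed integer master seed.
#' @return a [LibraryManifest-class] without controls (see
#'   [addControls()]).
#' @export
designLibrary <- function(fixture, k = 20, candidateRange = c(18L, 40L),
                          minEfficiency = 0.2, minSpecificity = 0.2,
                          totalGuides = NULL, seed = 1) {
  st <- sites(fixture)
  n <- length(st)
  stopifnot(n > 0L)
  withSeed(opSeed(seed, "design_library"), {
    if (!is.null(totalGuides)) {
      alloc <- allocateCounts(totalGuides, rep(1, n))
      if (any(alloc < 1L) || any(alloc > k))
        stop("totalGuides not reachable with <= ", k, " guides per site")
    } else alloc <- NULL
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      lo <- start(st)[i]; hi <- end(st)[i]
      if (is.null(alloc)) {
        m <- sample(seq(candidateRange[1], candidateRange[2]), 1L)
        cand <- DataFrame(cut = as.integer(floor(runif(m, lo, hi + 1))),
                          strand = sample(c("+", "-"), m, TRUE),
                          efficiency = runif(m), specificity = runif(m))
        cand <- filterGuides(cand, minEfficiency, minSpecificity)
        cand <- selectGuides(cand, st$summit[i], k)
      } else {
        m <- alloc[i]
        cand <- DataFrame(cut = as.integer(floor(runif(m, lo, hi + 1))),
                          strand = sample(c("+", "-"), m, TRUE),
                          efficiency = runif(m, minEfficiency, 1),
                          specificity = runif(m, minSpecificity, 1))
      }
      if (nrow(cand) == 0L) next
      rows[[i]] <- DataFrame(
        guide_id = sprintf("%s_sg%02d", st$site_id[i], seq_len(nrow(cand))),
        class = "site", site_id = st$site_id[i],
        factor = st$factor[i],
        chrom = as.character(seqnames(st))[i],
        cut = cand$cut, strand = cand$strand,
        efficiency = cand$efficiency, specificity = cand$specificity)
    }
    g <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    new("LibraryManifest", guides = g,
        pairs = DataFrame(pair_id = character(0), site_id = character(0),
                          left_cut = integer(0), right_cut = integer(0)))
  })
}

#' Add gene-targeting and AAVS1 control guides to a manifest
#'
#' @param manifest a [LibraryManifest-class].
#' @param essentialGeneIds character vector of positive-control gene ids.
#' @param guidesPerGene guides per control gene (default 5).
#' @param nNegative number of AAVS1 safe-harbor negative-control guides
#'   (default 267).
#' @return the manifest with control guide rows appended.
#' @export
addControls <- function(manifest, essentialGeneIds, guidesPerGene = 5,
                        nNegative = 267) {
  stopifnot(guidesPerGene >= 1)
  g <- guides(manifest)
  mk <- function(ids, cls) {
    if (!length(ids)) return(NULL)
    DataFrame(guide_id = ids, class = cls,
              site_id = sub("_sg[0-9]+$", "", ids),
              factor = NA_character_, chrom = NA_character_,
              cut = NA_integer_, strand = NA_character_,
              efficiency = NA_real_, specificity = NA_real_)
  }
  geneIds <- if (length(essentialGeneIds)) {
    as.vector(t(outer(essentialGeneIds, seq_len(guidesPerGene),
                      function(a, b) sprintf("%s_sg%d", a, b))))
  } else character(0)
  negIds <- if (nNegative > 0) sprintf("AAVS1_sg%03d", seq_len(nNegative))
    else character(0)
  parts <- Filter(Negate(is.null),
                  list(mk(geneIds, "gene_targeting"), mk(negIds, "AAVS1")))
  newRows <- if (length(parts)) do.call(rbind, parts) else NULL
  if (!is.null(newRows)) {
    dup <- intersect(newRows$guide_id, g$guide_id)
    if (length(dup))
      stop("duplicate control IDs: ", paste(head(dup, 3), collapse = ", "))
    g <- rbind(g, newRows)
  }
  initialize(manifest, guides = g)
}

#' Attach paired guides designed for each site to a manifest
#'
#' Synthetic-mode pgRNA designer: flanking cut candidates are drawn
#' uniformly in a `flankWindow` on each side of every site and combined
#' with [designPgRNAs()].
#'
#' @inheritParams designLibrary
#' @param manifest a [LibraryManifest-class].
#' @param k maximum pairs per site (default 25).
#' @param flankWindow flank size in bp (default 1000).
#' @param candidatesPerFlank flanking candidates drawn per side
#'   (default 8).
#' @return the manifest with its `pairs` slot filled.
#' @export
designPairedLibrary <- function(manifest, fixture, k = 25,
                                flankWindow = 1000, candidatesPerFlank = 8L,
                                seed = 1) {
  st <- sites(fixture)
  withSeed(opSeed(seed, "design_paired_library"), {
    rows <- lapply(seq_along(st), function(i) {
      lo <- start(st)[i]; hi <- end(st)[i]
      left <- DataFrame(cut = as.integer(floor(
        runif(candidatesPerFlank, max(lo - flankWindow, 1), lo))))
      right <- DataFrame(cut = as.integer(floor(
        runif(candidatesPerFlank, hi + 1, hi + flankWindow + 1))))
      designPgRNAs(st[i], left, right, flankWindow, k)
    })
    pairs <- do.call(rbind, rows)
    initialize(manifest, pairs = pairs)
  })
}

#' Summarize a library manifest (Table-1 style)
#'
#' @param manifest a [LibraryManifest-class].
#' @return `data.frame` with one column per targeted factor plus a
#'   `total` column; rows: `binding_sites`, `sgrnas`,
#'   `guides_per_site_min`, `guides_per_site_max`,
#'   `gene_targeting_sgrnas`, `aavs1_sgrnas`, `pg_pairs`.
#' @export
summarizeLibrary <- function(manifest) {
  g <- guides(manifest)
  siteG <- g[g$class == "site", , drop = FALSE]
  facs <- sort(unique(stats::na.omit(siteG$factor)))
  perSite <- if (nrow(siteG)) table(siteG$site_id) else integer(0)
  col <- function(fac) {
    sel <- siteG$factor == fac
    ps <- table(siteG$site_id[sel])
    c(binding_sites = length(unique(siteG$site_id[sel])),
      sgrnas = sum(sel),
      guides_per_site_min = if (length(ps)) min(ps) else 0L,
      guides_per_site_max = if (length(ps)) max(ps) else 0L,
      gene_targeting_sgrnas = sum(g$class == "gene_targeting"),
      aavs1_sgrnas = sum(g$class == "AAVS1"),
      pg_pairs = if (nrow(manifest@pairs))
        sum(manifest@pairs$site_id %in% siteG$site_id[sel]) else 0L)
  }
  out <- if (length(facs)) {
    as.data.frame(lapply(setNames(facs, facs), col))
  } else {
    data.frame(row.names = c("binding_sites", "sgrnas",
                             "guides_per_site_min", "guides_per_site_max",
                             "gene_targeting_sgrnas", "aavs1_sgrnas",
                             "pg_pairs"))
  }
  out$total <- if (length(facs)) {
    c(sum(out["binding_sites", seq_along(facs)]),
      sum(out["sgrnas", seq_along(facs)]),
      if (length(perSite)) min(perSite) else 0L,
      if (length(perSite)) max(perSite) else 0L,
      sum(g$class == "gene_targeting"),
      sum(g$class == "AAVS1"),
      nrow(manifest@pairs))
  } else {
    rep(0L, 7L)[seq_len(nrow(out))]
  }
  out
}
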