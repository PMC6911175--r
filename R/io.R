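## All BED-style files are written 0-based half-open; TSVs with a header
## keep 1-based positions where the column is a point coordinate (tss,
## pos, summit written as BED offset). Readers invert the conversion, so
## every writer/reader pair round-trips exactly.

.writeTsv <- function(df, path, col.names = TRUE) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = col.names)
}

#' Write / read a genome fixture as plain-text files
#'
#' `writeFixture()` writes `chrom_sizes.tsv`, `genes.tsv`,
#' `sites.bed` (BED6 + summit offset, factor, selection class, cell
#' specificity, context), `tads.bed`, `anchors.bed` (name column holds
#' the head-to-head flag), and `copy_number.tsv` (0-based half-open).
#' `readFixture()` reconstructs the [GenomeFixture-class] from such a
#' directory.
#'
#' @param fixture a [GenomeFixture-class].
#' @param dir output/input directory.
#' @return `writeFixture()` the directory (invisibly); `readFixture()`
#'   a `GenomeFixture`.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sz <- chromSizes(fixture)
  .writeTsv(data.frame(chrom = names(sz), length = unname(sz)),
            file.path(dir, "chrom_sizes.tsv"))
  gn <- genes(fixture)
  .writeTsv(data.frame(gene_id = gn$gene_id,
                       chrom = as.character(seqnames(gn)),
                       tss = start(gn),
                       strand = as.character(strand(gn)),
                       beta_gene = gn$beta_gene,
                       expression = gn$expression),
            file.path(dir, "genes.tsv"))
  st <- sites(fixture)
  .writeTsv(data.frame(chrom = as.character(seqnames(st)),
                       start = start(st) - 1L, end = end(st),
                       name = st$site_id, score = 0L, strand = ".",
                       summit_offset = st$summit - start(st),
                       factor = st$factor,
                       selection_class = st$selection_class,
                       cell_specificity = st$cell_specificity,
                       context = st$context),
            file.path(dir, "sites.bed"), col.names = FALSE)
  td <- tadBoundaries(fixture)
  .writeTsv(data.frame(chrom = as.character(seqnames(td)),
                       start = start(td) - 1L, end = end(td)),
            file.path(dir, "tads.bed"), col.names = FALSE)
  an <- anchors(fixture)
  .writeTsv(data.frame(chrom = as.character(seqnames(an)),
                       start = start(an) - 1L, end = end(an),
                       name = ifelse(an$head_to_head, "head_to_head",
                                     "other")),
            file.path(dir, "anchors.bed"), col.names = FALSE)
  cs <- copySegments(fixture)
  .writeTsv(data.frame(chrom = as.character(seqnames(cs)),
                       start = start(cs) - 1L, end = end(cs),
                       copy_number = cs$copy_number),
            file.path(dir, "copy_number.tsv"))
  invisible(dir)
}

#' @rdname writeFixture
#' @export
readFixture <- function(dir) {
  szd <- read.delim(file.path(dir, "chrom_sizes.tsv"))
  sz <- setNames(as.integer(szd$length), szd$chrom)
  g <- read.delim(file.path(dir, "genes.tsv"))
  gn <- GRanges(g$chrom, IRanges(g$tss, width = 1L), strand = g$strand)
  gn$gene_id <- g$gene_id; gn$beta_gene <- g$beta_gene
  gn$expression <- g$expression
  s <- read.delim(file.path(dir, "sites.bed"), header = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score",
                                "strand", "summit_offset", "factor",
                                "selection_class", "cell_specificity",
                                "context"))
  st <- GRanges(s$chrom, IRanges(s$start + 1L, s$end))
  st$site_id <- s$name
  st$summit <- as.integer(s$start + 1L + s$summit_offset)
  st$factor <- s$factor; st$selection_class <- s$selection_class
  st$cell_specificity <- s$cell_specificity; st$context <- s$context
  t <- read.delim(file.path(dir, "tads.bed"), header = FALSE,
                  col.names = c("chrom", "start", "end"))
  td <- GRanges(t$chrom, IRanges(t$start + 1L, t$end))
  a <- read.delim(file.path(dir, "anchors.bed"), header = FALSE,
                  col.names = c("chrom", "start", "end", "name"))
  an <- GRanges(a$chrom, IRanges(a$start + 1L, a$end))
  an$head_to_head <- a$name == "head_to_head"
  cc <- read.delim(file.path(dir, "copy_number.tsv"))
  cs <- GRanges(cc$chrom, IRanges(cc$start + 1L, cc$end))
  cs$copy_number <- as.integer(cc$copy_number)
  new("GenomeFixture", chromSizes = sz, genes = gn, sites = st,
      tadBoundaries = td, anchors = an, copySegments = cs)
}

#' Write / read a guide count table
#'
#' TSV with columns `guide_id`, `site_id`, `class` followed by one
#' column per sample; sample timepoints are encoded in the column names
#' (`day0_*` / `endpoint_*`).
#'
#' @param sc a [ScreenCounts-class].
#' @param path file path.
#' @return `writeCounts()` the path invisibly; `readCounts()` a
#'   `ScreenCounts`.
#' @export
writeCounts <- function(sc, path) {
  rd <- rowData(sc)
  df <- data.frame(guide_id = rd$guide_id, site_id = rd$site_id,
                   class = rd$class, as.data.frame(assay(sc, "counts")),
                   check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  sampleCols <- setdiff(names(df), c("guide_id", "site_id", "class"))
  cnt <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(cnt) <- df$guide_id
  storage.mode(cnt) <- "integer"
  tp <- ifelse(grepl("^day0", sampleCols), "day0", "endpoint")
  se <- SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = DataFrame(guide_id = df$guide_id, site_id = df$site_id,
                        class = df$class, row.names = df$guide_id),
    colData = DataFrame(sample = sampleCols, timepoint = tp,
                        replicate = as.integer(sub(".*_r", "", sampleCols)),
                        row.names = sampleCols))
  new("ScreenCounts", se)
}

#' Write / read simple record tables
#'
#' TSV writers/readers for site results, ground-truth essentiality,
#' SNP catalogs, feature tables and library manifests. All are plain
#' header-bearing TSVs whose columns match the corresponding
#' `DataFrame`s.
#'
#' @param x the table to write.
#' @param path file path.
#' @return writers return the path invisibly; readers a `DataFrame`
#'   (or [LibraryManifest-class] for `readManifest()`).
#' @name table-io
NULL

#' @rdname table-io
#' @export
writeTable <- function(x, path) {
  .writeTsv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname table-io
#' @export
readTable <- function(path) DataFrame(read.delim(path, check.names = FALSE))

#' @rdname table-io
#' @export
writeManifest <- function(x, path) {
  .writeTsv(as.data.frame(guides(x)), path)
  if (nrow(guidePairs(x)))
    .writeTsv(as.data.frame(guidePairs(x)),
              sub("\\.tsv$", "_pairs.tsv", path))
  invisible(path)
}

#' @rdname table-io
#' @export
readManifest <- function(path) {
  g <- DataFrame(read.delim(path, check.names = FALSE))
  pp <- sub("\\.tsv$", "_pairs.tsv", path)
  pairs <- if (file.exists(pp)) DataFrame(read.delim(pp)) else
    DataFrame(pair_id = character(0), site_id = character(0),
              left_cut = integer(0), right_cut = integer(0))
  new("LibraryManifest", guides = g, pairs = pairs)
}
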