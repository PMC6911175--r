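#' Accessors for GenomeFixture and LibraryManifest
#'
#' `chromSizes()`, `genes()`, `sites()`, `tadBoundaries()`, `anchors()`
#' and `copySegments()` extract the corresponding slot of a
#' [GenomeFixture-class]; `guides()` and `guidePairs()` extract the guide
#' tables of a [LibraryManifest-class].
#'
#' @param x a `GenomeFixture` or `LibraryManifest`.
#' @return the slot contents (a named integer vector for `chromSizes`,
#'   `GRanges` for the interval slots, `DataFrame` for guide tables).
#' @name fixture-accessors
NULL

#' @rdname fixture-accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @rdname fixture-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname fixture-accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname fixture-accessors
#' @export
setGeneric("tadBoundaries", function(x) standardGeneric("tadBoundaries"))
#' @rdname fixture-accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname fixture-accessors
#' @export
setGeneric("copySegments", function(x) standardGeneric("copySegments"))
#' @rdname fixture-accessors
#' @export
setGeneric("guides", function(x) standardGeneric("guides"))
#' @rdname fixture-accessors
#' @export
setGeneric("guidePairs", function(x) standardGeneric("guidePairs"))

#' @rdname fixture-accessors
setMethod("chromSizes", "GenomeFixture", function(x) x@chromSizes)
#' @rdname fixture-accessors
setMethod("genes", "GenomeFixture", function(x) x@genes)
#' @rdname fixture-accessors
setMethod("sites", "GenomeFixture", function(x) x@sites)
#' @rdname fixture-accessors
setMethod("tadBoundaries", "GenomeFixture", function(x) x@tadBoundaries)
#' @rdname fixture-accessors
setMethod("anchors", "GenomeFixture", function(x) x@anchors)
#' @rdname fixture-accessors
setMethod("copySegments", "GenomeFixture", function(x) x@copySegments)
#' @rdname fixture-accessors
setMethod("guides", "LibraryManifest", function(x) x@guides)
#' @rdname fixture-accessors
setMethod("guidePairs", "LibraryManifest", function(x) x@pairs)

setMethod("show", "GenomeFixture", function(object) {
  cat("GenomeFixture\n")
  cat(sprintf("  %d chromosome(s), %.1f Mb total\n",
              length(object@chromSizes), sum(object@chromSizes) / 1e6))
  cat(sprintf("  %d genes, %d binding sites", length(object@genes),
              length(object@sites)))
  if (length(object@sites))
    cat(sprintf(" (%s)", paste(sprintf("%s: %d",
      names(table(object@sites$factor)), table(object@sites$factor)),
      collapse = ", ")))
  cat("\n")
  cat(sprintf("  %d TAD boundaries, %d anchors, %d copy segments\n",
              length(object@tadBoundaries), length(object@anchors),
              length(object@copySegments)))
})

setMethod("show", "LibraryManifest", function(object) {
  g <- object@guides
  cat("LibraryManifest\n")
  tab <- table(g$class)
  for (cl in names(tab)) cat(sprintf("  %s guides: %d\n", cl, tab[[cl]]))
  nsite <- length(unique(g$site_id[g$class == "site"]))
  cat(sprintf("  binding sites targeted: %d\n", nsite))
  if (nrow(object@pairs))
    cat(sprintf("  paired guides: %d (%d sites)\n", nrow(object@pairs),
                length(unique(object@pairs$site_id))))
})
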