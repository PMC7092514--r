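#' @name accessors
#' @title Accessors for spliceScape classes
#' @param x an object
#' @description Slot accessors: prefer these over `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname accessors
#' @export
setGeneric("cdsSpans", function(x) standardGeneric("cdsSpans"))
#' @rdname accessors
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))
#' @rdname accessors
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))
#' @rdname accessors
#' @export
setGeneric("regionProportions", function(x) standardGeneric("regionProportions"))
#' @rdname accessors
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))
#' @rdname accessors
#' @export
setGeneric("goParentProportions",
           function(x) standardGeneric("goParentProportions"))
#' @rdname accessors
#' @export
setGeneric("psiAssay", function(x) standardGeneric("psiAssay"))
#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname accessors
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname accessors
#' @export
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("chromName", "TranscriptModel", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("strand", "TranscriptModel", function(x) x@strand)
#' @rdname accessors
#' @export
setMethod("exons", "TranscriptModel", function(x) x@exons)
#' @rdname accessors
#' @export
setMethod("cdsSpans", "TranscriptModel", function(x) x@cds)
#' @rdname accessors
#' @export
setMethod("phases", "TranscriptModel", function(x) x@phases)

#' @rdname accessors
#' @export
setMethod("regionCounts", "ExpectationModel", function(x) x@regionCounts)
#' @rdname accessors
#' @export
setMethod("regionProportions", "ExpectationModel",
          function(x) x@regionProportions)
#' @rdname accessors
#' @export
setMethod("exonLengths", "ExpectationModel", function(x) x@exonLengths)
#' @rdname accessors
#' @export
setMethod("goParentProportions", "ExpectationModel",
          function(x) x@goParentProportions)

#' @rdname accessors
#' @export
setMethod("psiAssay", "PsiTable",
          function(x) SummarizedExperiment::assay(x, "psi"))
#' @rdname accessors
#' @export
setMethod("designTable", "PsiTable", function(x) {
    as.data.frame(SummarizedExperiment::colData(x))
})

#' Samples selected by one side of a comparison
#'
#' @param cmp a [Comparison]
#' @param design data.frame with rownames = sample ids and the design factors
#'   as columns
#' @param side `"A"` or `"B"`
#' @return character vector of sample ids
#' @export
comparisonSamples <- function(cmp, design, side = c("A", "B")) {
    side <- match.arg(side)
    g <- if (side == "A") cmp@groupA else cmp@groupB
    keep <- rep(TRUE, nrow(design))
    for (f in names(g)) {
        if (!f %in% colnames(design))
            stop("design has no factor '", f, "'")
        keep <- keep & design[[f]] %in% g[[f]]
    }
    rownames(design)[keep]
}
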