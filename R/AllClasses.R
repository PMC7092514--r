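#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics strand width start end
NULL

## Region vocabulary, ordered by the documented assignment tie-break
## (CDS beats FIVE_UTR beats THREE_UTR at equal overlap).
.REGIONS <- c("FIVE_UTR", "CDS", "THREE_UTR")
.REGION_PRIORITY <- c(CDS = 1L, FIVE_UTR = 2L, THREE_UTR = 3L)

## The eight event types the upstream splice-graph quantifier emits.
.EVENT_TYPES <- c("CE", "AA", "AD", "RI", "TE", "TS", "AF", "AL")

.TISSUES <- c("hypothalamus", "pituitary", "gonad")
.SEXES <- c("M", "F")
.TREATMENTS <- c("control", "stress")

#' Transcript model parsed from GFF3
#'
#' One mRNA with its exon and CDS structure. Exons and CDS spans are stored
#' 5'->3' in *transcript* orientation (descending genomic coordinates on the
#' minus strand); coordinates are 1-based inclusive as in GFF3. `phases` holds
#' the GFF3 phase (bases to skip to reach the first complete codon) of each
#' CDS span.
#'
#' @slot transcriptId,geneId,chrom single character identifiers
#' @slot strand `"+"` or `"-"`
#' @slot exons,cds [IRanges::IRanges] in transcript orientation
#' @slot phases integer vector, one phase in 0:2 per CDS span
#' @export
setClass("TranscriptModel", representation(
    transcriptId = "character",
    geneId = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cds = "IRanges",
    phases = "integer"
))

.cumlen_phases <- function(widths, phase1) {
    ## expected phase of span k+1 given phase of span 1 and widths 1..k
    if (length(widths) == 0L) return(integer(0))
    cum <- cumsum(widths)
    c(phase1, ((3L - ((cum[-length(cum)] - phase1) %% 3L)) %% 3L))
}

setValidity("TranscriptModel", function(object) {
    msg <- character(0)
    for (s in c("transcriptId", "geneId", "chrom", "strand"))
        if (length(slot(object, s)) != 1L)
            msg <- c(msg, sprintf("'%s' must be length 1", s))
    if (length(msg)) return(msg)
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex)) {
        st <- start(ex)
        ## transcript orientation: ascending starts on '+', descending on '-'
        ord <- if (object@strand == "+") all(diff(st) > 0) else all(diff(st) < 0)
        if (!ord)
            msg <- c(msg, "exons must be ordered 5'->3' in transcript orientation")
        gs <- sort(st)
        ge <- sort(end(ex))
        if (length(ex) > 1L && any(gs[-1L] <= ge[-length(ge)]))
            msg <- c(msg, "exons must be non-overlapping")
    }
    cds <- object@cds
    if (length(cds)) {
        if (length(object@phases) != length(cds))
            msg <- c(msg, "need one phase per CDS span")
        else {
            if (!all(object@phases %in% 0:2))
                msg <- c(msg, "phases must be in 0:2")
            expected <- .cumlen_phases(width(cds), object@phases[1L])
            if (!all(object@phases == expected))
                msg <- c(msg, sprintf(
                    "phases inconsistent with cumulative CDS length in '%s'",
                    object@transcriptId))
        }
        ## every CDS span contained in exactly one exon
        for (i in seq_along(cds)) {
            inside <- start(cds)[i] >= pmin(start(ex), end(ex)) &
                end(cds)[i] <= pmax(start(ex), end(ex))
            hit <- which(start(ex) <= start(cds)[i] & end(ex) >= end(cds)[i])
            if (length(hit) != 1L)
                msg <- c(msg, sprintf("CDS span %d of '%s' not contained in an exon",
                                      i, object@transcriptId))
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname TranscriptModel-class
#' @param transcriptId,geneId,chrom,strand,exons,cds,phases see slots
#' @export
TranscriptModel <- function(transcriptId, geneId, chrom, strand, exons,
                            cds = IRanges(), phases = integer(0)) {
    new("TranscriptModel", transcriptId = as.character(transcriptId),
        geneId = as.character(geneId), chrom = as.character(chrom),
        strand = as.character(strand), exons = exons, cds = cds,
        phases = as.integer(phases))
}

#' List of transcript models
#'
#' A [S4Vectors::SimpleList] whose elements are [TranscriptModel] objects,
#' named by transcript id.
#' @export
setClass("TranscriptModelList", contains = "SimpleList",
         prototype = prototype(elementType = "TranscriptModel"))

#' @rdname TranscriptModelList-class
#' @param ... `TranscriptModel` objects or a single list of them
#' @export
TranscriptModelList <- function(...) {
    args <- list(...)
    if (length(args) == 1L && is.list(args[[1]]) && !is(args[[1]], "TranscriptModel"))
        args <- args[[1]]
    names(args) <- vapply(args, function(m) m@transcriptId, character(1))
    new("TranscriptModelList", SimpleList(args))
}

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf("TranscriptModel '%s' (gene '%s') %s:%s exons=%d cds_spans=%d\n",
                object@transcriptId, object@geneId, object@chrom,
                object@strand, length(object@exons), length(object@cds)))
})

setMethod("show", "TranscriptModelList", function(object) {
    cat(sprintf("TranscriptModelList of %d transcript(s), %d gene(s)\n",
                length(object),
                length(unique(vapply(object, geneId, character(1))))))
})

#' Genome-derived expectation model
#'
#' Null proportions computed from the whole annotation: possible splicing
#' locations per transcript region, the genomic exon-length sample, and the
#' fraction of genome genes annotated to each GO parent term.
#'
#' @slot regionCounts named integer over `FIVE_UTR`, `CDS`, `THREE_UTR`
#' @slot regionProportions named numeric summing to 1
#' @slot exonLengths integer vector of annotated exon lengths (bp)
#' @slot goParentProportions named numeric in `[0,1]` (may be empty)
#' @export
setClass("ExpectationModel", representation(
    regionCounts = "integer",
    regionProportions = "numeric",
    exonLengths = "integer",
    goParentProportions = "numeric"
))

setValidity("ExpectationModel", function(object) {
    msg <- character(0)
    if (!identical(names(object@regionCounts), .REGIONS))
        msg <- c(msg, "regionCounts must be named FIVE_UTR, CDS, THREE_UTR")
    if (!identical(names(object@regionProportions), .REGIONS))
        msg <- c(msg, "regionProportions must be named FIVE_UTR, CDS, THREE_UTR")
    else if (abs(sum(object@regionProportions) - 1) > 1e-9)
        msg <- c(msg, "regionProportions must sum to 1")
    if (length(object@exonLengths) == 0L)
        msg <- c(msg, "exonLengths must be nonempty")
    else if (any(object@exonLengths <= 0L))
        msg <- c(msg, "exonLengths must be positive")
    p <- object@goParentProportions
    if (length(p) && (any(p < 0) || any(p > 1)))
        msg <- c(msg, "goParentProportions must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ExpectationModel", function(object) {
    cat("ExpectationModel\n  region proportions:",
        paste(sprintf("%s=%.3f", names(object@regionProportions),
                      object@regionProportions), collapse = " "),
        sprintf("\n  exon-length sample: n=%d (median %d bp)\n",
                length(object@exonLengths),
                as.integer(stats::median(object@exonLengths))),
        sprintf("  GO parent terms: %d\n", length(object@goParentProportions)))
})

#' Per-sample PSI measurements
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per splice-graph
#' node and one column per sample. Assays `psi` and `ciWidth` hold the
#' percent-spliced-in value and its confidence-interval width (both in
#' `[0,1]`, `NA` when the node was not quantifiable in a sample). Row data
#' carry `gene_id`, `node_id`, `chrom`, `start`, `end`, `strand` and
#' `event_type`; column data carry the design factors `sex`, `treatment`,
#' `tissue`.
#' @export
setClass("PsiTable", contains = "SummarizedExperiment")

setValidity("PsiTable", function(object) {
    msg <- character(0)
    if (!all(c("psi", "ciWidth") %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assays 'psi' and 'ciWidth' are required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sex", "treatment", "tissue") %in% colnames(cd)))
        msg <- c(msg, "colData must have sex, treatment and tissue")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("gene_id", "node_id", "chrom", "start", "end", "strand",
              "event_type")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste("rowData must have", paste(need, collapse = ", ")))
    else if (!all(rd$event_type %in% .EVENT_TYPES))
        msg <- c(msg, "event_type outside the 8-value vocabulary")
    if (!length(msg)) {
        p <- SummarizedExperiment::assay(object, "psi")
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msg <- c(msg, "psi values must lie in [0,1]")
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicated (gene, node) rows")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "PsiTable", function(object) {
    cat(sprintf("PsiTable: %d nodes x %d samples\n", nrow(object), ncol(object)))
    cd <- SummarizedExperiment::colData(object)
    cat("  design:", paste(sprintf(
        "%s(%s)", c("sex", "treatment", "tissue"),
        vapply(c("sex", "treatment", "tissue"),
               function(f) paste(unique(cd[[f]]), collapse = "/"), character(1))),
        collapse = " "), "\n")
})

#' Two-group comparison over the design
#'
#' `groupA`/`groupB` are named lists of design-factor values (e.g.
#' `list(sex = "M", treatment = "control", tissue = "hypothalamus")`); a sample
#' belongs to a group when all named factors match.
#' @slot label character, e.g. `"hypothalamus:MvF:control"`
#' @slot groupA,groupB named lists of design constraints
#' @export
setClass("Comparison", representation(
    label = "character", groupA = "list", groupB = "list"))

setValidity("Comparison", function(object) {
    msg <- character(0)
    if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
    if (!length(object@groupA) || !length(object@groupB))
        msg <- c(msg, "both groups need at least one design constraint")
    if (identical(object@groupA[order(names(object@groupA))],
                  object@groupB[order(names(object@groupB))]))
        msg <- c(msg, "groups must differ")
    if (length(msg)) msg else TRUE
})

#' @rdname Comparison-class
#' @param label,groupA,groupB see slots
#' @export
Comparison <- function(label, groupA, groupB) {
    new("Comparison", label = label, groupA = groupA, groupB = groupB)
}

setMethod("show", "Comparison", function(object) {
    fmt <- function(g) paste(sprintf("%s=%s", names(g), unlist(g)), collapse = ",")
    cat(sprintf("Comparison '%s': A{%s} vs B{%s}\n", object@label,
                fmt(object@groupA), fmt(object@groupB)))
})

#' Gene Ontology DAG restricted to hierarchy edges
#'
#' @slot terms character vector of term ids
#' @slot parents named list: term id -> character vector of parent ids
#' @slot namespace named character: term id -> namespace
#' @slot roots named character: namespace -> root term id
#' @slot names named character: term id -> human-readable name
#' @export
setClass("OntologyDag", representation(
    terms = "character", parents = "list", namespace = "character",
    roots = "character", names = "character"))

setValidity("OntologyDag", function(object) {
    msg <- character(0)
    if (!all(names(object@parents) %in% object@terms))
        msg <- c(msg, "parents keyed by unknown terms")
    if (!all(unlist(object@parents) %in% object@terms))
        msg <- c(msg, "parent edges point to unknown terms")
    ## acyclicity + root reachability by Kahn-style peeling
    if (!length(msg) && length(object@terms)) {
        remaining <- object@terms
        repeat {
            leaves <- remaining[vapply(remaining, function(t) {
                pa <- intersect(object@parents[[t]], remaining)
                length(pa) == 0L
            }, logical(1))]
            if (!length(leaves)) break
            remaining <- setdiff(remaining, leaves)
            if (!length(remaining)) break
        }
        if (length(remaining))
            msg <- c(msg, "ontology contains a cycle")
        nonroot <- setdiff(object@terms, object@roots)
        for (t in nonroot) {
            anc <- .dagAncestors(object, t)
            if (!any(object@roots %in% anc)) {
                msg <- c(msg, sprintf("term '%s' cannot reach a namespace root", t))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "OntologyDag", function(object) {
    cat(sprintf("OntologyDag: %d terms, %d namespaces (%s)\n",
                length(object@terms), length(object@roots),
                paste(names(object@roots), collapse = ", ")))
})

#' Synthetic-study configuration
#'
#' Defaults encode the emulated study design: three HPG tissues, two sexes,
#' two treatments, 12 replicates per cell (144 samples), an event-type mixture
#' dominated by core-exon events, Beta-distributed PSI noise, and a
#' convergence factor that halves the number of male-vs-female effect nodes
#' in the stress stratum.
#'
#' @slot seed integer master seed
#' @slot nGenes number of genes in the toy genome
#' @slot exonsPerGene integer range (min, max), mean ~8 exons per gene
#' @slot nPerCell replicates per sex x treatment x tissue cell
#' @slot eventTypeMix named probabilities over the 8 event types
#' @slot effectNodes fraction of nodes carrying a true effect
#' @slot effectRange absolute delta-PSI range effects are drawn from
#' @slot psiConcentration Beta concentration of replicate PSI noise
#' @slot convergenceFactor fraction of sex-effect nodes still active under
#'   stress (< 1 shrinks male-female differences in the stress stratum)
#' @slot nIsoformsPerGene,nExclusiveIsoforms TPM-table structure
#' @export
setClass("SimConfig", representation(
    seed = "integer", nGenes = "integer", exonsPerGene = "integer",
    nPerCell = "integer", eventTypeMix = "numeric", effectNodes = "numeric",
    effectRange = "numeric", psiConcentration = "numeric",
    convergenceFactor = "numeric", nIsoformsPerGene = "integer",
    nExclusiveIsoforms = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    if (object@nPerCell < 2L) msg <- c(msg, "nPerCell must be >= 2")
    if (!identical(names(object@eventTypeMix), .EVENT_TYPES))
        msg <- c(msg, "eventTypeMix must be named by the 8 event types")
    else if (abs(sum(object@eventTypeMix) - 1) > 1e-9)
        msg <- c(msg, "eventTypeMix must sum to 1")
    if (object@effectNodes < 0 || object@effectNodes > 1)
        msg <- c(msg, "effectNodes must be a fraction")
    if (any(object@effectRange < 0) || any(object@effectRange > 1) ||
        length(object@effectRange) != 2L || diff(object@effectRange) < 0)
        msg <- c(msg, "effectRange must be an increasing pair within [0,1]")
    if (object@effectRange[1] < 0.1)
        msg <- c(msg, "true effects must satisfy |dPSI| >= 0.1")
    if (object@convergenceFactor < 0 || object@convergenceFactor > 1)
        msg <- c(msg, "convergenceFactor must be in [0,1]")
    if (length(object@exonsPerGene) != 2L || any(object@exonsPerGene < 1L))
        msg <- c(msg, "exonsPerGene must be a positive (min, max) pair")
    if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param seed,nGenes,exonsPerGene,nPerCell,eventTypeMix,effectNodes
#'   see slots
#' @param effectRange,psiConcentration,convergenceFactor see slots
#' @param nIsoformsPerGene,nExclusiveIsoforms see slots
#' @export
SimConfig <- function(seed = 1L, nGenes = 60L, exonsPerGene = c(5L, 11L),
                      nPerCell = 12L,
                      eventTypeMix = c(CE = 0.55, AA = 0.10, AD = 0.10,
                                       RI = 0.10, TE = 0.05, TS = 0.04,
                                       AF = 0.03, AL = 0.03),
                      effectNodes = 0.08, effectRange = c(0.15, 0.5),
                      psiConcentration = 24, convergenceFactor = 0.5,
                      nIsoformsPerGene = 2L, nExclusiveIsoforms = 0L) {
    new("SimConfig", seed = as.integer(seed), nGenes = as.integer(nGenes),
        exonsPerGene = as.integer(exonsPerGene), nPerCell = as.integer(nPerCell),
        eventTypeMix = eventTypeMix, effectNodes = effectNodes,
        effectRange = effectRange, psiConcentration = psiConcentration,
        convergenceFactor = convergenceFactor,
        nIsoformsPerGene = as.integer(nIsoformsPerGene),
        nExclusiveIsoforms = as.integer(nExclusiveIsoforms))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: seed=%d, %d genes, %d-%d exons/gene, n=%d per cell,\n",
        "  effect nodes %.0f%% with |dPSI| in [%.2f, %.2f], Beta concentration %g,\n",
        "  convergence factor %.2f\n"),
        object@seed, object@nGenes, object@exonsPerGene[1],
        object@exonsPerGene[2], object@nPerCell, 100 * object@effectNodes,
        object@effectRange[1], object@effectRange[2],
        object@psiConcentration, object@convergenceFactor))
})
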