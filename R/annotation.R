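#' Parse a GFF3 annotation into transcript models
#'
#' Reads gene/mRNA/exon/CDS features (grouped through their `ID`/`Parent`
#' attributes) and returns one [TranscriptModel] per mRNA. Coordinates stay
#' 1-based inclusive; strand and CDS phase are retained. Parsing itself is
#' delegated to [rtracklayer::import()]; a pre-scan reports malformed lines
#' (wrong column count) with their line number, and referential checks catch
#' dangling `Parent` attributes and missing CDS phases.
#'
#' @param path path to a GFF3 file
#' @return a [TranscriptModelList]
#' @export
parseGFF3 <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    ## stop the scan at an embedded FASTA section, if any
    fasta_at <- which(lines == "##FASTA")
    scan_to <- if (length(fasta_at)) fasta_at[1L] - 1L else length(lines)
    body <- seq_len(scan_to)
    feature <- body[!startsWith(lines[body], "#") & nzchar(lines[body])]
    nfield <- lengths(strsplit(lines[feature], "\t", fixed = TRUE))
    if (any(nfield != 9L)) {
        bad <- feature[nfield != 9L][1L]
        stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                     bad, nfield[match(bad, feature)]))
    }
    if (!length(feature)) {
        warning("GFF3 file '", path, "' contains no features")
        return(TranscriptModelList(list()))
    }
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    ids <- if ("ID" %in% colnames(md)) as.character(md$ID) else
        rep(NA_character_, length(gr))
    parents <- if ("Parent" %in% colnames(md))
        as.list(md$Parent) else rep(list(character(0)), length(gr))

    is_mrna <- type %in% c("mRNA", "transcript")
    mrna_ids <- ids[is_mrna]
    if (anyDuplicated(stats::na.omit(mrna_ids)))
        stop("duplicated mRNA ID in ", path)
    ## gene id of each mRNA: its Parent when present, else its own ID
    mrna_gene <- vapply(which(is_mrna), function(i) {
        pa <- parents[[i]]
        if (length(pa)) pa[1L] else ids[i]
    }, character(1))
    names(mrna_gene) <- mrna_ids

    child <- type %in% c("exon", "CDS")
    for (i in which(child)) {
        pa <- parents[[i]]
        if (!length(pa))
            stop(type[i], " feature without Parent attribute in ", path)
        missing <- setdiff(pa, mrna_ids)
        if (length(missing))
            stop(sprintf("%s feature refers to absent Parent '%s'",
                         type[i], missing[1L]))
    }

    models <- lapply(seq_along(mrna_ids), function(k) {
        tx <- mrna_ids[k]
        sel <- which(child & vapply(parents, function(p) tx %in% p, logical(1)))
        ex <- sel[type[sel] == "exon"]
        cd <- sel[type[sel] == "CDS"]
        str <- as.character(BiocGenerics::strand(gr[which(is_mrna)[k]]))
        if (!str %in% c("+", "-"))
            stop("mRNA '", tx, "' lacks a +/- strand")
        ord <- function(idx) idx[order(BiocGenerics::start(gr[idx]),
                                       decreasing = (str == "-"))]
        ex <- ord(ex); cd <- ord(cd)
        ph <- md$phase[cd]
        if (length(cd) && any(is.na(ph)))
            stop("CDS of transcript '", tx, "' is missing a phase")
        m <- try(TranscriptModel(
            transcriptId = tx, geneId = unname(mrna_gene[tx]),
            chrom = as.character(GenomicRanges::seqnames(gr[which(is_mrna)[k]])),
            strand = str,
            exons = IRanges(BiocGenerics::start(gr[ex]), BiocGenerics::end(gr[ex])),
            cds = IRanges(BiocGenerics::start(gr[cd]), BiocGenerics::end(gr[cd])),
            phases = as.integer(ph)), silent = TRUE)
        if (inherits(m, "try-error"))
            stop("invalid transcript '", tx, "': ", attr(m, "condition")$message)
        m
    })
    TranscriptModelList(models)
}

#' Write transcript models as GTF2.2
#'
#' Emits `exon` and `CDS` rows (plus optional `gene`/`transcript` rows) with
#' quoted `gene_id`/`transcript_id` attributes, 1-based inclusive coordinates,
#' and the GFF3 phase copied into the frame column. Features are written in
#' ascending genomic order within each transcript.
#'
#' @param models a [TranscriptModelList]
#' @param path output path
#' @param includeParents also emit `gene` and `transcript` rows
#' @return number of feature rows written, invisibly
#' @export
gffToGtf <- function(models, path, includeParents = FALSE) {
    con <- try(file(path, open = "wt"), silent = TRUE)
    if (inherits(con, "try-error"))
        stop("cannot open '", path, "' for writing")
    on.exit(close(con))
    n <- 0L
    fmt <- function(chrom, feature, s, e, strand, frame, gene, tx)
        sprintf("%s\tspliceScape\t%s\t%d\t%d\t.\t%s\t%s\tgene_id \"%s\"; transcript_id \"%s\";",
                chrom, feature, s, e, strand, frame, gene, tx)
    for (m in as.list(models)) {
        ex <- m@exons; cd <- m@cds
        gs <- min(start(ex)); ge <- max(end(ex))
        rows <- character(0)
        if (includeParents)
            rows <- c(fmt(m@chrom, "gene", gs, ge, m@strand, ".",
                          m@geneId, m@transcriptId),
                      fmt(m@chrom, "transcript", gs, ge, m@strand, ".",
                          m@geneId, m@transcriptId))
        eo <- order(start(ex))
        rows <- c(rows, fmt(m@chrom, "exon", start(ex)[eo], end(ex)[eo],
                            m@strand, ".", m@geneId, m@transcriptId))
        if (length(cd)) {
            co <- order(start(cd))
            rows <- c(rows, fmt(m@chrom, "CDS", start(cd)[co], end(cd)[co],
                                m@strand, as.character(m@phases[co]),
                                m@geneId, m@transcriptId))
        }
        writeLines(rows, con)
        n <- n + length(rows)
    }
    invisible(n)
}

## Map a genomic position to its 1-based transcript coordinate.
.txCoord <- function(model, gpos) {
    ex <- model@exons
    w <- width(ex)
    prefix <- c(0L, cumsum(w))[seq_along(ex)]
    for (i in seq_along(ex)) {
        if (gpos >= start(ex)[i] && gpos <= end(ex)[i]) {
            off <- if (model@strand == "+") gpos - start(ex)[i]
                   else end(ex)[i] - gpos
            return(prefix[i] + off + 1L)
        }
    }
    stop("position ", gpos, " is not exonic in '", model@transcriptId, "'")
}

#' Split each exon of a coding transcript into transcript regions
#'
#' Every exonic base is assigned exactly one region in transcript
#' orientation: bases 5' of the first CDS base are `FIVE_UTR`, bases within
#' the CDS are `CDS`, bases 3' of the last CDS base are `THREE_UTR`.
#' Minus-strand transcripts are classified in transcript orientation, so
#' `FIVE_UTR` can lie at higher genomic coordinates.
#'
#' @param model a [TranscriptModel]
#' @return data.frame with one row per (exon, region) sub-interval, columns
#'   `exon` (transcript-order index), `chrom`, `start`, `end` (genomic,
#'   1-based inclusive), `width`, `region`, `strand`. For a non-coding
#'   transcript a zero-row frame with attribute `unclassified = TRUE` is
#'   returned and a message logged; such transcripts are excluded from region
#'   statistics.
#' @export
deriveRegions <- function(model) {
    empty <- data.frame(exon = integer(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        width = integer(0), region = character(0),
                        strand = character(0))
    if (!length(model@cds)) {
        message("transcript '", model@transcriptId,
                "' is non-coding: regions unclassified")
        attr(empty, "unclassified") <- TRUE
        return(empty)
    }
    cds <- model@cds
    cds5 <- if (model@strand == "+") min(start(cds)) else max(end(cds))
    cds3 <- if (model@strand == "+") max(end(cds)) else min(start(cds))
    tA <- .txCoord(model, cds5)
    tB <- .txCoord(model, cds3)
    ex <- model@exons
    w <- width(ex)
    prefix <- c(0L, cumsum(w))
    out <- vector("list", length(ex))
    for (i in seq_along(ex)) {
        a <- prefix[i] + 1L; b <- prefix[i + 1L]
        pieces <- list()
        if (a < tA) pieces <- c(pieces, list(c(a, min(b, tA - 1L), 1L)))
        if (b >= tA && a <= tB)
            pieces <- c(pieces, list(c(max(a, tA), min(b, tB), 2L)))
        if (b > tB) pieces <- c(pieces, list(c(max(a, tB + 1L), b, 3L)))
        rows <- lapply(pieces, function(p) {
            ## back to genomic coordinates
            if (model@strand == "+") {
                gs <- start(ex)[i] + (p[1] - a); geom <- start(ex)[i] + (p[2] - a)
                data.frame(exon = i, chrom = model@chrom, start = gs,
                           end = geom, width = p[2] - p[1] + 1L,
                           region = .REGIONS[p[3]], strand = model@strand)
            } else {
                gs <- end(ex)[i] - (p[2] - a); geom <- end(ex)[i] - (p[1] - a)
                data.frame(exon = i, chrom = model@chrom, start = gs,
                           end = geom, width = p[2] - p[1] + 1L,
                           region = .REGIONS[p[3]], strand = model@strand)
            }
        })
        out[[i]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
}

#' Region segments for a whole annotation
#'
#' Applies [deriveRegions()] to every coding transcript and binds the results,
#' adding `transcript_id` and `gene_id` columns. Non-coding transcripts are
#' skipped (logged by [deriveRegions()]).
#'
#' @param models a [TranscriptModelList]
#' @return data.frame of region segments
#' @export
regionSegments <- function(models) {
    segs <- lapply(models, function(m) {
        d <- suppressMessages(deriveRegions(m))
        if (isTRUE(attr(d, "unclassified")) || nrow(d) == 0L) return(NULL)
        d$transcript_id <- m@transcriptId
        d$gene_id <- m@geneId
        d
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (!length(segs))
        return(data.frame(exon = integer(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          width = integer(0), region = character(0),
                          strand = character(0),
                          transcript_id = character(0), gene_id = character(0)))
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out
}

#' Build the genomic expectation model
#'
#' Computes the null quantities every genome-wide comparison uses: the number
#' of possible splicing locations per transcript region (counted as exonic
#' segments after region splitting, so an exon spanning a region boundary
#' contributes one location to each region it touches), the genomic
#' exon-length sample (all annotated exons, coding or not), and the fraction
#' of genome genes annotated to each GO parent term.
#'
#' @param models a [TranscriptModelList]
#' @param goAssoc optional data.frame with columns `gene_id`, `term`
#' @param ontology optional [OntologyDag] used to abstract terms to parents
#' @param isoformPolicy count locations over all mRNAs (`"all"`, default) or
#'   only each gene's longest isoform (`"longest"`)
#' @param parentDepth depth below the namespace root that defines a "parent"
#'   term (default 1)
#' @return an [ExpectationModel]
#' @export
buildExpectationModel <- function(models, goAssoc = NULL, ontology = NULL,
                                  isoformPolicy = c("all", "longest"),
                                  parentDepth = 1L) {
    isoformPolicy <- match.arg(isoformPolicy)
    stopifnot(length(models) > 0L)
    if (isoformPolicy == "longest") {
        genes <- vapply(models, geneId, character(1))
        len <- vapply(models, function(m) sum(width(m@exons)), numeric(1))
        keep <- unlist(lapply(split(seq_along(models), genes),
                              function(i) i[which.max(len[i])]))
        models <- TranscriptModelList(as.list(models)[sort(keep)])
    }
    segs <- regionSegments(models)
    if (!nrow(segs)) stop("no coding transcript in annotation")
    counts <- vapply(.REGIONS, function(r) sum(segs$region == r), integer(1))
    lens <- unlist(lapply(models, function(m) width(m@exons)), use.names = FALSE)

    gop <- numeric(0)
    universe <- unique(vapply(models, geneId, character(1)))
    if (is.null(goAssoc) || is.null(ontology) || nrow(goAssoc) == 0L) {
        if (!is.null(goAssoc) && nrow(goAssoc) == 0L)
            warning("empty GO association: no parent proportions computed")
    } else {
        parentsByGene <- genesToParents(goAssoc, ontology, depth = parentDepth)
        parentsByGene <- parentsByGene[names(parentsByGene) %in% universe]
        tab <- table(unlist(parentsByGene, use.names = FALSE))
        gop <- as.numeric(tab) / length(universe)
        names(gop) <- names(tab)
    }
    new("ExpectationModel",
        regionCounts = counts,
        regionProportions = counts / sum(counts),
        exonLengths = as.integer(lens),
        goParentProportions = gop)
}
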