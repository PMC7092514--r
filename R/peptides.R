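.loadGenome <- function(genome) {
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    genome
}

#' Extract a genomic interval, strand-aware
#'
#' Plus strand returns the chromosome substring; minus strand returns its
#' reverse complement.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file
#' @param chrom chromosome name
#' @param start,end 1-based inclusive coordinates
#' @param strand `"+"` or `"-"`
#' @return nucleotide string
#' @export
extractExon <- function(genome, chrom, start, end, strand = "+") {
    genome <- .loadGenome(genome)
    if (!chrom %in% names(genome))
        stop("chromosome '", chrom, "' not in genome")
    len <- length(genome[[chrom]])
    if (start < 1L || end > len || start > end)
        stop(sprintf("interval %d-%d out of bounds for '%s' (length %d)",
                     start, end, chrom, len))
    s <- Biostrings::subseq(genome[[chrom]], start, end)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
}

#' Translate an exon sequence with GFF3 phase semantics
#'
#' Drops the first `phase` bases (the GFF3 phase is the number of bases to
#' skip to reach the first complete codon), translates successive codons with
#' the standard genetic code, renders stop codons as `"*"`, drops a trailing
#' partial codon, and translates any codon containing `N` as `"X"`.
#'
#' @param nt nucleotide string over `A`, `C`, `G`, `T`, `N`
#' @param phase 0, 1 or 2
#' @return amino-acid string (possibly empty)
#' @export
translateExon <- function(nt, phase = 0L) {
    stopifnot(length(nt) == 1L, phase %in% 0:2)
    if (grepl("[^ACGTN]", nt)) stop("sequence must be over A, C, G, T, N")
    s <- substr(nt, phase + 1L, nchar(nt))
    keep <- 3L * (nchar(s) %/% 3L)
    if (keep == 0L) return("")
    s <- substr(s, 1L, keep)
    ## no.init.codon: exon fragments are not initiators, so alternative
    ## start codons must not be forced to M
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
}

## Phase (bases to skip) at an offset o into a CDS span with phase p,
## in transcript orientation.
.phaseAtOffset <- function(p, o) ((p - o) %% 3L + 3L) %% 3L

#' Extract and translate alternatively spliced exons
#'
#' For each event, finds the region segment of its gene with maximal overlap,
#' extracts the overlapping genomic sequence strand-aware, and — for
#' CDS-region events — translates it using the reading-frame phase derived
#' from the annotated CDS phase at the extracted position. UTR-region events
#' get an empty peptide. By default only the CDS-overlapping portion of a
#' boundary-spanning exon is translated (`mode = "cds"`); `mode = "whole"`
#' extracts the whole node interval instead.
#'
#' @param events data.frame of events (typically significant calls)
#' @param models a [TranscriptModelList]
#' @param genome a [Biostrings::DNAStringSet] or FASTA path
#' @param mode `"cds"` (default) or `"whole"`
#' @return data.frame: event key, `gene_id`, `node_id`, `region`, `strand`,
#'   `phase`, `nt`, `length`, `peptide`
#' @export
exonPeptides <- function(events, models, genome, mode = c("cds", "whole")) {
    mode <- match.arg(mode)
    genome <- .loadGenome(genome)
    segments <- regionSegments(models)
    events <- regionAssign(events, segments)
    byTx <- stats::setNames(seq_along(models),
                            vapply(models, transcriptId, character(1)))
    out <- vector("list", nrow(events))
    for (i in seq_len(nrow(events))) {
        ev <- events[i, ]
        key <- sprintf("%s:%s", ev$gene_id, ev$node_id)
        if (is.na(ev$region)) next
        seg <- segments[segments$gene_id == ev$gene_id &
                        segments$chrom == ev$chrom, , drop = FALSE]
        ov <- pmax(0L, pmin(seg$end, ev$end) - pmax(seg$start, ev$start) + 1L)
        if (mode == "cds") {
            cand <- seg[ov > 0 & seg$region == ev$region, , drop = FALSE]
            ovc <- ov[ov > 0 & seg$region == ev$region]
            best <- cand[which.max(ovc), ]
            ps <- max(best$start, ev$start); pe <- min(best$end, ev$end)
        } else {
            best <- seg[which.max(ov), ]
            ps <- ev$start; pe <- ev$end
        }
        nt <- extractExon(genome, ev$chrom, ps, pe, ev$strand)
        phase <- 0L
        pep <- ""
        if (ev$region == "CDS") {
            model <- models[[byTx[[best$transcript_id]]]]
            cds <- cdsSpans(model)
            span <- which(start(cds) <= ps & end(cds) >= pe)
            if (length(span)) {
                span <- span[1L]
                o <- if (ev$strand == "+") ps - start(cds)[span]
                     else end(cds)[span] - pe
                phase <- .phaseAtOffset(phases(model)[span], o)
                pep <- translateExon(nt, phase)
            }
        }
        out[[i]] <- data.frame(
            key = key, gene_id = ev$gene_id, node_id = ev$node_id,
            region = ev$region, strand = ev$strand, phase = phase,
            nt = nt, length = nchar(nt), peptide = pep)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
        return(data.frame(key = character(0), gene_id = character(0),
                          node_id = integer(0), region = character(0),
                          strand = character(0), phase = integer(0),
                          nt = character(0), length = integer(0),
                          peptide = character(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Write translated exon peptides as FASTA
#'
#' Headers are event-keyed: `>gene:node|region|strand|phase`. Entries with an
#' empty peptide (UTR exons) are skipped.
#'
#' @param peptides data.frame from [exonPeptides()]
#' @param path output path
#' @return number of records written, invisibly
#' @export
writePeptideFasta <- function(peptides, path) {
    keep <- nzchar(peptides$peptide)
    p <- peptides[keep, , drop = FALSE]
    aa <- Biostrings::AAStringSet(p$peptide)
    names(aa) <- sprintf("%s|%s|%s|%d", p$key, p$region, p$strand, p$phase)
    Biostrings::writeXStringSet(aa, path)
    invisible(sum(keep))
}

#' Scan peptides for motifs through a pluggable adapter
#'
#' The external search the full analysis would use (PFAM/COG/SMART/TIGRFAM)
#' is not bundled; this defines the adapter contract and ships a toy regex
#' scanner. A scanner is a `function(peptide)` returning a data.frame
#' `motif`, `start`, `end`, `score`. A failing scanner call is recorded per
#' peptide (attribute `errors`) and the scan continues.
#'
#' @param peptides data.frame from [exonPeptides()] or a named character
#'   vector of peptide sequences
#' @param motifs named character vector of regular expressions for the
#'   bundled toy scanner (ignored when `scanner` is given)
#' @param scanner optional adapter function
#' @return data.frame `key`, `motif`, `start`, `end`, `score` with attribute
#'   `errors` (named character vector, possibly empty)
#' @export
motifScan <- function(peptides, motifs = NULL, scanner = NULL) {
    if (is.data.frame(peptides)) {
        seqs <- stats::setNames(peptides$peptide, peptides$key)
    } else seqs <- peptides
    if (!length(seqs)) stop("no peptides to scan")
    if (is.null(scanner)) {
        if (is.null(motifs) || is.null(names(motifs)))
            stop("bundled scanner needs a named 'motifs' vector of regexes")
        scanner <- function(peptide) {
            hits <- lapply(names(motifs), function(m) {
                g <- gregexpr(motifs[[m]], peptide)[[1L]]
                if (g[1L] == -1L) return(NULL)
                data.frame(motif = m, start = as.integer(g),
                           end = as.integer(g) + attr(g, "match.length") - 1L,
                           score = 1)
            })
            hits <- hits[!vapply(hits, is.null, logical(1))]
            if (!length(hits))
                return(data.frame(motif = character(0), start = integer(0),
                                  end = integer(0), score = numeric(0)))
            do.call(rbind, hits)
        }
    }
    errors <- character(0)
    rows <- list()
    for (k in names(seqs)) {
        h <- tryCatch(scanner(seqs[[k]]), error = function(e) e)
        if (inherits(h, "error")) {
            errors[k] <- conditionMessage(h)
            next
        }
        if (nrow(h)) rows[[k]] <- cbind(key = k, h)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(key = character(0), motif = character(0),
                   start = integer(0), end = integer(0), score = numeric(0))
    rownames(out) <- NULL
    attr(out, "errors") <- errors
    out
}
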