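test_that("parseGFF3 reads a toy annotation back verbatim", {
    models <- parseGFF3(writeToyGff3())
    expect_length(models, 1L)
    m <- models[["txP"]]
    expect_identical(geneId(m), "gP")
    expect_identical(BiocGenerics::start(exons(m)), c(1L, 201L, 401L))
    expect_identical(BiocGenerics::end(exons(m)), c(100L, 300L, 500L))
    expect_length(cdsSpans(m), 2L)
    expect_identical(phases(m), c(0L, 1L))
    expect_identical(strand(m), "+")
})

test_that("parseGFF3 rejects malformed and dangling input", {
    empty <- tempfile(fileext = ".gff3")
    writeLines("##gff-version 3", empty)
    expect_warning(models <- parseGFF3(empty), "no features")
    expect_length(models, 0L)

    bad <- tempfile(fileext = ".gff3")
    writeLines(c("chrT\ttoy\tgene\t1\t500", "x"), bad)
    expect_error(parseGFF3(bad), "line 1")

    dangling <- tempfile(fileext = ".gff3")
    writeLines(c(
        "chrT\ttoy\tmRNA\t1\t500\t.\t+\t.\tID=tx1",
        "chrT\ttoy\texon\t1\t500\t.\t+\t.\tID=e;Parent=tx1",
        "chrT\ttoy\tCDS\t1\t90\t.\t+\t0\tID=c;Parent=ghost"), dangling)
    expect_error(parseGFF3(dangling), "ghost")

    nophase <- tempfile(fileext = ".gff3")
    writeLines(c(
        "chrT\ttoy\tmRNA\t1\t500\t.\t+\t.\tID=tx1",
        "chrT\ttoy\texon\t1\t500\t.\t+\t.\tID=e;Parent=tx1",
        "chrT\ttoy\tCDS\t1\t90\t.\t+\t.\tID=c;Parent=tx1"), nophase)
    expect_error(parseGFF3(nophase), "phase")

    outside <- tempfile(fileext = ".gff3")
    writeLines(c(
        "chrT\ttoy\tmRNA\t1\t500\t.\t+\t.\tID=tx1",
        "chrT\ttoy\texon\t1\t100\t.\t+\t.\tID=e;Parent=tx1",
        "chrT\ttoy\tCDS\t50\t150\t.\t+\t0\tID=c;Parent=tx1"), outside)
    expect_error(parseGFF3(outside), "tx1")
})

test_that("TranscriptModel validity enforces the phase recurrence", {
    expect_error(
        TranscriptModel("t", "g", "c", "+",
                        exons = IRanges::IRanges(1, 300),
                        cds = IRanges::IRanges(c(1, 201), c(100, 300)),
                        phases = c(0L, 0L)),
        "phases inconsistent")
    ## width 100 with phase 0 consumed -> next phase (3 - 100 %% 3) %% 3 = 2
    m <- TranscriptModel("t", "g", "c", "+",
                         exons = IRanges::IRanges(c(1, 201), c(100, 300)),
                         cds = IRanges::IRanges(c(1, 201), c(100, 300)),
                         phases = c(0L, 2L))
    expect_s4_class(m, "TranscriptModel")
})

test_that("gffToGtf emits the expected rows and round-trips coordinates", {
    models <- parseGFF3(writeToyGff3())
    out <- tempfile(fileext = ".gtf")
    n <- gffToGtf(models, out)
    expect_identical(n, 5L)  # 3 exons + 2 CDS
    gr <- rtracklayer::import(out, format = "gtf")
    ex <- gr[gr$type == "exon"]
    expect_identical(sort(BiocGenerics::start(ex)), c(1L, 201L, 401L))
    expect_identical(sort(BiocGenerics::end(ex)), c(100L, 300L, 500L))
    expect_identical(unique(as.character(ex$gene_id)), "gP")
    cds <- gr[gr$type == "CDS"]
    expect_identical(sort(as.integer(as.character(cds$phase))), c(0L, 1L))

    ## non-coding model: exon rows only
    nc <- TranscriptModelList(list(TranscriptModel(
        "txN", "gN", "chrT", "+", exons = IRanges::IRanges(1, 90))))
    expect_identical(gffToGtf(nc, out), 1L)
})

test_that("gffToGtf preserves a simulated annotation under round trip", {
    b <- smallBundle()
    out <- tempfile(fileext = ".gtf")
    gffToGtf(b$models, out)
    gr <- rtracklayer::import(out, format = "gtf")
    for (m in as.list(b$models)[c(1, 2, 7)]) {
        ex <- gr[gr$type == "exon" & gr$transcript_id == transcriptId(m)]
        expect_setequal(BiocGenerics::start(ex),
                        BiocGenerics::start(exons(m)))
        expect_setequal(BiocGenerics::end(ex), BiocGenerics::end(exons(m)))
        expect_identical(unique(as.character(BiocGenerics::strand(ex))),
                         strand(m))
    }
})

test_that("deriveRegions splits exons at CDS boundaries, plus strand", {
    d <- deriveRegions(plusModel())
    expect_identical(
        d[, c("start", "end", "region")],
        data.frame(start = c(1L, 51L, 201L, 401L, 451L),
                   end = c(50L, 100L, 300L, 450L, 500L),
                   region = c("FIVE_UTR", "CDS", "CDS", "CDS", "THREE_UTR")))
    expect_identical(sum(d$width), 300L)
})

test_that("minus-strand regions mirror the plus strand in transcript orientation", {
    d <- deriveRegions(minusModel())
    ## same region sequence along the transcript ...
    expect_identical(d$region,
                     c("FIVE_UTR", "CDS", "CDS", "CDS", "THREE_UTR"))
    ## ... with FIVE_UTR at the genomically-highest coordinates
    expect_identical(d$start[1], 551L)
    expect_identical(d$end[1], 600L)
    expect_identical(d$region[d$start == 101], "THREE_UTR")
    ## reflection maps the plus-strand split exactly
    p <- deriveRegions(plusModel())
    expect_identical(601L - d$end, p$start)
    expect_identical(601L - d$start, p$end)
})

test_that("single-exon transcript with CDS covering the exon is all CDS", {
    m <- TranscriptModel("t1", "g1", "c", "+",
                         exons = IRanges::IRanges(11, 100),
                         cds = IRanges::IRanges(11, 100), phases = 0L)
    d <- deriveRegions(m)
    expect_identical(nrow(d), 1L)
    expect_identical(d$region, "CDS")
    expect_identical(d$width, 90L)
})

test_that("non-coding transcripts are flagged unclassified", {
    m <- TranscriptModel("t1", "g1", "c", "+",
                         exons = IRanges::IRanges(11, 100))
    expect_message(d <- deriveRegions(m), "non-coding")
    expect_identical(nrow(d), 0L)
    expect_true(attr(d, "unclassified"))
})

test_that("derived regions partition exonic bases for every coding transcript", {
    b <- smallBundle()
    for (m in as.list(b$models)) {
        d <- deriveRegions(m)
        expect_identical(sum(d$width),
                         sum(BiocGenerics::width(exons(m))))
        ## within each exon the sub-intervals tile the exon
        for (i in unique(d$exon)) {
            sub <- d[d$exon == i, ]
            expect_identical(sum(sub$width),
                             BiocGenerics::width(exons(m))[i])
        }
    }
})

test_that("expectation model counts exonic segments per region", {
    ## two identical three-exon transcripts: 2 FIVE_UTR + 6 CDS + 2 THREE_UTR
    ## segments in total, so proportions 0.2 / 0.6 / 0.2
    models <- TranscriptModelList(list(
        plusModel(),
        TranscriptModel("txP2", "gP2", "chr2", "+",
                        exons = IRanges::IRanges(c(1, 201, 401), c(100, 300, 500)),
                        cds = IRanges::IRanges(c(51, 201, 401), c(100, 300, 450)),
                        phases = c(0L, 1L, 0L))))
    em <- buildExpectationModel(models)
    expect_identical(unname(regionCounts(em)), c(2L, 6L, 2L))
    expect_equal(unname(regionProportions(em)), c(0.2, 0.6, 0.2))
    expect_equal(sum(regionProportions(em)), 1)
    ## duplication leaves proportions at the single-transcript values
    em1 <- buildExpectationModel(TranscriptModelList(list(plusModel())))
    expect_equal(regionProportions(em1), regionProportions(em))
    ## and the exon-length sample covers all annotated exons
    expect_identical(sort(exonLengths(em1)), c(100L, 100L, 100L))
})

test_that("region location counts match independent manual enumeration", {
    ## Oracle: classify every exonic base of every coding transcript by
    ## comparing its transcript coordinate against the CDS extremes, then
    ## count distinct (transcript, exon, region) combinations.
    b <- smallBundle()
    oracle <- c(FIVE_UTR = 0L, CDS = 0L, THREE_UTR = 0L)
    lens <- integer(0)
    for (m in as.list(b$models)) {
        ex <- exons(m)
        lens <- c(lens, BiocGenerics::width(ex))
        cds <- cdsSpans(m)
        ## genomic positions of every exonic base, in transcript order
        pos <- unlist(lapply(seq_along(ex), function(i) {
            p <- BiocGenerics::start(ex)[i]:BiocGenerics::end(ex)[i]
            if (strand(m) == "-") rev(p) else p
        }))
        exonOf <- rep(seq_along(ex), BiocGenerics::width(ex))
        cdsBases <- unlist(lapply(seq_along(cds), function(i)
            BiocGenerics::start(cds)[i]:BiocGenerics::end(cds)[i]))
        txIdx <- seq_along(pos)
        cdsTx <- range(txIdx[pos %in% cdsBases])
        region <- ifelse(txIdx < cdsTx[1], "FIVE_UTR",
                         ifelse(txIdx > cdsTx[2], "THREE_UTR", "CDS"))
        seen <- unique(paste(exonOf, region))
        for (r in c("FIVE_UTR", "CDS", "THREE_UTR"))
            oracle[r] <- oracle[r] + sum(endsWith(seen, r))
    }
    em <- buildExpectationModel(b$models)
    expect_identical(regionCounts(em), oracle)
    expect_identical(sort(exonLengths(em)), sort(lens))
    ## every coding transcript contributes at least one CDS location
    expect_gte(regionCounts(em)[["CDS"]], length(b$models))
})

test_that("longest-isoform policy keeps one transcript per gene", {
    short <- TranscriptModel("txS", "gP", "chrT", "+",
                             exons = IRanges::IRanges(1, 90),
                             cds = IRanges::IRanges(1, 90), phases = 0L)
    models <- TranscriptModelList(list(plusModel(), short))
    emAll <- buildExpectationModel(models)
    emLong <- buildExpectationModel(models, isoformPolicy = "longest")
    expect_identical(sum(regionCounts(emAll)), 6L)   # 5 + 1 segments
    expect_identical(sum(regionCounts(emLong)), 5L)  # longest isoform only
})
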