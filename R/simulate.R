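.BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")
.TISSUE_CODE <- c(hypothalamus = "hyp", pituitary = "pit", gonad = "gon")

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.randOrf <- function(len) {
    stopifnot(len %% 3 == 0, len >= 9)
    codons <- apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste, collapse = "")
    sense <- setdiff(codons, .STOP_CODONS)
    paste0("ATG",
           paste(sample(sense, len / 3 - 2, replace = TRUE), collapse = ""),
           sample(.STOP_CODONS, 1L))
}

## One simulated gene: exon/intron layout, a valid ORF, coordinates relative
## to the unspliced pre-mRNA. Returns the pieces needed to place it on a
## chromosome and to emit GFF3.
.simGene <- function(cfg, geneId) {
    k <- sample(cfg@exonsPerGene[1]:cfg@exonsPerGene[2], 1L)
    w <- pmin(pmax(round(stats::rlnorm(k, log(140), 0.5)), 30L), 1500L)
    introns <- if (k > 1L) sample(60:400, k - 1L, replace = TRUE) else integer(0)
    L <- sum(w)
    u5 <- sample(15:max(16L, floor(0.2 * L)), 1L)
    u3 <- sample(15:max(16L, floor(0.2 * L)), 1L)
    cdsLen <- L - u5 - u3
    if (cdsLen < 66L) { u5 <- 15L; u3 <- 15L; cdsLen <- L - 30L }
    u3 <- u3 + cdsLen %% 3L
    cdsLen <- cdsLen - cdsLen %% 3L
    tx <- paste0(.randSeq(u5), .randOrf(cdsLen), .randSeq(u3))
    ## transcript coordinates of exons
    ce <- cumsum(w)
    txStart <- c(1L, ce[-k] + 1L)
    ## unspliced coordinates (introns inserted)
    shift <- c(0L, cumsum(introns))
    uStart <- txStart + shift
    uEnd <- ce + shift
    segs <- character(2L * k - 1L)
    segs[seq(1L, 2L * k - 1L, by = 2L)] <-
        substring(tx, txStart, ce)
    if (k > 1L)
        segs[seq(2L, 2L * k - 2L, by = 2L)] <-
            vapply(introns, .randSeq, character(1))
    ## CDS in transcript coordinates, split per exon
    cdsA <- u5 + 1L; cdsB <- u5 + cdsLen
    spans <- list()
    for (i in seq_len(k)) {
        a <- max(txStart[i], cdsA); b <- min(ce[i], cdsB)
        if (a <= b)
            spans[[length(spans) + 1L]] <-
                c(uStart[i] + (a - txStart[i]), uStart[i] + (b - txStart[i]))
    }
    spans <- do.call(rbind, spans)
    list(id = geneId, unspliced = paste(segs, collapse = ""),
         G = uEnd[k], exonU = cbind(uStart, uEnd), cdsU = spans,
         phases = .cumlen_phases(spans[, 2] - spans[, 1] + 1L, 0L))
}

#' Simulate a toy genome, annotation and GO resources
#'
#' Writes a multi-record FASTA genome, a GFF3 annotation of coding genes with
#' distinct 5'UTR/CDS/3'UTR exon composition and valid CDS phases on both
#' strands, a gene-to-GO-term association table, and a three-namespace toy
#' ontology in OBO format. Every CDS is a valid open reading frame (start
#' codon, no internal stop, terminal stop), so phase-aware translation can be
#' verified end to end. Output is byte-deterministic for a given seed.
#'
#' @param cfg a [SimConfig]
#' @param dir output directory (created if needed)
#' @return list with paths (`fasta`, `gff3`, `goAssoc`, `obo`), the parsed
#'   [TranscriptModelList] in `models`, and the gene table in `genes`
#' @export
simulateGenomeAnnotation <- function(cfg, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(cfg@seed)
    nChrom <- max(2L, ceiling(cfg@nGenes / 30L))
    cursor <- stats::setNames(rep(0L, nChrom), paste0("chr", seq_len(nChrom)))
    chromSeq <- stats::setNames(rep(list(character(0)), nChrom), names(cursor))
    models <- list()
    generows <- list()
    gff <- c("##gff-version 3")
    for (g in seq_len(cfg@nGenes)) {
        gid <- sprintf("gene%03d", g)
        tid <- sprintf("mrna%03d", g)
        strand <- sample(c("+", "-"), 1L)
        sim <- .simGene(cfg, gid)
        chrom <- names(cursor)[(g - 1L) %% nChrom + 1L]
        spacer <- sample(200:500, 1L)
        geneStart <- cursor[[chrom]] + spacer + 1L
        geneEnd <- geneStart + sim$G - 1L
        chromSeq[[chrom]] <- c(chromSeq[[chrom]], .randSeq(spacer),
                               if (strand == "+") sim$unspliced else
                               as.character(Biostrings::reverseComplement(
                                   Biostrings::DNAString(sim$unspliced))))
        cursor[[chrom]] <- geneEnd
        toGenomic <- function(u) {
            if (strand == "+")
                cbind(geneStart + u[, 1] - 1L, geneStart + u[, 2] - 1L)
            else cbind(geneEnd - u[, 2] + 1L, geneEnd - u[, 1] + 1L)
        }
        exG <- toGenomic(sim$exonU)
        cdsG <- toGenomic(sim$cdsU)
        ## toGenomic keeps transcript order: on the minus strand exon 1 has
        ## the highest genomic coordinates, as TranscriptModel expects
        model <- TranscriptModel(
            tid, gid, chrom, strand,
            exons = IRanges(exG[, 1], exG[, 2]),
            cds = IRanges(cdsG[, 1], cdsG[, 2]),
            phases = sim$phases)
        models[[tid]] <- model
        generows[[gid]] <- data.frame(gene_id = gid, transcript_id = tid,
                                      chrom = chrom, strand = strand,
                                      start = geneStart, end = geneEnd)
        attr_ <- function(id, parent)
            if (is.na(parent)) sprintf("ID=%s", id)
            else sprintf("ID=%s;Parent=%s", id, parent)
        gff <- c(gff,
                 sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s", chrom,
                         geneStart, geneEnd, strand, attr_(gid, NA)),
                 sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\t%s", chrom,
                         geneStart, geneEnd, strand, attr_(tid, gid)),
                 sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         chrom, exG[, 1], exG[, 2], strand, tid,
                         seq_len(nrow(exG)), tid))
        ## each CDS row carries the phase of its transcript-order span
        gff <- c(gff,
                 sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                         chrom, cdsG[, 1], cdsG[, 2], strand, sim$phases,
                         tid, tid))
    }
    genome <- Biostrings::DNAStringSet(vapply(chromSeq, paste,
                                              character(1), collapse = ""))
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "annotation.gff3"),
                  goAssoc = file.path(dir, "go_association.tsv"),
                  obo = file.path(dir, "ontology.obo"))
    Biostrings::writeXStringSet(genome, paths$fasta, width = 70L)
    writeLines(gff, paths$gff3)
    onto <- .simOntology()
    writeLines(onto$obo, paths$obo)
    assoc <- .simAssociations(cfg, names(generows), onto)
    utils::write.table(assoc, paths$goAssoc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(paths, list(models = TranscriptModelList(models),
                  genes = do.call(rbind, c(generows, make.row.names = FALSE))))
}

## Toy three-namespace ontology: roots, depth-1 parents, leaves (one leaf
## with two molecular_function parents to exercise DAG semantics).
.simOntology <- function() {
    term <- function(id, name, ns, isa = character(0)) {
        c("", "[Term]", paste0("id: ", id), paste0("name: ", name),
          paste0("namespace: ", ns),
          if (length(isa)) paste0("is_a: ", isa, " ! parent"))
    }
    parents <- list(
        mf = c("TOY:0100" = "binding", "TOY:0101" = "catalytic activity",
               "TOY:0102" = "transporter activity",
               "TOY:0103" = "structural molecule activity"),
        bp = c("TOY:0200" = "metabolic process", "TOY:0201" = "signaling",
               "TOY:0202" = "cellular process"),
        cc = c("TOY:0300" = "membrane", "TOY:0301" = "organelle"))
    leaves <- list(
        c("TOY:1000", "small molecule binding", "molecular_function", "TOY:0100"),
        c("TOY:1001", "drug binding", "molecular_function", "TOY:0100"),
        c("TOY:1002", "hydrolase activity", "molecular_function", "TOY:0101"),
        c("TOY:1003", "ion transport activity", "molecular_function", "TOY:0102"),
        c("TOY:1005", "structural constituent", "molecular_function", "TOY:0103"),
        c("TOY:2000", "lipid metabolic process", "biological_process", "TOY:0200"),
        c("TOY:2001", "signal transduction", "biological_process", "TOY:0201"),
        c("TOY:2002", "cell cycle", "biological_process", "TOY:0202"),
        c("TOY:3000", "plasma membrane", "cellular_component", "TOY:0300"),
        c("TOY:3001", "nucleus", "cellular_component", "TOY:0301"))
    obo <- c("format-version: 1.2",
             term("TOY:0001", "molecular_function", "molecular_function"),
             term("TOY:0002", "biological_process", "biological_process"),
             term("TOY:0003", "cellular_component", "cellular_component"))
    rootOf <- c(mf = "TOY:0001", bp = "TOY:0002", cc = "TOY:0003")
    nsOf <- c(mf = "molecular_function", bp = "biological_process",
              cc = "cellular_component")
    for (ns in names(parents))
        for (i in seq_along(parents[[ns]]))
            obo <- c(obo, term(names(parents[[ns]])[i], parents[[ns]][i],
                               nsOf[[ns]], rootOf[[ns]]))
    for (lf in leaves)
        obo <- c(obo, term(lf[1], lf[2], lf[3], lf[4]))
    ## one multi-parent leaf: catalytic AND binding
    obo <- c(obo, term("TOY:1004", "catalytic binding bridge",
                       "molecular_function", c("TOY:0100", "TOY:0101")))
    list(obo = obo,
         leaves = c(vapply(leaves, `[`, character(1), 1L), "TOY:1004"),
         leafWeights = c(0.30, 0.12, 0.20, 0.10, 0.01, 0.15, 0.15, 0.10,
                         0.15, 0.15, 0.05))
}

## Gene-term associations: 1-3 leaf terms per gene, weighted so parent-term
## genome proportions are uneven; one parent is kept rare (< 2%) to exercise
## the report filter.
.simAssociations <- function(cfg, genes, onto) {
    rows <- lapply(genes, function(g) {
        n <- sample(1:3, 1L)
        data.frame(gene_id = g,
                   term = sample(onto$leaves, n, prob = onto$leafWeights))
    })
    do.call(rbind, rows)
}

.designTable <- function(cfg) {
    grid <- expand.grid(rep = seq_len(cfg@nPerCell),
                        treatment = .TREATMENTS, sex = .SEXES,
                        tissue = .TISSUES, stringsAsFactors = FALSE)
    grid$sample_id <- sprintf("%s_%s_%s_r%02d", .TISSUE_CODE[grid$tissue],
                              grid$sex, ifelse(grid$treatment == "control",
                                               "C", "S"), grid$rep)
    grid[, c("sample_id", "sex", "treatment", "tissue")]
}

#' Simulate per-sample PSI tables with known effects
#'
#' Emulates the replicated multi-tissue two-sex two-treatment design: every
#' exon of every gene becomes a splice-graph node with a baseline PSI;
#' replicate noise is Beta-distributed around the group mean with
#' concentration `psiConcentration`. A configured fraction of nodes carries a
#' true effect of at least 0.1 |delta-PSI|: sex effects (hypothalamus or
#' pituitary; active in the control stratum and, with probability
#' `convergenceFactor`, still active under stress — so sexes converge under
#' stress) and treatment effects (one sex, any tissue). A small fraction of
#' measurements (2%) is set missing. Every injected effect is recorded in a
#' truth table for recovery tests. Output is byte-deterministic per seed.
#'
#' @param cfg a [SimConfig]
#' @param annotation result of [simulateGenomeAnnotation()]
#' @param dir output directory
#' @return list: `paths` (named per-sample TSVs), `designPath`, `truthPath`,
#'   `design` (data.frame), `truth` (data.frame), `nodes` (data.frame)
#' @export
simulatePsiTables <- function(cfg, annotation, dir) {
    dir.create(file.path(dir, "psi"), recursive = TRUE, showWarnings = FALSE)
    set.seed(cfg@seed + 1L)
    models <- annotation$models
    nodes <- do.call(rbind, lapply(as.list(models), function(m) {
        ex <- exons(m)
        data.frame(gene_id = geneId(m), node_id = seq_along(ex),
                   chrom = chromName(m),
                   start = pmin(start(ex), end(ex)),
                   end = pmax(start(ex), end(ex)), strand = strand(m))
    }))
    rownames(nodes) <- NULL
    N <- nrow(nodes)
    nodes$event_type <- sample(names(cfg@eventTypeMix), N, replace = TRUE,
                               prob = cfg@eventTypeMix)
    nodes$psi0 <- stats::runif(N, 0.15, 0.85)

    nEffect <- floor(cfg@effectNodes * N)
    eff <- data.frame()
    if (nEffect > 0L) {
        idx <- sort(sample.int(N, nEffect))
        kind <- sample(c("sex", "treatment"), nEffect, replace = TRUE)
        size <- stats::runif(nEffect, cfg@effectRange[1], cfg@effectRange[2]) *
            sample(c(-1, 1), nEffect, replace = TRUE)
        eff <- data.frame(
            gene_id = nodes$gene_id[idx], node_id = nodes$node_id[idx],
            node = idx, kind = kind,
            tissue = ifelse(kind == "sex",
                            sample(c("hypothalamus", "pituitary"), nEffect,
                                   replace = TRUE),
                            sample(.TISSUES, nEffect, replace = TRUE)),
            sex = ifelse(kind == "treatment",
                         sample(.SEXES, nEffect, replace = TRUE), NA),
            effect = size,
            active_in_stress = ifelse(
                kind == "sex",
                stats::runif(nEffect) < cfg@convergenceFactor, NA))
        ## keep both group means inside (0.02, 0.98)
        half <- abs(eff$effect) / 2
        nodes$psi0[idx] <- pmin(pmax(nodes$psi0[idx], half + 0.02),
                                1 - half - 0.02)
    }

    design <- .designTable(cfg)
    kappa <- cfg@psiConcentration
    paths <- character(0)
    for (s in seq_len(nrow(design))) {
        d <- design[s, ]
        mu <- nodes$psi0
        if (nrow(eff)) {
            for (j in seq_len(nrow(eff))) {
                e <- eff[j, ]
                if (e$tissue != d$tissue) next
                shift <- 0
                if (e$kind == "sex") {
                    active <- d$treatment == "control" || e$active_in_stress
                    if (active)
                        shift <- if (d$sex == "M") e$effect / 2 else -e$effect / 2
                } else if (d$sex == e$sex) {
                    shift <- if (d$treatment == "stress") e$effect / 2
                             else -e$effect / 2
                }
                mu[e$node] <- mu[e$node] + shift
            }
        }
        psi <- stats::rbeta(N, mu * kappa, (1 - mu) * kappa)
        ci <- pmin(pmax(3.92 * sqrt(psi * (1 - psi) / (kappa + 1)), 0.02), 1)
        drop <- stats::runif(N) < 0.02
        psiTxt <- sprintf("%.5f", psi); ciTxt <- sprintf("%.5f", ci)
        psiTxt[drop] <- "NA"; ciTxt[drop] <- "NA"
        tab <- data.frame(
            Gene = nodes$gene_id, Node = nodes$node_id,
            Coord = sprintf("%s:%d-%d", nodes$chrom, nodes$start, nodes$end),
            Strand = nodes$strand, Type = nodes$event_type,
            Psi = psiTxt, CI_Width = ciTxt)
        p <- file.path(dir, "psi", paste0(d$sample_id, ".psi.tsv"))
        utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[d$sample_id] <- p
    }
    designPath <- file.path(dir, "design.tsv")
    utils::write.table(design, designPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truthPath <- file.path(dir, "truth.tsv")
    truth <- if (nrow(eff)) eff[, setdiff(colnames(eff), "node")] else
        data.frame(gene_id = character(0), node_id = integer(0),
                   kind = character(0), tissue = character(0),
                   sex = character(0), effect = numeric(0),
                   active_in_stress = logical(0))
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(paths = paths, designPath = designPath, truthPath = truthPath,
         design = design, truth = truth, nodes = nodes)
}

#' Simulate an isoform x sample TPM table
#'
#' Log-normal abundances per isoform with per-sample noise; optionally
#' injects isoforms expressed exclusively in the stress treatment group
#' (names prefixed `excl`), silent everywhere else, for testing exclusive
#' isoform detection.
#'
#' @param cfg a [SimConfig]
#' @param annotation result of [simulateGenomeAnnotation()]
#' @param dir output directory
#' @return list: `path` (TSV, isoforms x samples), `tpm` matrix,
#'   `design`, `injected` (character vector of injected isoform ids)
#' @export
simulateTpm <- function(cfg, annotation, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(cfg@seed + 2L)
    design <- .designTable(cfg)
    genes <- annotation$genes$gene_id
    iso <- as.vector(t(outer(genes, seq_len(cfg@nIsoformsPerGene),
                             function(g, i) sprintf("%s.i%d", g, i))))
    base <- stats::rlnorm(length(iso), log(10), 1)
    tpm <- matrix(base, nrow = length(iso), ncol = nrow(design)) *
        matrix(stats::rlnorm(length(iso) * nrow(design), 0, 0.3),
               nrow = length(iso))
    rownames(tpm) <- iso
    colnames(tpm) <- design$sample_id
    injected <- character(0)
    if (cfg@nExclusiveIsoforms > 0L) {
        injected <- sprintf("excl%02d.i1", seq_len(cfg@nExclusiveIsoforms))
        on <- design$treatment == "stress"
        extra <- matrix(0, nrow = length(injected), ncol = nrow(design),
                        dimnames = list(injected, design$sample_id))
        extra[, on] <- pmax(stats::rlnorm(length(injected) * sum(on),
                                          log(5), 0.2), 1.5)
        tpm <- rbind(tpm, extra)
    }
    path <- file.path(dir, "tpm.tsv")
    out <- data.frame(isoform = rownames(tpm),
                      apply(tpm, 2L, function(x) sprintf("%.4f", x)),
                      check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(path = path, tpm = tpm, design = design, injected = injected)
}
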