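## Shared fixtures, all built in code.

## The canonical three-exon coding transcript: exons 1-100, 201-300, 401-500,
## CDS 51-100, 201-300, 401-450 (phases 0,1,0 from cumulative CDS length).
plusModel <- function() {
    TranscriptModel("txP", "gP", "chrT", "+",
                    exons = IRanges::IRanges(c(1, 201, 401), c(100, 300, 500)),
                    cds = IRanges::IRanges(c(51, 201, 401), c(100, 300, 450)),
                    phases = c(0L, 1L, 0L))
}

## The same structure reflected through position 601 - x on a 600 bp
## chromosome, on the minus strand (transcript orientation preserved).
minusModel <- function() {
    TranscriptModel("txM", "gM", "chrT", "-",
                    exons = IRanges::IRanges(c(501, 301, 101), c(600, 400, 200)),
                    cds = IRanges::IRanges(c(501, 301, 151), c(550, 400, 200)),
                    phases = c(0L, 1L, 0L))
}

writeToyGff3 <- function(path = tempfile(fileext = ".gff3")) {
    writeLines(c(
        "##gff-version 3",
        "chrT\ttoy\tgene\t1\t500\t.\t+\t.\tID=gP",
        "chrT\ttoy\tmRNA\t1\t500\t.\t+\t.\tID=txP;Parent=gP",
        "chrT\ttoy\texon\t1\t100\t.\t+\t.\tID=txP.e1;Parent=txP",
        "chrT\ttoy\texon\t201\t300\t.\t+\t.\tID=txP.e2;Parent=txP",
        "chrT\ttoy\texon\t401\t500\t.\t+\t.\tID=txP.e3;Parent=txP",
        "chrT\ttoy\tCDS\t51\t100\t.\t+\t0\tID=txP.c1;Parent=txP",
        "chrT\ttoy\tCDS\t201\t300\t.\t+\t1\tID=txP.c2;Parent=txP"),
        path)
    path
}

## A tiny toy ontology with two namespaces, two depth-1 parents under
## molecular_function, and a leaf reachable through both parents.
writeToyObo <- function(path = tempfile(fileext = ".obo")) {
    term <- function(id, name, ns, isa = character(0)) {
        c("", "[Term]", paste0("id: ", id), paste0("name: ", name),
          paste0("namespace: ", ns),
          if (length(isa)) paste0("is_a: ", isa, " ! up"))
    }
    writeLines(c(
        "format-version: 1.2",
        term("MF:0", "molecular_function", "molecular_function"),
        term("BP:0", "biological_process", "biological_process"),
        term("MF:1", "binding", "molecular_function", "MF:0"),
        term("MF:2", "catalytic activity", "molecular_function", "MF:0"),
        term("MF:11", "small molecule binding", "molecular_function", "MF:1"),
        term("MF:12", "drug binding", "molecular_function", "MF:1"),
        term("MF:21", "hydrolase activity", "molecular_function", "MF:2"),
        term("MF:31", "catalytic binding", "molecular_function",
             c("MF:1", "MF:2")),
        term("BP:1", "metabolic process", "biological_process", "BP:0"),
        term("BP:11", "lipid metabolism", "biological_process", "BP:1")),
        path)
    path
}

## Build an in-memory PsiTable: `groups` is a named list of numeric vectors
## (one value per sample) per node; design has one row per sample.
psiTableFrom <- function(psiMatrix, design, eventType = "CE") {
    n <- nrow(psiMatrix)
    rd <- data.frame(
        gene_id = sprintf("g%03d", seq_len(n)), node_id = 1L,
        chrom = "chr1", start = 10L * seq_len(n),
        end = 10L * seq_len(n) + 5L, strand = "+",
        event_type = eventType,
        row.names = sprintf("g%03d:1", seq_len(n)))
    colnames(psiMatrix) <- rownames(design)
    rownames(psiMatrix) <- rownames(rd)
    ci <- psiMatrix * 0 + 0.1
    makePsiTable(psiMatrix, ci, rd, design)
}

twoGroupDesign <- function(nA, nB, tissue = "hypothalamus") {
    design <- data.frame(
        sex = c(rep("M", nA), rep("F", nB)),
        treatment = "control", tissue = tissue,
        row.names = c(sprintf("a%02d", seq_len(nA)),
                      sprintf("b%02d", seq_len(nB))))
    design
}

mvfComparison <- function(tissue = "hypothalamus") {
    Comparison(paste0(tissue, ":MvF:control"),
               list(sex = "M", tissue = tissue),
               list(sex = "F", tissue = tissue))
}

## Small synthetic bundle shared by annotation/peptide/pipeline tests.
smallBundle <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- SimConfig(seed = 11, nGenes = 14, nPerCell = 3)
            dir <- file.path(tempdir(), "ssbundle")
            ann <- simulateGenomeAnnotation(cfg, dir)
            cache <<- list(cfg = cfg, ann = ann,
                           models = parseGFF3(ann$gff3))
        }
        cache
    }
})
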