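#' Default pipeline configuration
#'
#' A nested list with one section per command; every analysis threshold lives
#' here (significance filter 0.95/0.1, GO parent depth and 2% genome filter,
#' TPM exclusivity cutoffs, bootstrap size).
#'
#' @return named list of sections
#' @export
defaultConfig <- function() {
    list(
        seed = 1L,
        simulate = list(n_genes = 60L, exons_per_gene = c(5L, 11L),
                        n_per_cell = 12L, effect_nodes = 0.08,
                        effect_range = c(0.15, 0.5), psi_concentration = 24,
                        convergence_factor = 0.5, n_isoforms_per_gene = 2L,
                        n_exclusive_isoforms = 0L),
        delta = list(n_boot = 10000L, method = "bootstrap"),
        significance = list(prob_min = 0.95, dpsi_min = 0.1, fdr = FALSE,
                            sensitivity_alpha = 0.05),
        annotation = list(isoform_policy = "all"),
        go = list(parent_depth = 1L, min_genome_frac = 0.02,
                  include_part_of = FALSE),
        isoforms = list(on_min = 1, off_max = 0.1, min_frac = 0.75),
        report = list(psi_bins = 20L, percent_digits = 0L))
}

.mergeConfig <- function(base, override, path = character(0)) {
    bad <- setdiff(names(override), names(base))
    if (length(bad))
        stop("unknown config key(s): ",
             paste(paste(c(path, ""), collapse = "."), bad, sep = "",
                   collapse = ", "), call. = FALSE)
    for (k in names(override)) {
        if (is.list(base[[k]]) && is.list(override[[k]]))
            base[[k]] <- .mergeConfig(base[[k]], override[[k]], c(path, k))
        else base[[k]] <- override[[k]]
    }
    base
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys are rejected (naming the offending keys); omitted keys take
#' their defaults from [defaultConfig()].
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return validated config list
#' @export
readConfig <- function(path = NULL) {
    cfg <- defaultConfig()
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
    }
    cfg
}

.simConfigFrom <- function(config) {
    s <- config$simulate
    SimConfig(seed = config$seed, nGenes = s$n_genes,
              exonsPerGene = s$exons_per_gene, nPerCell = s$n_per_cell,
              effectNodes = s$effect_nodes, effectRange = s$effect_range,
              psiConcentration = s$psi_concentration,
              convergenceFactor = s$convergence_factor,
              nIsoformsPerGene = s$n_isoforms_per_gene,
              nExclusiveIsoforms = s$n_exclusive_isoforms)
}

#' The standard comparison set for the HPG design
#'
#' Male-vs-female within each treatment stratum for hypothalamus and
#' pituitary (gonads are never compared across sexes: splicing differs
#' inherently between ovary and testis), and control-vs-stress within each
#' sex for all three tissues. Labels follow `tissue:kind:stratum`.
#'
#' @return list of [Comparison] objects
#' @export
standardComparisons <- function() {
    cmps <- list()
    for (tis in c("hypothalamus", "pituitary"))
        for (tr in .TREATMENTS)
            cmps[[paste(tis, "MvF", tr, sep = ":")]] <- Comparison(
                paste(tis, "MvF", tr, sep = ":"),
                list(tissue = tis, treatment = tr, sex = "M"),
                list(tissue = tis, treatment = tr, sex = "F"))
    for (tis in .TISSUES)
        for (sx in .SEXES)
            cmps[[paste(tis, "CvS", sx, sep = ":")]] <- Comparison(
                paste(tis, "CvS", sx, sep = ":"),
                list(tissue = tis, sex = sx, treatment = "control"),
                list(tissue = tis, sex = sx, treatment = "stress"))
    cmps
}

#' Generate the synthetic fixture bundle
#'
#' @param config config list from [readConfig()]
#' @param outDir output directory; files go under `outDir/sim`
#' @return list: `annotation`, `psi`, `tpm` (generator results)
#' @export
runSimulate <- function(config, outDir) {
    cfg <- .simConfigFrom(config)
    simDir <- file.path(outDir, "sim")
    annotation <- simulateGenomeAnnotation(cfg, simDir)
    psi <- simulatePsiTables(cfg, annotation, simDir)
    tpm <- simulateTpm(cfg, annotation, simDir)
    message(sprintf("simulated %d genes, %d nodes, %d samples",
                    cfg@nGenes, nrow(psi$nodes), nrow(psi$design)))
    list(annotation = annotation, psi = psi, tpm = tpm)
}

#' Differential-splicing tables for every standard comparison
#'
#' Reads the per-sample PSI tables, runs the bootstrap delta-PSI for each
#' comparison (seeded deterministically from the config seed), and writes one
#' diff TSV per comparison under `outDir/diff`.
#'
#' @param config config list
#' @param outDir output directory
#' @param psiPaths named per-sample TSV paths
#' @param design design data.frame (rownames or `sample_id` column)
#' @return data.frame of all events across comparisons
#' @export
runDelta <- function(config, outDir, psiPaths, design) {
    for (p in psiPaths) if (!file.exists(p)) stop("missing input: ", p)
    table <- readPsiTable(psiPaths, design)
    dir.create(file.path(outDir, "diff"), recursive = TRUE,
               showWarnings = FALSE)
    cmps <- standardComparisons()
    all <- list()
    for (i in seq_along(cmps)) {
        cmp <- cmps[[i]]
        ev <- suppressWarnings(deltaPsi(
            table, cmp, nBoot = config$delta$n_boot,
            seed = config$seed + 97L * i, method = config$delta$method))
        writeDiffTable(ev, file.path(outDir, "diff", paste0(
            gsub(":", "_", cmp@label), ".diff.tsv")))
        all[[cmp@label]] <- ev
    }
    out <- do.call(rbind, c(all, make.row.names = FALSE))
    message(sprintf("delta: %d node-comparisons across %d comparisons",
                    nrow(out), length(cmps)))
    out
}

.significant <- function(config, events) {
    sig <- callSignificant(events, config$significance$prob_min,
                           config$significance$dpsi_min)
    if (isTRUE(config$significance$fdr)) {
        ## optional Benjamini-Hochberg on (1 - probability)
        padj <- stats::p.adjust(1 - sig$probability, method = "BH")
        sig <- sig[padj <= 1 - config$significance$prob_min, , drop = FALSE]
    }
    message(sprintf("filter: %d events in -> %d significant, %d not",
                    nrow(events), nrow(sig), nrow(events) - nrow(sig)))
    sig
}

.writeTsv <- function(d, path) {
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(nrow(d))
}

#' Landscape reports: tallies, chi-square table, regions, lengths, PSI
#'
#' Writes under `outDir/landscape`: the significant-event tally, a
#' "analysis / description / p / df / n"-shaped chi-square report covering
#' tissue, treatment-stratum, event-type and transcript-region tests
#' (uniform and genome-expectation nulls), per-region deviations, spliced
#' exon-length rank-sum tests against the genomic distribution, percent
#' changes, delta-PSI/PSI histograms, the relaxed-threshold sensitivity
#' recall, and exclusive-isoform flags.
#'
#' @param config config list
#' @param outDir output directory
#' @param events data.frame from [runDelta()]
#' @param models a [TranscriptModelList]
#' @param expectation an [ExpectationModel]
#' @param tpm optional TPM matrix with matching design for exclusivity checks
#' @param design design data.frame (required with `tpm`)
#' @return list of the report data.frames
#' @export
runLandscape <- function(config, outDir, events, models, expectation,
                         tpm = NULL, design = NULL) {
    dir <- file.path(outDir, "landscape")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sig <- .significant(config, events)
    tally <- tallyEvents(sig)
    .writeTsv(tally, file.path(dir, "tally.tsv"))

    lab <- .splitLabel(sig$comparison)
    rows <- list()
    addRow <- function(analysis, description, res) {
        rows[[length(rows) + 1L]] <<- data.frame(
            analysis = analysis, description = description,
            statistic = res$statistic, p = res$p, df = res$df, n = res$n)
    }
    pct <- list()
    for (kind in unique(lab$kind)) {
        sel <- lab$kind == kind
        ## splicing abundance across tissues
        byTissue <- table(lab$tissue[sel])
        if (length(byTissue) >= 2L && all(byTissue > 0))
            addRow(kind, "splicing abundance by tissue",
                   chiSquareGof(as.integer(byTissue)))
        if (all(c("hypothalamus", "pituitary") %in% names(byTissue)) &&
            byTissue[["hypothalamus"]] > 0)
            pct[[paste0(kind, ":pit_vs_hyp")]] <- data.frame(
                kind = kind, contrast = "pituitary_vs_hypothalamus",
                percent = percentChange(byTissue[["pituitary"]],
                                        byTissue[["hypothalamus"]],
                                        config$report$percent_digits))
        for (tis in unique(lab$tissue[sel])) {
            st <- table(lab$stratum[sel & lab$tissue == tis])
            if (length(st) >= 2L && all(st > 0)) {
                addRow(kind, sprintf("splicing by stratum - %s", tis),
                       chiSquareGof(as.integer(st)))
                pct[[paste0(kind, ":", tis, ":stratum")]] <- data.frame(
                    kind = kind, contrast = sprintf(
                        "%s_%s_vs_%s", tis, names(st)[1L], names(st)[2L]),
                    percent = percentChange(st[[1L]], st[[2L]],
                                            config$report$percent_digits))
            }
            ty <- table(sig$event_type[sel & lab$tissue == tis])
            ty <- ty[ty > 0]
            if (length(ty) >= 2L)
                addRow(kind, sprintf("event-type abundance - %s", tis),
                       chiSquareGof(as.integer(ty)))
        }
    }

    ## transcript regions: observed vs genomic expectation
    segments <- regionSegments(models)
    sig <- regionAssign(sig, segments)
    regionReport <- list()
    for (kind in unique(lab$kind)) {
        for (tis in unique(lab$tissue[lab$kind == kind])) {
            reg <- sig$region[lab$kind == kind & lab$tissue == tis]
            reg <- reg[!is.na(reg)]
            if (length(reg) < 3L) next
            rt <- regionDeviationTest(reg, expectation)
            addRow(kind, sprintf("regions vs genomic expectation - %s", tis),
                   rt$omnibus)
            obs <- vapply(.REGIONS, function(r) sum(reg == r), integer(1))
            if (all(obs > 0))
                addRow(kind, sprintf("splicing by region (uniform) - %s", tis),
                       chiSquareGof(as.integer(obs)))
            for (j in seq_len(nrow(rt$deviations)))
                addRow(kind, sprintf("%s vs genome - %s",
                                     rt$deviations$region[j], tis),
                       data.frame(statistic = rt$deviations$statistic[j],
                                  p = rt$deviations$p[j], df = 1L,
                                  n = length(reg)))
            rt$deviations$kind <- kind
            rt$deviations$tissue <- tis
            regionReport[[paste(kind, tis)]] <- rt$deviations
        }
    }
    if (length(regionReport))
        .writeTsv(do.call(rbind, c(regionReport, make.row.names = FALSE)),
                  file.path(dir, "region_deviation.tsv"))

    ## spliced exon lengths vs genomic distribution (core-exon events)
    lenRows <- list()
    for (kind in unique(lab$kind)) {
        for (tis in unique(lab$tissue[lab$kind == kind])) {
            sel <- lab$kind == kind & lab$tissue == tis &
                sig$event_type == "CE"
            lens <- sig$end[sel] - sig$start[sel] + 1L
            if (length(lens) < 2L) next
            res <- exonLengthTest(lens, exonLengths(expectation))
            addRow(kind, sprintf("spliced exon lengths vs genome - %s", tis),
                   res)
            lenRows[[paste(kind, tis)]] <- data.frame(
                kind = kind, tissue = tis, n_spliced = length(lens),
                median_spliced = stats::median(lens),
                median_genome = stats::median(exonLengths(expectation)),
                p = res$p)
        }
    }
    if (length(lenRows))
        .writeTsv(do.call(rbind, c(lenRows, make.row.names = FALSE)),
                  file.path(dir, "exon_lengths.tsv"))

    chiTable <- do.call(rbind, c(rows, make.row.names = FALSE))
    .writeTsv(chiTable, file.path(dir, "chi_square_tests.tsv"))
    if (length(pct))
        .writeTsv(do.call(rbind, c(pct, make.row.names = FALSE)),
                  file.path(dir, "percent_change.tsv"))

    if (nrow(sig))
        .writeTsv(psiDistribution(sig, config$report$psi_bins),
                  file.path(dir, "psi_distribution.tsv"))
    recall <- sensitivityRecall(events, config$significance$sensitivity_alpha)
    .writeTsv(tallyEvents(recall), file.path(dir, "sensitivity_recall.tsv"))

    excl <- NULL
    if (!is.null(tpm)) {
        if ("sample_id" %in% colnames(design)) {
            rownames(design) <- design$sample_id
        }
        hits <- list()
        for (tis in unique(design$tissue)) {
            sel <- rownames(design)[design$tissue == tis]
            for (f in c("treatment", "sex")) {
                h <- exclusiveIsoforms(
                    tpm[, sel, drop = FALSE], design[sel, , drop = FALSE],
                    groupBy = f, onMin = config$isoforms$on_min,
                    offMax = config$isoforms$off_max,
                    minFrac = config$isoforms$min_frac)
                if (nrow(h)) { h$tissue <- tis; hits[[paste(tis, f)]] <- h }
            }
        }
        excl <- if (length(hits))
            do.call(rbind, c(hits, make.row.names = FALSE))
        else data.frame(isoform = character(0), group = character(0),
                        factor = character(0), tissue = character(0))
        .writeTsv(excl, file.path(dir, "exclusive_isoforms.tsv"))
        message(sprintf("exclusive isoforms flagged: %d", nrow(excl)))
    }
    list(significant = sig, tally = tally, chiTable = chiTable,
         regions = if (length(regionReport))
             do.call(rbind, c(regionReport, make.row.names = FALSE)) else NULL,
         recall = recall, exclusives = excl)
}

#' Extract, classify and translate significant spliced exons
#'
#' @param config config list
#' @param outDir output directory
#' @param significant data.frame of significant events
#' @param models a [TranscriptModelList]
#' @param genome FASTA path or [Biostrings::DNAStringSet]
#' @return the peptide data.frame
#' @export
runExons <- function(config, outDir, significant, models, genome) {
    dir <- file.path(outDir, "exons")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ## one record per unique node
    uniq <- significant[!duplicated(paste(significant$gene_id,
                                          significant$node_id)), , drop = FALSE]
    peps <- suppressMessages(exonPeptides(uniq, models, genome))
    writePeptideFasta(peps, file.path(dir, "spliced_exon_peptides.fa"))
    .writeTsv(peps[, c("key", "gene_id", "node_id", "region", "strand",
                       "phase", "length", "peptide")],
              file.path(dir, "exon_regions_lengths.tsv"))
    message(sprintf("exons: %d unique nodes -> %d classified, %d translated",
                    nrow(uniq), nrow(peps), sum(nzchar(peps$peptide))))
    peps
}

#' GO parent-term deviation reports per tissue and comparison kind
#'
#' @param config config list
#' @param outDir output directory
#' @param significant data.frame of significant events
#' @param assoc gene-term association data.frame
#' @param dag an [OntologyDag]
#' @param expectation an [ExpectationModel] with parent proportions
#' @return data.frame of deviations across tissues
#' @export
runGo <- function(config, outDir, significant, assoc, dag, expectation) {
    dir <- file.path(outDir, "go")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    lab <- .splitLabel(significant$comparison)
    out <- list()
    for (kind in unique(lab$kind)) {
        for (tis in unique(lab$tissue[lab$kind == kind])) {
            sel <- lab$kind == kind & lab$tissue == tis
            genes <- unique(significant$gene_id[sel])
            if (!length(genes)) next
            dev <- suppressWarnings(goDeviationTest(
                genes, assoc, dag, expectation, tissueTotal = sum(sel),
                minGenomeFrac = config$go$min_genome_frac,
                depth = config$go$parent_depth))
            if (!nrow(dev)) next
            dev$kind <- kind; dev$tissue <- tis
            out[[paste(kind, tis)]] <- dev
        }
    }
    res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
    else data.frame()
    .writeTsv(res, file.path(dir, "go_parent_deviation.tsv"))
    res
}

#' Run the full pipeline on a seeded synthetic bundle
#'
#' simulate -> read PSI -> delta -> significance filter -> landscape,
#' region, length, GO, exon-peptide and exclusive-isoform reports, then a
#' run manifest (config snapshot, seed, per-stage counts, md5 checksum of
#' every output file). Reruns with the same config are byte-identical.
#'
#' @param config config list from [readConfig()]
#' @param outDir output directory
#' @return list of stage results, invisibly
#' @export
runAll <- function(config, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    bundle <- runSimulate(config, outDir)
    events <- runDelta(config, outDir, bundle$psi$paths, bundle$psi$design)
    models <- bundle$annotation$models
    assoc <- readGoAssociations(bundle$annotation$goAssoc)
    dag <- readObo(bundle$annotation$obo,
                   includePartOf = config$go$include_part_of)
    expectation <- buildExpectationModel(
        models, assoc, dag, isoformPolicy = config$annotation$isoform_policy,
        parentDepth = config$go$parent_depth)
    land <- runLandscape(config, outDir, events, models, expectation,
                         tpm = bundle$tpm$tpm, design = bundle$psi$design)
    peps <- runExons(config, outDir, land$significant, models,
                     bundle$annotation$fasta)
    godev <- runGo(config, outDir, land$significant, assoc, dag, expectation)
    gffToGtf(models, file.path(outDir, "sim", "annotation.gtf"))
    writeManifest(config, outDir, counts = c(
        events = nrow(events), significant = nrow(land$significant),
        assigned = sum(!is.na(land$significant$region)),
        peptides = nrow(peps), go_terms = nrow(godev)))
    invisible(list(bundle = bundle, events = events, landscape = land,
                   peptides = peps, go = godev))
}

#' Write the run manifest
#'
#' YAML with the config snapshot, seed, package version, per-stage row
#' counts, and an md5 checksum for every file under `outDir` (so identical
#' reruns are verifiable byte for byte).
#'
#' @param config config list
#' @param outDir output directory
#' @param counts named integer vector of per-stage row counts
#' @return path to the manifest, invisibly
#' @export
writeManifest <- function(config, outDir, counts = integer(0)) {
    files <- sort(list.files(outDir, recursive = TRUE, full.names = FALSE))
    files <- setdiff(files, "manifest.yaml")
    sums <- tools::md5sum(file.path(outDir, files))
    names(sums) <- files
    manifest <- list(
        tool = "spliceScape",
        version = as.character(utils::packageVersion("spliceScape")),
        seed = config$seed,
        config = config,
        counts = as.list(counts),
        checksums = as.list(sums))
    path <- file.path(outDir, "manifest.yaml")
    yaml::write_yaml(manifest, path)
    invisible(path)
}
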