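#' Construct a PsiTable from matrices
#'
#' @param psi,ciWidth numeric matrices (nodes x samples), values in `[0,1]`
#'   or `NA`; rownames `"gene:node"`, colnames sample ids
#' @param rowData data.frame with `gene_id`, `node_id`, `chrom`, `start`,
#'   `end`, `strand`, `event_type`
#' @param design data.frame with rownames = sample ids and columns `sex`,
#'   `treatment`, `tissue`
#' @return a [PsiTable]
#' @export
makePsiTable <- function(psi, ciWidth, rowData, design) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(psi = psi, ciWidth = ciWidth),
        rowData = rowData,
        colData = S4Vectors::DataFrame(design))
    new("PsiTable", se)
}

.parseCoord <- function(coord, line = NA_integer_) {
    m <- regmatches(coord, regexec("^(.+):([0-9]+)-([0-9]+)$", coord))[[1]]
    if (length(m) != 4L)
        stop(sprintf("malformed Coord '%s'%s: expected chrom:start-end", coord,
                     if (is.na(line)) "" else sprintf(" at line %d", line)))
    list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Read per-sample Whippet-style PSI tables
#'
#' Each TSV must have the header `Gene Node Coord Strand Type Psi CI_Width`,
#' with `Coord` formatted `chrom:start-end` and `"NA"` or empty for
#' unquantified PSI. The file set is joined with the design; a sample present
#' in `paths` but absent from `design` is an error, as is an event type
#' outside the 8-value vocabulary.
#'
#' @param paths named character vector of TSV paths; names are sample ids
#' @param design data.frame with rownames (or column `sample_id`) and columns
#'   `sex`, `treatment`, `tissue`
#' @return a [PsiTable]
#' @export
readPsiTable <- function(paths, design) {
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
        stop("'paths' must be named by sample id")
    if ("sample_id" %in% colnames(design)) {
        rownames(design) <- design$sample_id
        design$sample_id <- NULL
    }
    missing <- setdiff(names(paths), rownames(design))
    if (length(missing))
        stop("sample(s) not in design: ", paste(missing, collapse = ", "))
    per <- lapply(names(paths), function(s) {
        d <- utils::read.delim(paths[[s]], colClasses = "character",
                               check.names = FALSE)
        need <- c("Gene", "Node", "Coord", "Strand", "Type", "Psi", "CI_Width")
        if (!all(need %in% colnames(d)))
            stop("PSI table for sample '", s, "' lacks columns: ",
                 paste(setdiff(need, colnames(d)), collapse = ", "))
        bad <- setdiff(unique(d$Type), .EVENT_TYPES)
        if (length(bad))
            stop("unknown event type '", bad[1L], "' in sample '", s, "'")
        d$sample <- s
        d
    })
    all <- do.call(rbind, per)
    key <- paste0(all$Gene, ":", all$Node)
    if (anyDuplicated(paste(all$sample, key)))
        stop("duplicated (sample, node) record")
    nodes <- !duplicated(key)
    ## Coord parsing with a usable line number (1-based, header = line 1)
    coords <- vector("list", sum(nodes))
    idx <- which(nodes)
    for (j in seq_along(idx)) {
        i <- idx[j]
        within <- which(all$sample[i] == names(paths))[1L]
        line <- sum(all$sample[seq_len(i)] == all$sample[i]) + 1L
        coords[[j]] <- .parseCoord(all$Coord[i], line)
    }
    ukey <- key[nodes]
    rowData <- data.frame(
        gene_id = all$Gene[nodes], node_id = as.integer(all$Node[nodes]),
        chrom = vapply(coords, `[[`, character(1), "chrom"),
        start = vapply(coords, `[[`, integer(1), "start"),
        end = vapply(coords, `[[`, integer(1), "end"),
        strand = all$Strand[nodes], event_type = all$Type[nodes],
        row.names = ukey)
    num <- function(x) { x[x %in% c("NA", "")] <- NA; as.numeric(x) }
    psi <- matrix(NA_real_, nrow = length(ukey), ncol = length(paths),
                  dimnames = list(ukey, names(paths)))
    ci <- psi
    ri <- match(key, ukey)
    cj <- match(all$sample, names(paths))
    psi[cbind(ri, cj)] <- num(all$Psi)
    ci[cbind(ri, cj)] <- num(all$CI_Width)
    makePsiTable(psi, ci, rowData, design[names(paths), , drop = FALSE])
}

## Beta shapes for a PSI point estimate and 95% CI width (posterior mode).
.betaShapes <- function(p, ci) {
    p <- min(max(p, 1e-4), 1 - 1e-4)
    sdv <- max(ci, 0.02) / 3.92
    k <- max(p * (1 - p) / sdv^2 - 1, 2)
    c(p * k, (1 - p) * k)
}

.bootProbability <- function(a, b, nBoot) {
    d <- mean(a) - mean(b)
    if (d == 0) return(0.5)
    na <- length(a); nb <- length(b)
    ma <- matrix(a[sample.int(na, na * nBoot, replace = TRUE)], nrow = na)
    mb <- matrix(b[sample.int(nb, nb * nBoot, replace = TRUE)], nrow = nb)
    dd <- .colMeans(ma, na, nBoot) - .colMeans(mb, nb, nBoot)
    (sum(sign(dd) == sign(d)) + 0.5 * sum(dd == 0)) / nBoot
}

.posteriorProbability <- function(a, b, ciA, ciB, nBoot) {
    d <- mean(a) - mean(b)
    if (d == 0) return(0.5)
    draw <- function(p, ci) {
        m <- matrix(NA_real_, nrow = length(p), ncol = nBoot)
        for (i in seq_along(p)) {
            if (p[i] <= 0 || p[i] >= 1) { m[i, ] <- p[i]; next }
            sh <- .betaShapes(p[i], ci[i])
            m[i, ] <- stats::rbeta(nBoot, sh[1], sh[2])
        }
        .colMeans(m, length(p), nBoot)
    }
    dd <- draw(a, ciA) - draw(b, ciB)
    (sum(sign(dd) == sign(d)) + 0.5 * sum(dd == 0)) / nBoot
}

#' Replicate-based delta-PSI with an inclusion-difference probability
#'
#' For every node, `delta_psi` is the difference of group-mean PSI
#' (group A minus group B, missing values dropped). The significance
#' `probability` is the fraction of seeded bootstrap resamples — samples drawn
#' with replacement within each group — whose resampled delta has the same
#' sign as the point estimate (resampled deltas of exactly zero count one
#' half); a point estimate of exactly zero reports 0.5 by convention.
#' `method = "posterior"` instead draws per-sample PSI from Beta
#' distributions parameterized by the point estimate and CI width,
#' approximating the upstream quantifier's posterior sampling.
#'
#' Nodes where a group has no non-missing value are skipped with a warning.
#'
#' @param table a [PsiTable]
#' @param cmp a [Comparison]
#' @param nBoot bootstrap replicates (default 10000)
#' @param seed integer seed; required for reproducibility
#' @param method `"bootstrap"` (default) or `"posterior"`
#' @param nodes optional subset of row keys
#' @return data.frame of splicing events: `gene_id`, `node_id`, `chrom`,
#'   `start`, `end`, `strand`, `event_type`, `psi_a`, `psi_b`, `delta_psi`,
#'   `probability`, `n_a`, `n_b`, `comparison`
#' @export
deltaPsi <- function(table, cmp, nBoot = 10000L, seed = 1L,
                     method = c("bootstrap", "posterior"), nodes = NULL) {
    method <- match.arg(method)
    stopifnot(is(table, "PsiTable"), is(cmp, "Comparison"), nBoot >= 1L)
    design <- designTable(table)
    sa <- comparisonSamples(cmp, design, "A")
    sb <- comparisonSamples(cmp, design, "B")
    if (!length(sa) || !length(sb))
        stop("comparison '", cmp@label, "' selects an empty group")
    if (length(intersect(sa, sb)))
        stop("comparison '", cmp@label, "' groups are not disjoint")
    if (!is.null(nodes)) table <- table[nodes, ]
    psi <- psiAssay(table)
    ci <- SummarizedExperiment::assay(table, "ciWidth")
    rd <- as.data.frame(SummarizedExperiment::rowData(table))
    set.seed(seed)
    n <- nrow(psi)
    out <- data.frame(
        gene_id = rd$gene_id, node_id = rd$node_id, chrom = rd$chrom,
        start = rd$start, end = rd$end, strand = rd$strand,
        event_type = rd$event_type,
        psi_a = NA_real_, psi_b = NA_real_, delta_psi = NA_real_,
        probability = NA_real_, n_a = NA_integer_, n_b = NA_integer_,
        comparison = cmp@label, row.names = rownames(psi))
    skipped <- 0L
    for (i in seq_len(n)) {
        a <- psi[i, sa]; b <- psi[i, sb]
        ka <- !is.na(a); kb <- !is.na(b)
        if (!any(ka) || !any(kb)) { skipped <- skipped + 1L; next }
        a <- a[ka]; b <- b[kb]
        out$psi_a[i] <- mean(a); out$psi_b[i] <- mean(b)
        out$delta_psi[i] <- mean(a) - mean(b)
        out$n_a[i] <- length(a); out$n_b[i] <- length(b)
        out$probability[i] <- if (method == "bootstrap")
            .bootProbability(a, b, nBoot)
        else .posteriorProbability(a, b, ci[i, sa][ka], ci[i, sb][kb], nBoot)
    }
    if (skipped > 0L)
        warning(skipped, " node(s) skipped: a group had no quantified PSI")
    out[!is.na(out$probability), , drop = FALSE]
}

#' Apply the significance filter to splicing events
#'
#' Keeps events with `probability > probMin` (strict) and
#' `|delta_psi| >= dpsiMin`, the rule used to call true splicing events.
#'
#' @param events data.frame from [deltaPsi()]
#' @param probMin probability threshold (default 0.95, strict `>`)
#' @param dpsiMin minimum `|delta_psi|` (default 0.1, inclusive `>=`)
#' @return the significant subset
#' @export
callSignificant <- function(events, probMin = 0.95, dpsiMin = 0.1) {
    if (!nrow(events)) return(events)
    events[events$probability > probMin &
           abs(events$delta_psi) >= dpsiMin, , drop = FALSE]
}

#' Low-effect events admitted by a relaxed probability rule
#'
#' Returns the additional events with `|delta_psi| < 0.1` that pass
#' `probability >= 1 - alpha`, i.e. the events a temporary "p <= alpha"
#' call would add beyond the default filter. Used to probe how strongly the
#' delta-PSI cutoff biases PSI distributions toward bimodality.
#'
#' @param events data.frame from [deltaPsi()]
#' @param alpha significance level (default 0.05)
#' @return the additional low-effect subset
#' @export
sensitivityRecall <- function(events, alpha = 0.05) {
    if (!nrow(events)) return(events)
    events[abs(events$delta_psi) < 0.1 &
           events$probability >= 1 - alpha, , drop = FALSE]
}

#' Write a differential-splicing table
#'
#' TSV with columns `Gene Node Coord Strand Type Psi_A Psi_B DeltaPsi
#' Probability`; floats at 5 decimals.
#'
#' @param events data.frame from [deltaPsi()]
#' @param path output path
#' @return number of data rows written, invisibly
#' @export
writeDiffTable <- function(events, path) {
    con <- try(file(path, open = "wt"), silent = TRUE)
    if (inherits(con, "try-error"))
        stop("cannot open '", path, "' for writing")
    on.exit(close(con))
    d <- data.frame(
        Gene = events$gene_id, Node = events$node_id,
        Coord = sprintf("%s:%d-%d", events$chrom, events$start, events$end),
        Strand = events$strand, Type = events$event_type,
        Psi_A = sprintf("%.5f", events$psi_a),
        Psi_B = sprintf("%.5f", events$psi_b),
        DeltaPsi = sprintf("%.5f", events$delta_psi),
        Probability = sprintf("%.5f", events$probability))
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(nrow(d))
}

#' Read back a differential-splicing table written by [writeDiffTable()]
#'
#' @param path TSV path
#' @return data.frame in [deltaPsi()] layout (without replicate counts)
#' @export
readDiffTable <- function(path) {
    d <- utils::read.delim(path, colClasses = "character")
    cc <- lapply(d$Coord, .parseCoord)
    data.frame(
        gene_id = d$Gene, node_id = as.integer(d$Node),
        chrom = vapply(cc, `[[`, character(1), "chrom"),
        start = vapply(cc, `[[`, integer(1), "start"),
        end = vapply(cc, `[[`, integer(1), "end"),
        strand = d$Strand, event_type = d$Type,
        psi_a = as.numeric(d$Psi_A), psi_b = as.numeric(d$Psi_B),
        delta_psi = as.numeric(d$DeltaPsi),
        probability = as.numeric(d$Probability))
}
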