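.comparisonResult <- function(statistic, df, n, p, test) {
    data.frame(statistic = unname(statistic), df = unname(df), n = n,
               p = unname(p), test = test)
}

## Comparison labels follow "tissue:kind:stratum"
## (e.g. "pituitary:MvF:control", "hypothalamus:CvS:M").
.splitLabel <- function(label) {
    parts <- strsplit(label, ":", fixed = TRUE)
    data.frame(
        tissue = vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_, character(1)),
        kind = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1)),
        stratum = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, character(1)))
}

#' Tally significant events by comparison, tissue and type
#'
#' Counts events per (comparison kind, tissue, stratum, event type), parsing
#' `tissue:kind:stratum` comparison labels. With `collapse = TRUE` the four
#' core types (CE, AA, AD, RI) are kept and the remaining types are lumped
#' into `OTHER`, so totals are conserved — the reduced view drawn in figures
#' while every type still counts toward the analyses.
#'
#' @param events data.frame of (significant) events with a `comparison` column
#' @param collapse lump TE/TS/AF/AL into `OTHER`
#' @return data.frame `comparison`, `tissue`, `kind`, `stratum`,
#'   `event_type`, `count`
#' @export
tallyEvents <- function(events, collapse = FALSE) {
    if (!nrow(events)) {
        return(data.frame(comparison = character(0), tissue = character(0),
                          kind = character(0), stratum = character(0),
                          event_type = character(0), count = integer(0)))
    }
    type <- events$event_type
    if (collapse)
        type[!type %in% c("CE", "AA", "AD", "RI")] <- "OTHER"
    tab <- as.data.frame(table(comparison = events$comparison,
                               event_type = type), stringsAsFactors = FALSE)
    names(tab)[3] <- "count"
    lab <- .splitLabel(tab$comparison)
    out <- cbind(tab[, "comparison", drop = FALSE], lab,
                 tab[, c("event_type", "count")])
    out$count <- as.integer(out$count)
    rownames(out) <- NULL
    out
}

#' Chi-square goodness-of-fit test on event counts
#'
#' Tests observed category counts against expected proportions (uniform when
#' omitted): the null that splicing events are evenly distributed across
#' tissues, treatments, sexes, types or regions. For two uniform cells the
#' statistic reduces to `(a - b)^2 / (a + b)`.
#'
#' @param observed nonnegative integer counts (>= 2 categories)
#' @param expectedProportions optional proportions summing to 1
#' @return one-row data.frame: `statistic`, `df`, `n`, `p`, `test`
#' @export
chiSquareGof <- function(observed, expectedProportions = NULL) {
    if (length(observed) < 2L) stop("need at least 2 categories")
    n <- sum(observed)
    if (n < 1) stop("need at least one observation")
    test <- "chi_square_gof"
    if (is.null(expectedProportions)) {
        expectedProportions <- rep(1 / length(observed), length(observed))
    } else {
        test <- "chi_square_expected"
        if (length(expectedProportions) != length(observed))
            stop("expectedProportions length mismatch")
        if (abs(sum(expectedProportions) - 1) > 1e-9)
            stop("expectedProportions must sum to 1")
    }
    if (any(n * expectedProportions == 0))
        stop("expected count of zero in a category")
    if (any(n * expectedProportions < 5))
        warning("expected count < 5 in a category; test run anyway")
    ht <- suppressWarnings(stats::chisq.test(observed, p = expectedProportions))
    .comparisonResult(ht$statistic, as.integer(ht$parameter), n, ht$p.value, test)
}

#' Signed percent change between two counts
#'
#' `100 * (a - b) / b`, rounded to `digits` decimals (the reports print whole
#' percents).
#'
#' @param a,b counts; `b` must be positive
#' @param digits decimals to round to (default 0)
#' @return signed percent
#' @export
percentChange <- function(a, b, digits = 0) {
    if (b == 0) stop("percent change undefined for a zero reference count")
    round(100 * (a - b) / b, digits)
}

#' Assign each splicing event to a transcript region
#'
#' Overlaps the event's node interval with the region segments of its gene
#' and picks the region with maximal base overlap; ties break
#' CDS > FIVE_UTR > THREE_UTR. Events overlapping no classified exon get
#' `NA` (logged) and are excluded from region statistics.
#'
#' @param events data.frame of events
#' @param segments data.frame from [regionSegments()]
#' @return `events` with a `region` column added
#' @export
regionAssign <- function(events, segments) {
    region <- rep(NA_character_, nrow(events))
    for (i in seq_len(nrow(events))) {
        seg <- segments[segments$gene_id == events$gene_id[i] &
                        segments$chrom == events$chrom[i], , drop = FALSE]
        if (!nrow(seg)) next
        ov <- pmax(0L, pmin(seg$end, events$end[i]) -
                        pmax(seg$start, events$start[i]) + 1L)
        if (all(ov == 0L)) next
        byreg <- vapply(.REGIONS, function(r) sum(ov[seg$region == r]),
                        numeric(1))
        best <- byreg == max(byreg)
        region[i] <- .REGIONS[best][order(.REGION_PRIORITY[.REGIONS[best]])][1L]
    }
    if (anyNA(region) && nrow(events))
        message(sum(is.na(region)),
                " event(s) overlap no classified exon: left unassigned")
    events$region <- region
    events
}

#' Deviation of splicing-event regions from genomic expectation
#'
#' Expected count per region = total assigned events x the region's share of
#' possible splicing locations genome-wide; deviation =
#' (observed - expected) / expected, so -0.5 means 50% fewer events than the
#' genomic proportions predict. Each region is tested against its complement
#' with a 1-df chi-square; an omnibus 2-df test covers all three regions.
#'
#' @param regions character vector of assigned regions (NAs dropped), or a
#'   data.frame with a `region` column
#' @param expectation an [ExpectationModel]
#' @return list with `deviations` (per-region data.frame: `region`,
#'   `observed`, `expected`, `deviation`, `statistic`, `df`, `p`) and
#'   `omnibus` (one-row test data.frame)
#' @export
regionDeviationTest <- function(regions, expectation) {
    if (is.data.frame(regions)) regions <- regions$region
    regions <- regions[!is.na(regions)]
    if (!length(regions)) stop("no assigned events")
    props <- regionProportions(expectation)
    if (any(props == 0)) stop("a region proportion is zero")
    obs <- vapply(.REGIONS, function(r) sum(regions == r), numeric(1))
    total <- sum(obs)
    expd <- total * props
    dev <- (obs - expd) / expd
    per <- lapply(.REGIONS, function(r) {
        ht <- suppressWarnings(stats::chisq.test(
            c(obs[r], total - obs[r]), p = c(props[r], 1 - props[r])))
        data.frame(region = r, observed = unname(obs[r]),
                   expected = unname(expd[r]), deviation = unname(dev[r]),
                   statistic = unname(ht$statistic), df = 1L,
                   p = unname(ht$p.value))
    })
    omnibus <- chiSquareGof(obs, props)
    list(deviations = do.call(rbind, per), omnibus = omnibus)
}

## Exact two-sided rank-sum p-value by enumeration over all labelings,
## midranks for ties. Returns (U statistic of x, p).
.rankSumExact <- function(x, ref) {
    nx <- length(x); N <- nx + length(ref)
    r <- rank(c(x, ref))
    W <- sum(r[seq_len(nx)])
    mu <- nx * (N + 1) / 2
    combos <- utils::combn(N, nx)
    Wperm <- colSums(matrix(r[combos], nrow = nx))
    p <- mean(abs(Wperm - mu) >= abs(W - mu) - 1e-9)
    c(U = W - nx * (nx + 1) / 2, p = p)
}

#' Compare spliced-exon lengths to the genomic length distribution
#'
#' Two-sample rank-sum (Mann-Whitney) test, two-sided. When both samples have
#' at most 10 values the p-value is computed by exhaustive enumeration of all
#' labelings (midranks, so ties are handled exactly); otherwise the
#' tie-corrected normal approximation of [stats::wilcox.test()] is used.
#'
#' @param splicedLengths,referenceLengths positive lengths in bp, >= 2 each
#' @return one-row data.frame: `statistic` (Mann-Whitney U of the spliced
#'   sample), `df` (`NA` for a rank test), `n`, `p`, `test`
#' @export
exonLengthTest <- function(splicedLengths, referenceLengths) {
    if (length(splicedLengths) < 2L || length(referenceLengths) < 2L)
        stop("both length samples need at least 2 values")
    n <- length(splicedLengths) + length(referenceLengths)
    if (length(splicedLengths) <= 10L && length(referenceLengths) <= 10L) {
        res <- .rankSumExact(splicedLengths, referenceLengths)
        return(.comparisonResult(res["U"], NA_integer_, n, res["p"], "rank_sum"))
    }
    ht <- suppressWarnings(stats::wilcox.test(
        splicedLengths, referenceLengths, exact = FALSE, correct = FALSE))
    .comparisonResult(ht$statistic, NA_integer_, n, ht$p.value, "rank_sum")
}

#' Histograms of delta-PSI and group PSI values
#'
#' Bins `delta_psi` over `[-1, 1]` and the group means `psi_a`/`psi_b` over
#' `[0, 1]` per (comparison, tissue, event type). The significance filter
#' discounts any event with `delta_psi` strictly between -0.1 and 0.1, so
#' histograms of significant events have an empty central band; the band is
#' recorded in the `excluded_band` attribute.
#'
#' @param events data.frame of events
#' @param bins number of bins (default 20)
#' @return tidy data.frame `comparison`, `tissue`, `event_type`, `metric`,
#'   `bin_lo`, `bin_hi`, `count`, with attribute `excluded_band = c(-0.1, 0.1)`
#' @export
psiDistribution <- function(events, bins = 20L) {
    stopifnot(nrow(events) > 0L)
    lab <- .splitLabel(events$comparison)
    key <- paste(events$comparison, events$event_type, sep = "\r")
    res <- lapply(unique(key), function(k) {
        sel <- key == k
        e <- events[sel, , drop = FALSE]
        one <- function(values, metric, lo, hi) {
            br <- seq(lo, hi, length.out = bins + 1L)
            cnt <- hist(values[!is.na(values)], breaks = br, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)$counts
            ## hist(right=FALSE) drops values equal to the upper bound; add them
            cnt[bins] <- cnt[bins] + sum(values == hi, na.rm = TRUE)
            data.frame(comparison = e$comparison[1],
                       tissue = lab$tissue[sel][1],
                       event_type = e$event_type[1], metric = metric,
                       bin_lo = br[-length(br)], bin_hi = br[-1L], count = cnt)
        }
        rbind(one(e$delta_psi, "delta_psi", -1, 1),
              one(e$psi_a, "psi_a", 0, 1),
              one(e$psi_b, "psi_b", 0, 1))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "excluded_band") <- c(-0.1, 0.1)
    out
}

#' Detect group-exclusive isoforms from TPM abundances
#'
#' An isoform is flagged exclusive to a design group when it is expressed
#' (`TPM >= onMin`) in at least `minFrac` of that group's samples and
#' silent (`TPM <= offMax`) in every sample of the complement. Subset the
#' matrix to one tissue first to assess tissue-by-tissue.
#'
#' @param tpm nonnegative matrix, isoforms x samples
#' @param design data.frame with rownames = sample ids
#' @param groupBy design factor defining the groups (default `"treatment"`)
#' @param onMin,offMax,minFrac thresholds (defaults 1 TPM, 0.1 TPM, 0.75)
#' @return data.frame `isoform`, `group`, `factor` of flagged isoforms
#'   (zero rows when none)
#' @export
exclusiveIsoforms <- function(tpm, design, groupBy = "treatment",
                              onMin = 1, offMax = 0.1, minFrac = 0.75) {
    stopifnot(all(tpm >= 0), groupBy %in% colnames(design))
    if (is.null(colnames(tpm)) || is.null(rownames(tpm)))
        stop("tpm needs isoform rownames and sample colnames")
    design <- design[colnames(tpm), , drop = FALSE]
    levels <- unique(as.character(design[[groupBy]]))
    hits <- list()
    for (g in levels) {
        inG <- design[[groupBy]] == g
        if (!any(inG) || all(inG)) next
        on <- rowMeans(tpm[, inG, drop = FALSE] >= onMin) >= minFrac
        off <- apply(tpm[, !inG, drop = FALSE] <= offMax, 1L, all)
        flagged <- rownames(tpm)[on & off]
        if (length(flagged))
            hits[[g]] <- data.frame(isoform = flagged, group = g,
                                    factor = groupBy)
    }
    if (!length(hits))
        return(data.frame(isoform = character(0), group = character(0),
                          factor = character(0)))
    out <- do.call(rbind, hits)
    rownames(out) <- NULL
    out
}
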