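eventsFixture <- function(counts) {
    ## counts: named vector comparison-label -> list of event_type counts
    rows <- list()
    for (lab in names(counts)) {
        types <- counts[[lab]]
        for (ty in names(types)) {
            k <- types[[ty]]
            if (k == 0) next
            rows[[paste(lab, ty)]] <- data.frame(
                gene_id = "g", node_id = seq_len(k), chrom = "c", start = 1L,
                end = 100L, strand = "+", event_type = ty, psi_a = 0.6,
                psi_b = 0.4, delta_psi = 0.2, probability = 0.99,
                n_a = 3L, n_b = 3L, comparison = lab)
        }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
}

test_that("tallyEvents counts cells and conserves totals when collapsing", {
    ev <- eventsFixture(list(
        "hypothalamus:MvF:control" = c(CE = 5, RI = 2, TS = 1),
        "hypothalamus:MvF:stress" = c(CE = 3, AF = 2)))
    tal <- tallyEvents(ev)
    expect_identical(
        tal$count[tal$stratum == "control" & tal$event_type == "CE"], 5L)
    expect_identical(
        tal$count[tal$stratum == "control" & tal$event_type == "RI"], 2L)
    expect_identical(sum(tal$count), nrow(ev))
    col <- tallyEvents(ev, collapse = TRUE)
    expect_identical(sum(col$count), nrow(ev))
    ## TS and AF fold into OTHER; the four core types stay
    expect_setequal(unique(col$event_type), c("CE", "RI", "OTHER"))
    expect_identical(sum(col$count[col$event_type == "OTHER"]), 3L)
    expect_identical(nrow(tallyEvents(ev[0, ])), 0L)
})

test_that("chi-square goodness of fit reproduces printed two-cell tests", {
    ## event totals printed for the male-female comparison
    expect_equal(signif(chiSquareGof(c(225, 158))$p, 3), 6.18e-4)
    expect_equal(signif(chiSquareGof(c(99, 59))$p, 3), 1.46e-3)
    expect_equal(signif(chiSquareGof(c(123, 102))$p, 3), 0.162)
    perfect <- chiSquareGof(c(50, 50))
    expect_equal(perfect$statistic, 0)
    expect_equal(perfect$p, 1)
    expect_identical(perfect$n, 100)
    expect_identical(perfect$df, 1L)
})

test_that("two-cell uniform chi-square equals the closed form (a-b)^2/(a+b)", {
    set.seed(2)
    for (i in 1:20) {
        ab <- sample(5:400, 2)
        expect_equal(chiSquareGof(ab)$statistic,
                     diff(ab)^2 / sum(ab))
    }
})

test_that("chi-square errors on zero expectation and warns on small cells", {
    expect_error(chiSquareGof(c(10, 10), c(1, 0)), "zero")
    expect_error(chiSquareGof(c(5)), "2 categories")
    expect_warning(chiSquareGof(c(4, 3)), "< 5")
    res <- suppressWarnings(chiSquareGof(c(4, 3)))
    expect_true(res$p > 0 && res$p <= 1)
    ## non-uniform expectation is used verbatim
    res <- chiSquareGof(c(30, 70), c(0.3, 0.7))
    expect_equal(res$statistic, 0)
    expect_identical(res$test, "chi_square_expected")
})

test_that("percent change matches the printed rounding convention", {
    expect_identical(percentChange(225, 158), 42)
    expect_identical(percentChange(7, 7), 0)
    expect_identical(percentChange(158, 225), round(100 * (158 - 225) / 225))
    expect_error(percentChange(5, 0), "zero")
})

test_that("events are assigned to the maximally-overlapping region", {
    segs <- regionSegments(TranscriptModelList(list(plusModel())))
    mk <- function(s, e) data.frame(
        gene_id = "gP", node_id = 1L, chrom = "chrT", start = s, end = e,
        strand = "+", event_type = "CE", psi_a = 1, psi_b = 0,
        delta_psi = 1, probability = 1, n_a = 1L, n_b = 1L, comparison = "x")
    ## fully inside the CDS segment of exon 2
    expect_identical(regionAssign(mk(210L, 290L), segs)$region, "CDS")
    ## 40 bp FIVE_UTR vs 60 bp CDS in exon 1
    expect_identical(regionAssign(mk(11L, 110L), segs)$region, "CDS")
    ## 50/50 split CDS vs THREE_UTR in exon 3 -> documented tie-break
    expect_identical(regionAssign(mk(401L, 500L), segs)$region, "CDS")
    ## a node overlapping no exon is left unassigned
    expect_message(out <- regionAssign(mk(150L, 160L), segs), "unassigned")
    expect_true(is.na(out$region))
})

test_that("region deviation matches arithmetic and sums to zero weighted", {
    em <- buildExpectationModel(TranscriptModelList(list(plusModel())))
    ## proportions are 0.2 / 0.6 / 0.2
    res <- suppressWarnings(regionDeviationTest(rep("CDS", 10), em))
    expect_equal(res$deviations$deviation,
                 c(-1, (10 - 6) / 6, -1), tolerance = 1e-12)
    ## observed exactly proportional -> all deviations zero, omnibus p = 1
    prop <- c(rep("FIVE_UTR", 2), rep("CDS", 6), rep("THREE_UTR", 2))
    res2 <- suppressWarnings(regionDeviationTest(prop, em))
    expect_equal(res2$deviations$deviation, c(0, 0, 0))
    expect_equal(res2$omnibus$p, 1)
    ## expectation-weighted deviations always sum to zero
    set.seed(4)
    for (i in 1:10) {
        regions <- sample(c("FIVE_UTR", "CDS", "THREE_UTR"), 50,
                          replace = TRUE, prob = runif(3))
        r <- suppressWarnings(regionDeviationTest(regions, em))
        w <- regionProportions(em)
        expect_equal(sum(w * r$deviations$deviation), 0, tolerance = 1e-12)
    }
})

test_that("an injected 50% 3'UTR depletion is recovered", {
    em <- buildExpectationModel(TranscriptModelList(list(plusModel())))
    p <- regionProportions(em)
    ## sample events so the 3'UTR arrives at half its expected share, the
    ## other regions absorbing the difference proportionally
    k <- (1 - 0.5 * p[["THREE_UTR"]]) /
        (p[["FIVE_UTR"]] + p[["CDS"]])
    probs <- c(p[["FIVE_UTR"]] * k, p[["CDS"]] * k,
               0.5 * p[["THREE_UTR"]])
    set.seed(19)
    regions <- sample(c("FIVE_UTR", "CDS", "THREE_UTR"), 8000,
                      replace = TRUE, prob = probs)
    res <- regionDeviationTest(regions, em)
    dev3 <- res$deviations$deviation[res$deviations$region == "THREE_UTR"]
    expect_equal(dev3, -0.5, tolerance = 0.07)
    expect_lt(res$deviations$p[res$deviations$region == "THREE_UTR"], 0.05)
})

test_that("rank-sum exact mode equals permutation brute force", {
    bruteForce <- function(x, y) {
        ## independent oracle: loop over every labeling, recomputing ranks
        v <- c(x, y); N <- length(v); nx <- length(x)
        obs <- sum(rank(v)[seq_len(nx)]) - nx * (N + 1) / 2
        combos <- utils::combn(N, nx)
        cnt <- 0L
        for (j in seq_len(ncol(combos))) {
            w <- sum(rank(v)[combos[, j]]) - nx * (N + 1) / 2
            if (abs(w) >= abs(obs) - 1e-9) cnt <- cnt + 1L
        }
        cnt / ncol(combos)
    }
    expect_equal(exonLengthTest(c(10, 12, 14), c(100, 120, 140))$p,
                 bruteForce(c(10, 12, 14), c(100, 120, 140)))
    set.seed(12)
    for (i in 1:8) {
        x <- sample(50:200, sample(3:8, 1), replace = TRUE)
        y <- sample(50:250, sample(3:8, 1), replace = TRUE)
        expect_equal(exonLengthTest(x, y)$p, bruteForce(x, y))
    }
    ## identical samples -> two-sided p of 1
    expect_equal(exonLengthTest(c(5, 6, 7), c(5, 6, 7))$p, 1)
    expect_error(exonLengthTest(5, c(1, 2)), "at least 2")
})

test_that("rank-sum p-values are roughly uniform under the null", {
    set.seed(77)
    ref <- rlnorm(300, log(150), 0.5)
    ps <- replicate(60, {
        exonLengthTest(sample(ref, 25), ref)$p
    })
    expect_gt(mean(ps), 0.3)
    expect_lt(mean(ps), 0.7)
    expect_lt(mean(ps < 0.05), 0.2)
})

test_that("psi distributions respect the discounted central band", {
    ev <- eventsFixture(list("pituitary:CvS:M" = c(CE = 30)))
    ev$delta_psi <- c(runif(15, 0.2, 0.9), runif(15, -0.9, -0.2))
    ev$psi_a <- runif(30); ev$psi_b <- runif(30)
    h <- psiDistribution(ev, bins = 20)
    expect_equal(attr(h, "excluded_band"), c(-0.1, 0.1))
    central <- h$metric == "delta_psi" & h$bin_lo >= -0.1 & h$bin_hi <= 0.1
    expect_identical(sum(h$count[central]), 0L)
    expect_identical(sum(h$count[h$metric == "delta_psi"]), 30L)
    ## a single event lands in exactly one bin
    h1 <- psiDistribution(ev[1, ], bins = 10)
    expect_identical(sum(h1$count[h1$metric == "delta_psi"] > 0), 1L)
    ## a constructed bimodal mixture reads back
    ev$delta_psi <- rep(c(0.55, -0.55), each = 15)
    h2 <- psiDistribution(ev, bins = 20)
    d <- h2[h2$metric == "delta_psi", ]
    expect_identical(d$count[d$bin_lo <= 0.55 & d$bin_hi > 0.55], 15L)
    expect_identical(d$count[d$bin_lo <= -0.55 & d$bin_hi > -0.55], 15L)
})

test_that("exclusive isoforms are flagged only for on/off patterns", {
    design <- data.frame(
        treatment = rep(c("control", "stress"), each = 4),
        sex = "M", tissue = "gonad",
        row.names = sprintf("s%d", 1:8))
    tpm <- rbind(
        onoff = c(rep(0, 4), rep(5, 4)),
        everywhere = rep(8, 8),
        nearmiss = c(rep(0.5, 4), rep(5, 4)))  # complement not silent
    colnames(tpm) <- rownames(design)
    flags <- exclusiveIsoforms(tpm, design)
    expect_identical(flags$isoform, "onoff")
    expect_identical(flags$group, "stress")
    ## shared expression -> no flags
    none <- exclusiveIsoforms(tpm["everywhere", , drop = FALSE], design)
    expect_identical(nrow(none), 0L)
    ## null simulation: log-normal shared abundances never flag
    set.seed(3)
    nullTpm <- matrix(rlnorm(50 * 8, log(10), 1), nrow = 50,
                      dimnames = list(sprintf("i%02d", 1:50), rownames(design)))
    expect_identical(nrow(exclusiveIsoforms(nullTpm, design)), 0L)
})
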