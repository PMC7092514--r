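writePsiTsv <- function(df, path = tempfile(fileext = ".tsv")) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

samplePsiDf <- function(psi = c("0.5", "0.7", "0.9")) {
    data.frame(Gene = c("g1", "g1", "g2"), Node = c(1L, 2L, 1L),
               Coord = c("chr1:100-150", "chr1:300-350", "chr2:10-90"),
               Strand = "+", Type = c("CE", "RI", "CE"),
               Psi = psi, CI_Width = "0.10000")
}

test_that("readPsiTable joins per-sample files with the design", {
    paths <- c(s1 = writePsiTsv(samplePsiDf()),
               s2 = writePsiTsv(samplePsiDf(c("0.1", "NA", "0.3"))))
    design <- data.frame(sample_id = c("s1", "s2"), sex = c("M", "F"),
                         treatment = "control", tissue = "hypothalamus")
    pt <- readPsiTable(paths, design)
    expect_s4_class(pt, "PsiTable")
    expect_identical(dim(pt), c(3L, 2L))          # 3 nodes x 2 samples
    expect_identical(sum(!is.na(psiAssay(pt))), 5L)
    ## "NA" psi kept as missing measurement, record retained
    expect_true(is.na(psiAssay(pt)["g1:2", "s2"]))
    expect_identical(psiAssay(pt)["g2:1", "s2"], 0.3)
    rd <- SummarizedExperiment::rowData(pt)
    expect_identical(rd["g1:1", "start"], 100L)
    expect_identical(rd["g1:1", "event_type"], "CE")
})

test_that("readPsiTable rejects bad types, coords and unknown samples", {
    bad <- samplePsiDf(); bad$Type[2] <- "XX"
    expect_error(
        readPsiTable(c(s1 = writePsiTsv(bad)),
                     data.frame(sample_id = "s1", sex = "M",
                                treatment = "control", tissue = "gonad")),
        "XX")
    malformed <- samplePsiDf(); malformed$Coord[2] <- "chr1:100"
    expect_error(
        readPsiTable(c(s1 = writePsiTsv(malformed)),
                     data.frame(sample_id = "s1", sex = "M",
                                treatment = "control", tissue = "gonad")),
        "line 3")
    expect_error(
        readPsiTable(c(ghost = writePsiTsv(samplePsiDf())),
                     data.frame(sample_id = "s1", sex = "M",
                                treatment = "control", tissue = "gonad")),
        "ghost")
})

test_that("deltaPsi honours the sign and zero conventions", {
    design <- twoGroupDesign(3, 3)
    psi <- rbind(c(1, 1, 1, 0, 0, 0),
                 c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
    pt <- psiTableFrom(psi, design)
    ev <- deltaPsi(pt, mvfComparison(), nBoot = 200, seed = 1)
    expect_equal(ev$delta_psi, c(1, 0))
    expect_equal(ev$probability, c(1, 0.5))
    expect_identical(ev$n_a, c(3L, 3L))
})

test_that("bootstrap probability matches exhaustive enumeration on 3-vs-3", {
    enumProb <- function(a, b) {
        ## all 3^3 x 3^3 equally likely index draws
        meansOf <- function(v) {
            idx <- expand.grid(1:3, 1:3, 1:3)
            (v[idx[, 1]] + v[idx[, 2]] + v[idx[, 3]]) / 3
        }
        d <- sign(mean(a) - mean(b))
        dd <- outer(meansOf(a), meansOf(b), "-")
        (sum(sign(dd) == d) + 0.5 * sum(dd == 0)) / length(dd)
    }
    cases <- list(
        list(a = c(0.8, 0.7, 0.9), b = c(0.4, 0.5, 0.3)),
        list(a = c(0.60, 0.40, 0.55), b = c(0.50, 0.45, 0.35)),
        list(a = c(0.2, 0.8, 0.5), b = c(0.6, 0.4, 0.45)))
    design <- twoGroupDesign(3, 3)
    for (cs in cases) {
        pt <- psiTableFrom(matrix(c(cs$a, cs$b), nrow = 1), design)
        ev <- deltaPsi(pt, mvfComparison(), nBoot = 20000, seed = 42)
        expect_equal(ev$probability, enumProb(cs$a, cs$b), tolerance = 0.011)
    }
})

test_that("deltaPsi is deterministic under a fixed seed and antisymmetric", {
    set.seed(5)
    design <- twoGroupDesign(6, 6)
    psi <- matrix(runif(20 * 12), nrow = 20)
    pt <- psiTableFrom(psi, design)
    cmp <- mvfComparison()
    swapped <- Comparison("swap", cmp@groupB, cmp@groupA)
    e1 <- deltaPsi(pt, cmp, nBoot = 4000, seed = 9)
    e2 <- deltaPsi(pt, cmp, nBoot = 4000, seed = 9)
    expect_identical(e1$probability, e2$probability)
    e3 <- deltaPsi(pt, swapped, nBoot = 4000, seed = 9)
    expect_equal(e3$delta_psi, -e1$delta_psi)
    ## probability is invariant up to Monte-Carlo error
    expect_equal(e3$probability, e1$probability, tolerance = 0.05)
})

test_that("nodes unquantified in a whole group are skipped with a warning", {
    design <- twoGroupDesign(2, 2)
    psi <- rbind(c(0.4, 0.6, NA, NA), c(0.2, 0.4, 0.5, 0.6))
    pt <- psiTableFrom(psi, design)
    expect_warning(ev <- deltaPsi(pt, mvfComparison(), nBoot = 100, seed = 1),
                   "skipped")
    expect_identical(nrow(ev), 1L)
})

test_that("posterior method gives high probability for separated groups", {
    design <- twoGroupDesign(4, 4)
    psi <- matrix(c(0.85, 0.9, 0.8, 0.88, 0.2, 0.15, 0.25, 0.18), nrow = 1)
    pt <- psiTableFrom(psi, design)
    ev <- deltaPsi(pt, mvfComparison(), nBoot = 2000, seed = 3,
                   method = "posterior")
    expect_gt(ev$probability, 0.99)
    expect_equal(ev$delta_psi, mean(psi[1:4]) - mean(psi[5:8]))
})

test_that("significance filter uses strict probability and inclusive delta", {
    ev <- data.frame(gene_id = "g", node_id = 1:4, chrom = "c",
                     start = 1L, end = 2L, strand = "+", event_type = "CE",
                     psi_a = 0.5, psi_b = 0.4,
                     delta_psi = c(0.5, 0.1, 0.1, 0.09),
                     probability = c(0.95, 0.96, 0.95, 0.99),
                     n_a = 3L, n_b = 3L, comparison = "x")
    sig <- callSignificant(ev)
    ## probability exactly 0.95 excluded; |dPSI| exactly 0.1 included
    expect_identical(sig$node_id, 2L)
    expect_identical(nrow(callSignificant(ev[0, ])), 0L)
    ## negative deltas pass on absolute value
    ev$delta_psi <- -ev$delta_psi
    expect_identical(callSignificant(ev)$node_id, 2L)
})

test_that("sensitivity recall returns only the additional low-effect events", {
    ev <- data.frame(gene_id = "g", node_id = 1:3, chrom = "c",
                     start = 1L, end = 2L, strand = "+", event_type = "CE",
                     psi_a = 0.5, psi_b = 0.45,
                     delta_psi = c(0.5, 0.05, 0.05),
                     probability = c(0.99, 0.97, 0.90),
                     n_a = 3L, n_b = 3L, comparison = "x")
    extra <- sensitivityRecall(ev)
    expect_identical(extra$node_id, 2L)
    expect_identical(nrow(sensitivityRecall(ev[ev$delta_psi >= 0.1, ])), 0L)
    ## a constructed cohort of 60 low-effect high-probability nodes
    cohort <- ev[rep(2, 60), ]
    cohort$node_id <- 1:60
    expect_identical(nrow(sensitivityRecall(cohort)), 60L)
})

test_that("diff tables survive a write/read round trip", {
    design <- twoGroupDesign(3, 3)
    psi <- matrix(runif(3 * 6, 0.2, 0.8), nrow = 3)
    pt <- psiTableFrom(psi, design)
    ev <- deltaPsi(pt, mvfComparison(), nBoot = 500, seed = 2)
    out <- tempfile(fileext = ".tsv")
    expect_identical(writeDiffTable(ev, out), 3L)
    back <- readDiffTable(out)
    expect_identical(back$gene_id, ev$gene_id)
    ## stored at 5 decimals: absolute error bounded by half an ulp
    expect_true(all(abs(back$delta_psi - ev$delta_psi) <= 5e-6 + 1e-12))
    expect_true(all(abs(back$probability - ev$probability) <= 5e-6 + 1e-12))
    ## empty table -> header only
    writeDiffTable(ev[0, ], out)
    expect_identical(length(readLines(out)), 1L)
})

test_that("null nodes rarely pass and strong effects are recovered (reduced)", {
    ## reduced-size calibration/power check; the full-size study-condition
    ## version runs in the acceptance suite
    set.seed(31)
    design <- twoGroupDesign(12, 12)
    kappa <- 24
    nullPsi <- t(vapply(rep(0.5, 200), function(m)
        rbeta(24, m * kappa, (1 - m) * kappa), numeric(24)))
    ptNull <- psiTableFrom(nullPsi, design)
    evNull <- deltaPsi(ptNull, mvfComparison(), nBoot = 2000, seed = 7)
    expect_lt(nrow(callSignificant(evNull)) / nrow(evNull), 0.02)

    effPsi <- t(vapply(seq_len(100), function(i)
        c(rnorm(12, 0.65, 0.1), rnorm(12, 0.35, 0.1)), numeric(24)))
    effPsi <- pmin(pmax(effPsi, 0), 1)
    ptEff <- psiTableFrom(effPsi, design)
    evEff <- deltaPsi(ptEff, mvfComparison(), nBoot = 2000, seed = 8)
    expect_gte(nrow(callSignificant(evEff)) / nrow(evEff), 0.9)
    expect_lt(abs(mean(evEff$delta_psi) - 0.3), 0.03)
})
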