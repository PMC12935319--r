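test_that("cohort summary reproduces hand-computed statistics", {
    res <- psiResultsFor(c(1.0, 0.9, 0.8))
    s <- summarizeCohort(res, cohortID = "toy")
    expect_equal(s@medianPsi, 0.9)
    expect_equal(s@propNearComplete, 2 / 3)
    expect_equal(s@nTotal, 3L)
    expect_equal(s@nPassingDepth, 3L)
    expect_equal(s@minPsi, 0.8)
    expect_equal(s@propMeasurableSkipping, 2 / 3)  # the two psi < 1 samples
    # quartiles use linear interpolation between order statistics (type 7)
    expect_equal(c(s@q1, s@q3), c(0.85, 0.95))
})

test_that("a degenerate all-inclusion cohort summarizes cleanly", {
    s <- summarizeCohort(psiResultsFor(rep(1.0, 8)))
    expect_equal(s@medianPsi, 1.0)
    expect_equal(c(s@q1, s@q3), c(1.0, 1.0))
    expect_equal(s@propMeasurableSkipping, 0)
    expect_equal(s@propNearComplete, 1)
})

test_that("summary is permutation-invariant and proportions complement", {
    set.seed(5)
    psis <- runif(40, 0.5, 1)
    res <- psiResultsFor(psis, depth = 200L)
    a <- summarizeCohort(res)
    b <- summarizeCohort(res[sample(length(res))])
    expect_equal(asDataFrame(a)[-1], asDataFrame(b)[-1])
    cls <- vapply(res, classification, character(1))
    expect_equal(a@propNearComplete +
                     mean(cls == "reduced_inclusion"), 1)
})

test_that("depth-failing samples are excluded and empty cohorts error", {
    tri <- data.frame(sample_id = c("lo1", "lo2", "hi"),
                      j12 = c(5, 3, 90), j13 = c(1, 0, 10),
                      j23 = c(4, 2, 20))
    tab <- computePsiTable(tri)
    s <- summarizeCohort(tab, cohortID = "mix")
    expect_equal(s@nTotal, 3L)
    expect_equal(s@nPassingDepth, 1L)
    expect_equal(s@medianPsi, 110 / 120)
    # measurable skipping over all samples vs passing samples
    sAll <- summarizeCohort(tab, cohortID = "mix", denominator = "all")
    expect_equal(sAll@propMeasurableSkipping, 2 / 3)
    expect_equal(s@propMeasurableSkipping, 1)
    expect_error(summarizeCohort(computePsiTable(tri[1:2, ])),
                 "empty cohort")
})

test_that("junctionReport is descriptive: counts, rank, no PSI column", {
    tri <- data.frame(sample_id = c("w", "x", "y", "z"),
                      j12 = c(3, 8, 12, 7), j13 = c(21, 13, 1, 0),
                      j23 = c(5, 7, 10, 6))
    rep <- junctionReport(tri)
    expect_identical(rep$sample_id, tri$sample_id)  # input order kept
    expect_equal(rep$skipping_rank, c(1L, 2L, 3L, 4L))
    expect_equal(rep$depth, c(29L, 28L, 23L, 13L))
    expect_false(rep$psi_eligible[1])
    expect_false("psi" %in% names(rep))
    # high-depth samples are flagged PSI-eligible
    deep <- junctionReport(data.frame(sample_id = "d", j12 = 500,
                                      j13 = 10, j23 = 490))
    expect_true(deep$psi_eligible)
    # empty input gives an empty table with the same columns
    empty <- junctionReport(tri[0, ])
    expect_equal(nrow(empty), 0L)
    expect_true(all(c("depth", "psi_eligible", "skipping_rank") %in%
                        names(empty)))
})

test_that("PSI histogram bins are left-closed and sum to passing samples", {
    tri <- data.frame(sample_id = sprintf("s%d", 1:5),
                      j12 = c(100, 90, 89, 50, 5),
                      j13 = c(0, 10, 11, 50, 1),
                      j23 = c(0, 0, 0, 0, 4))
    tab <- computePsiTable(tri)      # psi: 1.0, .9, .89, .5, NA
    h <- plotPsiHistogram(tab, threshold = 0.9)
    expect_equal(sum(h$bins$count), 4L)          # NA sample excluded
    expect_true(100 %in% h$bins$bin_left)        # psi = 1 in [100, 101)
    expect_true(90 %in% h$bins$bin_left)         # psi = .9 on the left edge
    # the dashed threshold line sits at 90 on the percentage axis
    built <- ggplot2::ggplot_build(h$plot)
    vl <- built$data[[2]]
    expect_equal(unique(vl$xintercept), 90)
})

test_that("multi-cohort histograms carry a cohort column per panel", {
    tab <- rbind(
        cbind(computePsiTable(data.frame(sample_id = "a1", j12 = 100,
                                         j13 = 0, j23 = 0)), cohort = "A"),
        cbind(computePsiTable(data.frame(sample_id = "b1", j12 = 80,
                                         j13 = 20, j23 = 0)), cohort = "B"))
    h <- plotPsiHistogram(tab)
    expect_setequal(unique(h$bins$cohort), c("A", "B"))
    expect_equal(sum(h$bins$count), 2L)
    expect_error(plotPsiHistogram(computePsiTable(
        data.frame(sample_id = "x", j12 = 1, j13 = 1, j23 = 1))),
        "no depth-passing")
})

test_that("sashimi arcs echo the junction counts and flag skipping", {
    ev <- deriveCassetteEvent(toyGeneModel(), 2)
    cfg <- simConfig(plantedTriple = c(15, 5, 14), coveragePerBase = 3,
                     seed = 9)
    sim <- simulateSplicedReads(cfg, dir = tempfile())
    jc <- extractJunctions(sim$sam)
    p <- plotSashimi(jc, ev, alignmentPath = sim$sam)
    arcs <- attr(p, "arcs")
    expect_equal(arcs$count[match(c("inclusion_upstream", "skipping",
                                    "inclusion_downstream"), arcs$role)],
                 c(15L, 5L, 14L))
    expect_true(arcs$skipping[arcs$role == "skipping"])
    expect_s3_class(ggplot2::ggplot_build(p)$plot, "ggplot")
})

test_that("sashimi degrades to counts-only mode and validates the window", {
    ev <- deriveCassetteEvent(toyGeneModel(), 2)
    expect_message(p <- plotSashimi(junctionTriple(15, 5, 14), ev),
                   "coverage track omitted")
    expect_equal(sum(attr(p, "arcs")$count), 34L)
    # zero-count skipping junction draws no skipping arc
    p0 <- suppressMessages(plotSashimi(junctionTriple(15, 0, 14), ev))
    arcs0 <- attr(p0, "arcs")
    expect_equal(arcs0$count[arcs0$role == "skipping"], 0L)
    built <- ggplot2::ggplot_build(p0)
    labs <- built$data[[length(built$data)]]
    expect_equal(sort(labs$label), c(14, 15))    # only inclusion labels
    expect_error(suppressMessages(
        plotSashimi(junctionTriple(1, 1, 1), ev, window = "ctg1:600-900")),
        "window does not cover")
})
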