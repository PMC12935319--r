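test_that("expected PSI follows the closed form and inverts exactly", {
    expect_equal(expectedPsi(0), 1.0)
    expect_equal(expectedPsi(1), 0.0)
    expect_equal(expectedPsi(0.5), 2 / 3)
    expect_error(expectedPsi(-0.1), "\\[0, 1\\]")
    expect_error(expectedPsi(1.1), "\\[0, 1\\]")
    # strictly decreasing bijection, self-inverse round-trip
    s <- seq(0, 1, by = 0.01)
    p <- expectedPsi(s)
    expect_true(all(diff(p) < 0))
    expect_equal(skipFractionFromPsi(p), s, tolerance = 1e-12)
    expect_equal(expectedPsi(skipFractionFromPsi(s)), s, tolerance = 1e-12)
})

test_that("multinomial triples honour degenerate skip fractions", {
    for (seed in 1:5) {
        t0 <- simulateJunctionTriple(0, 100, seed = seed)
        expect_equal(tripleCounts(t0)[["j13"]], 0L)
        expect_equal(junctionDepth(t0), 100L)
        t1 <- simulateJunctionTriple(1, 40, seed = seed)
        expect_equal(unname(tripleCounts(t1)), c(0L, 40L, 0L))
    }
    # at a million reads the estimate sits within multinomial error of 2/3
    tBig <- simulateJunctionTriple(0.5, 1e6, seed = 3)
    p <- psi(computePsi(tBig))
    expect_lt(abs(p - 2 / 3), 0.003)
    expect_equal(junctionDepth(simulateJunctionTriple(0.2, 0)), 0L)
})

test_that("unequal junction efficiencies shift the multinomial as specified", {
    # doubling the skipping-junction efficiency at s = 0.5 gives
    # probabilities (1, 2, 1)/4
    t <- simulateJunctionTriple(0.5, 2e5, efficiency = c(1, 2, 1), seed = 8)
    expect_lt(abs(tripleCounts(t)[["j13"]] / 2e5 - 0.5), 0.005)
})

test_that("spliced-read simulation is byte-identical for a fixed seed", {
    cfg <- simConfig(skipFraction = 0.3, junctionDepth = 80,
                     coveragePerBase = 2, noiseRate = 0.05, seed = 17)
    a <- simulateSplicedReads(cfg, dir = tempfile())
    b <- simulateSplicedReads(cfg, dir = tempfile())
    expect_identical(readLines(a$sam), readLines(b$sam))
    expect_identical(readLines(a$fasta), readLines(b$fasta))
    # a different seed produces different reads
    c <- simulateSplicedReads(simConfig(skipFraction = 0.3,
                                        junctionDepth = 80,
                                        coveragePerBase = 2,
                                        noiseRate = 0.05, seed = 18),
                              dir = tempfile())
    expect_false(identical(readLines(a$sam), readLines(c$sam)))
})

test_that("planted junction counts round-trip through extraction", {
    cfg <- simConfig(plantedTriple = c(15, 5, 14), seed = 2)
    sim <- simulateSplicedReads(cfg, dir = tempfile())
    ev <- sim$event
    tr <- matchEvent(extractJunctions(sim$sam), ev)
    expect_equal(unname(tripleCounts(tr)), c(15L, 5L, 14L))
    # zero-noise zero-skip sample recovers exactly s = 0 evidence
    sim0 <- simulateSplicedReads(simConfig(skipFraction = 0,
                                           junctionDepth = 50, seed = 4),
                                 dir = tempfile())
    tr0 <- matchEvent(extractJunctions(sim0$sam), ev)
    expect_equal(tripleCounts(tr0)[["j13"]], 0L)
    expect_equal(junctionDepth(tr0), 50L)
})

test_that("spurious junctions surface in diagnostics, not the event triple", {
    cfg <- simConfig(plantedTriple = c(20, 6, 18), noiseRate = 0.2,
                     junctionDepth = 100, seed = 31)
    sim <- simulateSplicedReads(cfg, dir = tempfile())
    jc <- extractJunctions(sim$sam,
                           config = extractionConfig(minOverhang = 1))
    expect_equal(unname(tripleCounts(matchEvent(jc, sim$event))),
                 c(20L, 6L, 18L))
    expect_gt(length(junctions(jc)), 3L)   # extra non-event junctions exist
})

test_that("simulate-extract-match-compute equals PSI of the planted triple", {
    for (s in c(0, 0.25, 0.8)) {
        tr <- simulateJunctionTriple(s, 400, seed = 50 + s * 100)
        cfg <- simConfig(plantedTriple = tripleCounts(tr), seed = 60)
        sim <- simulateSplicedReads(cfg, dir = tempfile())
        direct <- computePsi(tr)
        viaSam <- computePsi(matchEvent(extractJunctions(sim$sam),
                                        sim$event))
        expect_equal(psi(viaSam), psi(direct))
        expect_identical(classification(viaSam), classification(direct))
    }
})

test_that("cohort simulation is deterministic and honours point masses", {
    spec <- cohortSimSpec("null", 100,
                          sDistribution = list(type = "point", value = 0),
                          depthDistribution = list(type = "point",
                                                   value = 100),
                          seed = 7)
    sim <- simulateCohort(spec)
    expect_equal(nrow(sim$triples), 100L)
    expect_true(all(sim$triples$j13 == 0L))
    s <- summarizeCohort(computePsiTable(sim$triples), cohortID = "null")
    expect_equal(s@medianPsi, 1.0)
    expect_equal(s@propMeasurableSkipping, 0)
    # identical spec and seed, identical output
    expect_identical(simulateCohort(spec), sim)
    # ground truth is consistent with the closed form
    expect_equal(sim$truth$expected_psi, expectedPsi(sim$truth$s))
})

test_that("cohort presets encode the study group sizes and shapes", {
    sizes <- c(ball_like = 75L, dlbcl_like = 553L, blood_like = 1048L,
               spleen_like = 255L)
    for (nm in names(sizes)) {
        spec <- cohortPreset(nm, seed = 1)
        expect_equal(spec@nSamples, sizes[[nm]])
        med <- configuredMedianPsi(spec)
        expect_gt(med, 0.85); expect_lt(med, 1)
    }
    # heterogeneous lymphoma cohort sits well below the tight cohorts
    expect_lt(configuredMedianPsi(cohortPreset("dlbcl_like")),
              configuredMedianPsi(cohortPreset("ball_like")) - 0.03)
})

test_that("the CAR-T case series plants the reported skipping counts", {
    dir <- tempfile()
    cart <- simulateCartCohort(dir = dir, seed = 12)
    expect_equal(cart$samples$j13, c(21L, 13L, 1L, 0L))
    expect_identical(cart$samples$patient, c("R1", "NR", "R2", "CR"))
    expect_true(all(file.exists(cart$samples$sam)))
    # every sample sits below the default depth filter: descriptive only
    expect_true(all(cart$samples$j12 + cart$samples$j13 +
                        cart$samples$j23 < 30))
})

test_that("mean PSI over seeds recovers the expected value at high depth", {
    # moderate-scale parameter recovery; the acceptance suite runs the
    # full grid
    for (s in c(0.1, 0.5)) {
        D <- 1e4
        ps <- vapply(1:30, function(seed)
            psi(computePsi(simulateJunctionTriple(s, D, seed = seed))),
            numeric(1))
        pTrue <- expectedPsi(s)
        se <- sqrt(pTrue * (1 - pTrue) / D / 30)
        expect_lt(abs(mean(ps) - pTrue), 3 * se + 1e-9)
    }
})
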