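# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

#' A small synthetic cassette-exon gene for simulation and examples
#'
#' Four 300-bp exons separated by 300-bp introns on a single ~2.6-kb contig,
#' mirroring the exon 1-4 neighbourhood of a cassette-exon gene at toy
#' scale. Exon 2 is the default skipping target.
#'
#' @param chrom contig name.
#' @param strand \code{"+"} or \code{"-"}.
#' @return an [ExonModel-class].
#' @export
toyGeneModel <- function(chrom = "ctg1", strand = "+") {
    exonModel("TOY1", "TOY1.t1", chrom, strand,
              starts = c(201L, 801L, 1401L, 2001L),
              ends = c(500L, 1100L, 1700L, 2300L))
}

#' Expected PSI implied by a latent skipping fraction
#'
#' Under equal junction detection efficiency, each inclusion transcript
#' contributes two inclusion junctions (upstream and downstream of the
#' target exon) while each skipping transcript contributes one skipping
#' junction, so a fraction s of skipping transcripts yields
#' \deqn{PSI = 2(1 - s) / (2 - s).}
#' The map is a strictly decreasing bijection of [0, 1] onto itself and is
#' its own inverse: [skipFractionFromPsi()] applies the same formula.
#'
#' @param s skipping fraction(s) in [0, 1].
#' @return expected PSI value(s) in [0, 1].
#' @examples
#' expectedPsi(c(0, 0.5, 1))   # 1, 2/3, 0
#' @export
expectedPsi <- function(s) {
    if (any(is.na(s)) || any(s < 0 | s > 1))
        stop("skipping fraction must lie in [0, 1]")
    2 * (1 - s) / (2 - s)
}

#' @rdname expectedPsi
#' @param psi expected PSI value(s) in [0, 1].
#' @export
skipFractionFromPsi <- function(psi) {
    if (any(is.na(psi)) || any(psi < 0 | psi > 1))
        stop("PSI must lie in [0, 1]")
    2 * (1 - psi) / (2 - psi)
}

#' @rdname SimConfig-class
#' @param model,targetExon,skipFraction,junctionDepth,readLength,coveragePerBase,minAnchor,noiseRate,efficiency,plantedTriple,seed
#'   see slot documentation.
#' @export
simConfig <- function(model = toyGeneModel(), targetExon = 2L,
                      skipFraction = 0.1, junctionDepth = 100L,
                      readLength = 60L, coveragePerBase = 0,
                      minAnchor = 8L, noiseRate = 0,
                      efficiency = c(1, 1, 1), plantedTriple = NULL,
                      seed = 1L) {
    if (!is.null(plantedTriple)) plantedTriple <- as.integer(plantedTriple)
    new("SimConfig", model = model, targetExon = as.integer(targetExon),
        skipFraction = skipFraction,
        junctionDepth = as.integer(junctionDepth),
        readLength = as.integer(readLength),
        coveragePerBase = coveragePerBase, minAnchor = as.integer(minAnchor),
        noiseRate = noiseRate, efficiency = efficiency,
        plantedTriple = plantedTriple, seed = as.integer(seed))
}

# junction class probabilities given skipping fraction and per-junction
# detection efficiencies (upstream-inclusion, skipping, downstream-inclusion)
.junctionProbs <- function(s, efficiency = c(1, 1, 1)) {
    w <- c((1 - s) * efficiency[1L], s * efficiency[2L],
           (1 - s) * efficiency[3L])
    if (sum(w) == 0) return(c(0, 0, 0))
    w / sum(w)
}

#' Draw a junction read triple from the generative model
#'
#' Draws (j12, j13, j23) from a multinomial with \code{depth} trials and
#' class probabilities proportional to ((1-s) e1, s e2, (1-s) e3): each
#' inclusion transcript offers two junction classes, each skipping
#' transcript one, scaled by the per-junction detection efficiencies.
#'
#' @param s latent skipping fraction in [0, 1].
#' @param depth total junction reads to draw.
#' @param efficiency per-junction relative efficiencies; the default
#'   c(1, 1, 1) matches the assumption implicit in summing raw counts.
#' @param seed optional seed for a deterministic draw.
#' @return a [JunctionTriple-class].
#' @examples
#' simulateJunctionTriple(0.5, 1000, seed = 7)
#' @export
simulateJunctionTriple <- function(s, depth, efficiency = c(1, 1, 1),
                                   seed = NULL) {
    if (s < 0 || s > 1) stop("skipping fraction must lie in [0, 1]")
    draw <- function() {
        if (depth == 0L) return(junctionTriple(0L, 0L, 0L))
        k <- stats::rmultinom(1L, depth, .junctionProbs(s, efficiency))
        junctionTriple(k[1L], k[2L], k[3L])
    }
    if (is.null(seed)) draw() else .withSeed(seed, draw())
}

# --- spliced-read simulation -----------------------------------------------

.writeFasta <- function(name, seq, path) {
    lines <- c(paste0(">", name),
               substring(seq, seq(1L, nchar(seq), 60L),
                         pmin(seq(60L, nchar(seq) + 59L, 60L), nchar(seq))))
    writeLines(lines, path)
    invisible(path)
}

#' Simulate spliced reads for one sample as a SAM file plus toy reference
#'
#' Emits a coordinate-sorted SAM of pre-aligned reads over the model's
#' contig, together with a FASTA of the synthetic reference the positions
#' refer to. Junction-spanning reads have CIGARs of the form
#' \code{aM gN bM} with the splice placed uniformly over offsets leaving at
#' least \code{minAnchor} aligned bases on each side; they follow the
#' inclusion path (upstream or downstream junction) or the skipping path in
#' the proportions implied by the skipping fraction, or exactly match
#' \code{plantedTriple} when given. Optional plain exonic reads build a
#' coverage track, and optional spurious junction reads with random
#' incorrect splice boundaries model extraction noise. Output is
#' byte-identical for a given seed. No sequencing-error, quality or
#' fragment-length modelling is attempted: reads are emitted pre-aligned.
#'
#' @param config a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return list with \code{sam}, \code{fasta}, the planted/drawn
#'   \code{triple}, the [CassetteEvent-class] and the contig name.
#' @export
simulateSplicedReads <- function(config, dir = tempdir(),
                                 prefix = "simulated") {
    stopifnot(is(config, "SimConfig"))
    model <- config@model
    ex <- exons(model)
    event <- deriveCassetteEvent(model, config@targetExon)
    chrom <- as.character(seqnames(ex))[1L]
    contigLen <- max(GenomicRanges::end(ex)) + 300L
    rl <- config@readLength
    anchorMax <- rl - config@minAnchor
    if (anchorMax < config@minAnchor)
        stop("read length too short for the anchor requirement")
    if (rl - config@minAnchor > min(width(ex)))
        stop("exon too short for read placement: reduce readLength")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)

    .withSeed(config@seed, {
        ref <- paste(sample(c("A", "C", "G", "T"), contigLen, replace = TRUE),
                     collapse = "")
        triple <- if (!is.null(config@plantedTriple)) {
            config@plantedTriple
        } else if (config@junctionDepth == 0L) {
            c(0L, 0L, 0L)
        } else {
            as.integer(stats::rmultinom(
                1L, config@junctionDepth,
                .junctionProbs(config@skipFraction, config@efficiency)))
        }
        ev <- junctionBounds(event)          # 0-based half-open introns
        jstart <- ev$intron_start + 1L       # 1-based first intronic base
        jend <- ev$intron_end                # 1-based last intronic base

        pos <- integer(); cig <- character()
        for (k in 1:3) {
            nk <- triple[k]
            if (nk == 0L) next
            a <- sample(seq.int(config@minAnchor, anchorMax), nk,
                        replace = TRUE)
            g <- jend[k] - jstart[k] + 1L
            pos <- c(pos, jstart[k] - a)
            cig <- c(cig, sprintf("%dM%dN%dM", a, g, rl - a))
        }
        # exonic (non-junction) coverage reads
        if (config@coveragePerBase > 0) {
            nCov <- as.integer(round(config@coveragePerBase *
                                     sum(width(ex)) / rl))
            if (nCov > 0L) {
                slots <- width(ex) - rl + 1L
                exPick <- sample(seq_along(ex), nCov, replace = TRUE,
                                 prob = slots / sum(slots))
                start <- GenomicRanges::start(ex)[exPick] +
                    vapply(slots[exPick], function(m)
                        sample.int(m, 1L) - 1L, integer(1))
                pos <- c(pos, start)
                cig <- c(cig, rep(sprintf("%dM", rl), nCov))
            }
        }
        # spurious junctions with random incorrect boundaries
        nNoise <- if (config@noiseRate > 0)
            stats::rbinom(1L, config@junctionDepth,
                          min(1, config@noiseRate)) else 0L
        if (nNoise > 0L) {
            lo <- min(GenomicRanges::start(ex)) + rl
            hi <- max(GenomicRanges::end(ex)) - rl - 350L
            for (i in seq_len(nNoise)) {
                repeat {
                    is <- sample(lo:hi, 1L)
                    g <- sample(50:300, 1L)
                    if (!any(is == jstart & (is + g - 1L) == jend)) break
                }
                a <- sample(seq.int(config@minAnchor, anchorMax), 1L)
                pos <- c(pos, is - a)
                cig <- c(cig, sprintf("%dM%dN%dM", a, g, rl - a))
            }
        }
        ord <- order(pos, cig)
        pos <- pos[ord]; cig <- cig[ord]
        seqs <- vapply(seq_along(pos), function(i) {
            cg <- .cigarOps(cig[i]); refpos <- pos[i]; out <- character()
            for (k in seq_along(cg$op)) {
                if (cg$op[k] == "M") {
                    out <- c(out, substr(ref, refpos, refpos + cg$len[k] - 1L))
                    refpos <- refpos + cg$len[k]
                } else refpos <- refpos + cg$len[k]
            }
            paste(out, collapse = "")
        }, character(1))
        recs <- paste(sprintf("read_%05d", seq_along(pos)), 0L, chrom, pos,
                      60L, cig, "*", 0L, 0L, seqs,
                      strrep("I", nchar(seqs)), sep = "\t")
        samPath <- file.path(dir, paste0(prefix, ".sam"))
        faPath <- file.path(dir, paste0(prefix, ".fa"))
        writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                     sprintf("@SQ\tSN:%s\tLN:%d", chrom, contigLen), recs),
                   samPath)
        .writeFasta(chrom, ref, faPath)
        list(sam = samPath, fasta = faPath,
             triple = junctionTriple(triple[1L], triple[2L], triple[3L]),
             event = event, chrom = chrom)
    })
}

# --- cohort simulation -----------------------------------------------------

#' @rdname CohortSimSpec-class
#' @param cohortID,nSamples,sDistribution,zeroInflation,depthDistribution,seed
#'   see slot documentation.
#' @export
cohortSimSpec <- function(cohortID, nSamples,
                          sDistribution = list(type = "point", value = 0),
                          zeroInflation = 0,
                          depthDistribution = list(type = "point",
                                                   value = 100),
                          seed = 1L) {
    new("CohortSimSpec", cohortID = as.character(cohortID),
        nSamples = as.integer(nSamples), sDistribution = sDistribution,
        zeroInflation = zeroInflation,
        depthDistribution = depthDistribution, seed = as.integer(seed))
}

#' Simulate a cohort of junction triples with known ground truth
#'
#' Per-sample latent skipping fractions and junction depths are drawn as
#' the spec describes (zero-inflated point mass or Beta for s; point mass
#' or negative binomial for depth), then each sample's triple is drawn with
#' [simulateJunctionTriple()]. Fully deterministic given the spec's seed.
#'
#' @param spec a [CohortSimSpec-class].
#' @return list with \code{triples} (\code{sample_id, cohort, j12, j13,
#'   j23}) and \code{truth} (\code{sample_id, s, depth, expected_psi}).
#' @export
simulateCohort <- function(spec) {
    stopifnot(is(spec, "CohortSimSpec"))
    .withSeed(spec@seed, {
        n <- spec@nSamples
        sd <- spec@sDistribution
        s <- switch(sd$type,
                    point = rep(sd$value, n),
                    beta = stats::rbeta(n, sd$shape1, sd$shape2))
        if (spec@zeroInflation > 0)
            s[stats::runif(n) < spec@zeroInflation] <- 0
        dd <- spec@depthDistribution
        depth <- switch(dd$type,
                        point = rep(as.integer(dd$value), n),
                        nbinom = stats::rnbinom(n, mu = dd$mu,
                                                size = dd$size))
        tri <- matrix(0L, nrow = n, ncol = 3L)
        for (i in seq_len(n)) {
            if (depth[i] > 0L)
                tri[i, ] <- as.integer(stats::rmultinom(
                    1L, depth[i], .junctionProbs(s[i])))
        }
        ids <- sprintf("%s_s%04d", spec@cohortID, seq_len(n))
        list(triples = data.frame(sample_id = ids, cohort = spec@cohortID,
                                  j12 = tri[, 1L], j13 = tri[, 2L],
                                  j23 = tri[, 3L],
                                  stringsAsFactors = FALSE),
             truth = data.frame(sample_id = ids, s = s, depth = depth,
                                expected_psi = expectedPsi(s),
                                stringsAsFactors = FALSE))
    })
}

# Frozen generative parameters emulating the study cohorts. The Beta shapes
# and zero-inflation weights were calibrated once so the expected-PSI
# distribution reproduces each cohort's reported median, quartiles and
# (approximately) its >=90%-inclusion proportion; depth distributions are
# near-Poisson for the homogeneous cohorts and overdispersed for the
# heterogeneous lymphoma cohort.
.presetParams <- list(
    ball_like = list(n = 75L, shape1 = 6.9538, shape2 = 73.1834,
                     w0 = 0.2442, mu = 400, size = 4),
    dlbcl_like = list(n = 553L, shape1 = 2.0673, shape2 = 8.8155,
                      w0 = 0.1091, mu = 150, size = 1.2),
    blood_like = list(n = 1048L, shape1 = 2.4886, shape2 = 31.2387,
                      w0 = 0.1056, mu = 250, size = 3),
    spleen_like = list(n = 255L, shape1 = 1.6415, shape2 = 27.0103,
                       w0 = 0.0551, mu = 300, size = 3))

#' Cohort presets emulating the study's tissue and disease groups
#'
#' \code{ball_like}, \code{blood_like} and \code{spleen_like} are tight,
#' high-inclusion cohorts (B-cell acute lymphoblastic leukemia, healthy
#' whole blood, healthy spleen); \code{dlbcl_like} is the heterogeneous
#' diffuse large B-cell lymphoma cohort with a broader, lower PSI
#' distribution. Sample sizes match the emulated cohorts (75, 1048, 255 and
#' 553). Each preset draws the latent skipping fraction from a
#' zero-inflated Beta whose parameters are fixed by a one-off calibration
#' to the cohort's PSI median, quartiles and near-complete-inclusion
#' proportion; [configuredMedianPsi()] returns the median the calibration
#' encodes, which is the oracle simulated cohorts are checked against.
#'
#' @param name preset name.
#' @param seed RNG seed for the resulting spec.
#' @return a [CohortSimSpec-class].
#' @examples
#' sim <- simulateCohort(cohortPreset("dlbcl_like", seed = 1))
#' head(sim$triples)
#' @export
cohortPreset <- function(name = c("ball_like", "dlbcl_like", "blood_like",
                                  "spleen_like"), seed = 1L) {
    name <- match.arg(name)
    p <- .presetParams[[name]]
    cohortSimSpec(name, p$n,
                  sDistribution = list(type = "beta", shape1 = p$shape1,
                                       shape2 = p$shape2),
                  zeroInflation = p$w0,
                  depthDistribution = list(type = "nbinom", mu = p$mu,
                                           size = p$size),
                  seed = seed)
}

#' Median expected PSI encoded by a cohort spec
#'
#' The median of the latent expected-PSI distribution the spec draws from
#' (before junction-count sampling noise): the quantity a simulated
#' cohort's observed median estimates.
#'
#' @param spec a [CohortSimSpec-class].
#' @return the configured median PSI (fraction).
#' @export
configuredMedianPsi <- function(spec) {
    w <- spec@zeroInflation
    sd <- spec@sDistribution
    if (w >= 0.5) return(1.0)
    sMed <- switch(sd$type,
                   point = sd$value,
                   beta = stats::qbeta(1 - 0.5 / (1 - w), sd$shape1,
                                       sd$shape2))
    expectedPsi(sMed)
}

#' Simulate the four-patient CAR-T-treated case series
#'
#' Plants the skipping-junction read counts observed in the motivating
#' four-patient series (21, 13, 1 and 0 reads for the rapid-relapse
#' patient, the non-responder, the slow-relapse patient and the complete
#' responder) together with low inclusion-junction depth, writes one
#' pre-treatment SAM per patient over the toy reference, and carries the
#' clinical response labels as metadata. All samples sit below the default
#' 30-read depth filter, so the intended analysis surface is the
#' descriptive [junctionReport()], not PSI. The inclusion-junction counts
#' are synthetic: only the skipping counts and response labels follow the
#' emulated series.
#'
#' @param dir output directory for the SAM/FASTA files.
#' @param seed RNG seed.
#' @return list with \code{samples} (metadata and file paths), the
#'   [CassetteEvent-class] and the [ExonModel-class] used.
#' @export
simulateCartCohort <- function(dir = tempdir(), seed = 1L) {
    model <- toyGeneModel()
    plan <- data.frame(
        sample_id = c("rapid_relapse", "non_responder", "slow_relapse",
                      "complete_responder"),
        patient = c("R1", "NR", "R2", "CR"),
        responder = c(TRUE, FALSE, TRUE, TRUE),
        relapse_months = c(1.5, NA, 13, NA),
        j12 = c(3L, 8L, 12L, 7L),
        j13 = c(21L, 13L, 1L, 0L),
        j23 = c(5L, 7L, 10L, 6L),
        stringsAsFactors = FALSE)
    paths <- vapply(seq_len(nrow(plan)), function(i) {
        cfg <- simConfig(model = model, targetExon = 2L,
                         plantedTriple = c(plan$j12[i], plan$j13[i],
                                           plan$j23[i]),
                         coveragePerBase = 2, seed = seed + i)
        simulateSplicedReads(cfg, dir = dir,
                             prefix = plan$sample_id[i])$sam
    }, character(1))
    plan$sam <- paths
    list(samples = plan, event = deriveCassetteEvent(model, 2L),
         model = model)
}
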