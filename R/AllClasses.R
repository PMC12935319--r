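#' @import methods
#' @importFrom GenomicRanges GRanges start end strand seqnames width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' ExonModel: the ordered exon structure of one transcript
#'
#' Holds the exon intervals of a single transcript of one gene, numbered in
#' transcription order (exon 1 is the 5'-most exon of the mRNA, so on the
#' minus strand it has the largest genomic coordinates). Exon coordinates are
#' 1-based inclusive genomic intervals, as in GTF.
#'
#' @slot geneID gene identifier the model was built from.
#' @slot transcriptID transcript whose exon set defines exon numbering.
#' @slot exons a \link[GenomicRanges]{GRanges} of exons in transcription
#'   order, with an \code{exon_rank} metadata column.
#'
#' @seealso [loadGeneModel()], [deriveCassetteEvent()]
#' @export
setClass("ExonModel",
    representation(geneID = "character", transcriptID = "character",
                   exons = "GRanges"))

setValidity("ExonModel", function(object) {
    ex <- object@exons
    msg <- character()
    if (length(ex) < 1L)
        msg <- c(msg, "model must contain at least one exon")
    if (length(unique(as.character(seqnames(ex)))) > 1L)
        msg <- c(msg, "all exons must lie on one chromosome")
    st <- unique(as.character(strand(ex)))
    if (length(st) != 1L || !st %in% c("+", "-"))
        msg <- c(msg, "exons must share a single explicit strand (+ or -)")
    if (length(ex) > 1L) {
        s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
        ord <- if (identical(st, "-")) all(diff(s) < 0) else all(diff(s) > 0)
        if (!isTRUE(ord))
            msg <- c(msg, "exons must be sorted in transcription order")
        gs <- sort(s)
        ge <- sort(e)
        if (any(gs[-1L] <= ge[-length(ge)]))
            msg <- c(msg, "exons must not overlap")
    }
    if (any(GenomicRanges::start(ex) > GenomicRanges::end(ex)))
        msg <- c(msg, "each exon must have start <= end")
    if (length(msg)) msg else TRUE
})

#' CassetteEvent: the three junctions defining a cassette-exon skipping event
#'
#' For a target exon t with flanking exons t-1 and t+1, the event consists of
#' the upstream inclusion junction (t-1 -> t), the skipping junction
#' (t-1 -> t+1) and the downstream inclusion junction (t -> t+1). Junctions
#' are stored as the genomic interval of the excised intron, 1-based
#' inclusive; use [junctionBounds()] for the 0-based half-open convention
#' used by BED and most junction tables.
#'
#' @slot targetExon 1-based exon number of the cassette exon (2 for the
#'   CD19 exon 2 event).
#' @slot geneID,transcriptID provenance of the exon numbering.
#' @slot junctions a \link[GenomicRanges]{GRanges} of length 3 named
#'   \code{inclusion_upstream}, \code{skipping}, \code{inclusion_downstream}.
#'
#' @export
setClass("CassetteEvent",
    representation(targetExon = "integer", geneID = "character",
                   transcriptID = "character", junctions = "GRanges"))

setValidity("CassetteEvent", function(object) {
    j <- object@junctions
    msg <- character()
    if (length(j) != 3L ||
        !identical(names(j),
                   c("inclusion_upstream", "skipping", "inclusion_downstream")))
        msg <- c(msg, paste("junctions must be named inclusion_upstream,",
                            "skipping, inclusion_downstream"))
    else {
        if (length(unique(as.character(seqnames(j)))) != 1L ||
            length(unique(as.character(strand(j)))) != 1L)
            msg <- c(msg, "junctions must share chromosome and strand")
        # the skipping intron must genomically contain both inclusion introns
        if (GenomicRanges::start(j["skipping"]) >
                GenomicRanges::start(j["inclusion_upstream"]) ||
            GenomicRanges::end(j["skipping"]) <
                GenomicRanges::end(j["inclusion_downstream"]))
            msg <- c(msg, "skipping junction must span both inclusion junctions")
    }
    if (length(msg)) msg else TRUE
})

#' JunctionCounts: observed junction read support for one sample
#'
#' Maps splice junctions (genomic intron intervals) to read counts, as
#' obtained from split-read extraction ([extractJunctions()]) or from
#' precomputed junction tables ([readStarJunctions()], [readJunctionBed()]).
#'
#' @slot sampleID sample identifier.
#' @slot provenance one of \code{"bam_extraction"}, \code{"star_sj_tab"},
#'   \code{"bed_table"}.
#' @slot junctions a \link[GenomicRanges]{GRanges} with a non-negative
#'   integer \code{count} metadata column; junction coordinates are the
#'   1-based inclusive intron interval.
#'
#' @export
setClass("JunctionCounts",
    representation(sampleID = "character", provenance = "character",
                   junctions = "GRanges"))

setValidity("JunctionCounts", function(object) {
    msg <- character()
    if (!object@provenance %in% c("bam_extraction", "star_sj_tab", "bed_table"))
        msg <- c(msg, "unknown provenance")
    cnt <- mcols(object@junctions)$count
    if (length(object@junctions) && is.null(cnt))
        msg <- c(msg, "junctions must carry a 'count' metadata column")
    if (!is.null(cnt) && any(cnt < 0))
        msg <- c(msg, "counts must be non-negative")
    if (anyDuplicated(paste(seqnames(object@junctions),
                            GenomicRanges::start(object@junctions),
                            GenomicRanges::end(object@junctions),
                            strand(object@junctions))))
        msg <- c(msg, "junction keys must be unique")
    if (length(msg)) msg else TRUE
})

#' JunctionTriple: the three counts feeding the PSI statistic
#'
#' Read counts for the upstream inclusion junction (\code{j12}), the skipping
#' junction (\code{j13}) and the downstream inclusion junction (\code{j23}).
#' Field names follow the CD19 exon numbering of the motivating event
#' (exon 1-2, exon 1-3, exon 2-3) but apply to any cassette exon.
#'
#' @slot j12,j13,j23 non-negative integer read counts.
#' @export
setClass("JunctionTriple",
    representation(j12 = "integer", j13 = "integer", j23 = "integer"))

setValidity("JunctionTriple", function(object) {
    v <- c(object@j12, object@j13, object@j23)
    if (length(v) != 3L || anyNA(v)) return("all three counts required")
    if (any(v < 0L)) return("counts must be non-negative")
    TRUE
})

#' ExtractionConfig: filters applied during split-read junction extraction
#'
#' @slot minOverhang minimum aligned (M/=/X) reference bases required on each
#'   side of a splice for a read to support that junction. Default 6.
#' @slot minMapq minimum mapping quality; MAPQ 255 ("unavailable") passes.
#'   Default 10.
#' @slot countDuplicates,countSecondary include flagged duplicate /
#'   secondary-or-supplementary alignments. Default \code{FALSE}: each
#'   fragment's primary evidence is counted once. Note that both mates of a
#'   properly paired fragment spanning the same junction count as 2
#'   (read-level counting, matching usual junction-table semantics).
#' @slot stranded compare strand when matching junctions to an event.
#'   Default \code{FALSE} (library strandedness often unknown).
#' @export
setClass("ExtractionConfig",
    representation(minOverhang = "integer", minMapq = "integer",
                   countDuplicates = "logical", countSecondary = "logical",
                   stranded = "logical"),
    prototype(minOverhang = 6L, minMapq = 10L, countDuplicates = FALSE,
              countSecondary = FALSE, stranded = FALSE))

setValidity("ExtractionConfig", function(object) {
    if (object@minOverhang < 1L) return("minOverhang must be >= 1")
    if (object@minMapq < 0L) return("minMapq must be >= 0")
    TRUE
})

#' AnalysisConfig: PSI depth filter, classification threshold and variant
#'
#' @slot minJunctionDepth minimum total junction reads (j12 + j13 + j23)
#'   required before PSI is computed; samples below it are classified
#'   \code{insufficient_depth}. Default 30.
#' @slot inclusionThreshold PSI at or above which a sample is classified
#'   \code{near_complete_inclusion}; inclusive comparison. Default 0.90.
#' @slot psiVariant \code{"canonical"} for the three-count ratio
#'   (j12 + j23) / (j12 + j13 + j23), the canonical definition here;
#'   \code{"standard"} for the MISO-style average-inclusion form
#'   ((j12 + j23)/2) / ((j12 + j23)/2 + j13), offered for sensitivity
#'   analysis.
#' @export
setClass("AnalysisConfig",
    representation(minJunctionDepth = "integer", inclusionThreshold = "numeric",
                   psiVariant = "character"),
    prototype(minJunctionDepth = 30L, inclusionThreshold = 0.90,
              psiVariant = "canonical"))

setValidity("AnalysisConfig", function(object) {
    if (object@minJunctionDepth < 0L) return("minJunctionDepth must be >= 0")
    if (object@inclusionThreshold <= 0 || object@inclusionThreshold > 1)
        return("inclusionThreshold must be in (0, 1]")
    if (!object@psiVariant %in% c("canonical", "standard"))
        return("psiVariant must be 'canonical' or 'standard'")
    TRUE
})

#' PsiResult: PSI value, depth-filter status and classification for one sample
#'
#' @slot sampleID sample identifier.
#' @slot triple the [JunctionTriple-class] of observed counts.
#' @slot depth total junction reads, j12 + j13 + j23.
#' @slot psi exon-inclusion fraction in [0, 1]; \code{NA} when the depth
#'   filter fails (the denominator is unstable at near-zero depth).
#' @slot passedDepthFilter whether depth met the configured minimum.
#' @slot measurableSkipping whether any skipping-junction read was observed
#'   (j13 >= 1); computed regardless of the depth filter.
#' @slot classification \code{near_complete_inclusion},
#'   \code{reduced_inclusion} or \code{insufficient_depth}.
#' @export
setClass("PsiResult",
    representation(sampleID = "character", triple = "JunctionTriple",
                   depth = "integer", psi = "numeric",
                   passedDepthFilter = "logical",
                   measurableSkipping = "logical",
                   classification = "character"))

setValidity("PsiResult", function(object) {
    msg <- character()
    if (!object@classification %in%
            c("near_complete_inclusion", "reduced_inclusion",
              "insufficient_depth"))
        msg <- c(msg, "unknown classification")
    if (!is.na(object@psi) && (object@psi < 0 || object@psi > 1))
        msg <- c(msg, "psi must lie in [0, 1]")
    if (is.na(object@psi) != !object@passedDepthFilter ||
        is.na(object@psi) != (object@classification == "insufficient_depth"))
        msg <- c(msg, "psi must be defined iff the depth filter passed")
    if (length(msg)) msg else TRUE
})

#' CohortSummary: descriptive statistics of PSI over one cohort
#'
#' Median, quartiles and threshold proportions are computed over
#' depth-passing samples (optionally over all samples, see
#' [summarizeCohort()]).
#'
#' @slot cohortID cohort label.
#' @slot nTotal,nPassingDepth sample counts before/after the depth filter.
#' @slot medianPsi,q1,q3,minPsi PSI order statistics (fractions).
#' @slot propNearComplete fraction of samples with PSI at or above the
#'   inclusion threshold.
#' @slot propMeasurableSkipping fraction of samples with at least one
#'   skipping-junction read.
#' @slot denominator \code{"passing"} or \code{"all"}: which samples the
#'   proportions are computed over.
#' @export
setClass("CohortSummary",
    representation(cohortID = "character", nTotal = "integer",
                   nPassingDepth = "integer", medianPsi = "numeric",
                   q1 = "numeric", q3 = "numeric",
                   propNearComplete = "numeric",
                   propMeasurableSkipping = "numeric",
                   minPsi = "numeric", denominator = "character"))

setValidity("CohortSummary", function(object) {
    msg <- character()
    if (object@nPassingDepth > object@nTotal)
        msg <- c(msg, "nPassingDepth cannot exceed nTotal")
    qs <- c(object@q1, object@medianPsi, object@q3)
    if (!anyNA(qs) && (is.unsorted(qs) || any(qs < 0) || any(qs > 1)))
        msg <- c(msg, "quartiles must satisfy 0 <= q1 <= median <= q3 <= 1")
    pr <- c(object@propNearComplete, object@propMeasurableSkipping)
    if (!anyNA(pr) && (any(pr < 0) || any(pr > 1)))
        msg <- c(msg, "proportions must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the spliced-read simulator for one sample
#'
#' @slot model the [ExonModel-class] reads are simulated from.
#' @slot targetExon 1-based index of the cassette exon.
#' @slot skipFraction latent fraction s of transcripts lacking the target
#'   exon (the quantity PSI proxies; PSI relates to it as
#'   2(1-s)/(2-s) under equal junction efficiency).
#' @slot junctionDepth expected total junction-spanning reads at the event.
#' @slot readLength simulated read length in bases.
#' @slot coveragePerBase expected exonic coverage for non-junction reads
#'   (builds the coverage track; 0 disables).
#' @slot minAnchor minimum aligned bases placed on each side of a simulated
#'   splice (keep at or above the extraction minOverhang so planted reads
#'   survive filtering).
#' @slot noiseRate expected spurious-junction reads per true junction read;
#'   spurious reads get random incorrect splice boundaries.
#' @slot efficiency relative detection efficiency of the three event
#'   junctions (upstream-inclusion, skipping, downstream-inclusion); the
#'   default c(1, 1, 1) is the equal-efficiency assumption implicit in
#'   summing raw counts.
#' @slot plantedTriple optional exact counts (j12, j13, j23) to plant instead
#'   of drawing from the multinomial.
#' @slot seed RNG seed for byte-identical reproduction.
#' @export
setClass("SimConfig",
    representation(model = "ExonModel", targetExon = "integer",
                   skipFraction = "numeric", junctionDepth = "integer",
                   readLength = "integer", coveragePerBase = "numeric",
                   minAnchor = "integer", noiseRate = "numeric",
                   efficiency = "numeric", plantedTriple = "integerOrNULL",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@skipFraction < 0 || object@skipFraction > 1)
        msg <- c(msg, "skipFraction must lie in [0, 1]")
    if (object@junctionDepth < 0L) msg <- c(msg, "junctionDepth must be >= 0")
    if (object@readLength < 2L * object@minAnchor)
        msg <- c(msg, "readLength must be >= 2 * minAnchor")
    if (object@noiseRate < 0) msg <- c(msg, "noiseRate must be >= 0")
    if (length(object@efficiency) != 3L || any(object@efficiency <= 0))
        msg <- c(msg, "efficiency must be three positive values")
    if (!is.null(object@plantedTriple) &&
        (length(object@plantedTriple) != 3L || any(object@plantedTriple < 0L)))
        msg <- c(msg, "plantedTriple must be three non-negative counts")
    if (length(msg)) msg else TRUE
})

#' CohortSimSpec: generative description of a simulated cohort
#'
#' Per-sample latent skipping fractions are drawn from a zero-inflated
#' distribution: with probability \code{zeroInflation} the sample has s = 0
#' (no skipping transcript at all), otherwise s follows the configured
#' distribution. Per-sample junction depth follows a point mass or a
#' negative binomial.
#'
#' @slot cohortID cohort label.
#' @slot nSamples number of samples.
#' @slot sDistribution list: \code{type = "point"} with \code{value}, or
#'   \code{type = "beta"} with \code{shape1}, \code{shape2}.
#' @slot zeroInflation probability that a sample carries no skipping
#'   transcript (s = 0).
#' @slot depthDistribution list: \code{type = "point"} with \code{value}, or
#'   \code{type = "nbinom"} with \code{mu}, \code{size}.
#' @slot seed RNG seed.
#' @export
setClass("CohortSimSpec",
    representation(cohortID = "character", nSamples = "integer",
                   sDistribution = "list", zeroInflation = "numeric",
                   depthDistribution = "list", seed = "integer"))

setValidity("CohortSimSpec", function(object) {
    msg <- character()
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (object@zeroInflation < 0 || object@zeroInflation > 1)
        msg <- c(msg, "zeroInflation must lie in [0, 1]")
    sd <- object@sDistribution
    if (is.null(sd$type) || !sd$type %in% c("point", "beta"))
        msg <- c(msg, "sDistribution$type must be 'point' or 'beta'")
    else if (sd$type == "point" &&
             (is.null(sd$value) || sd$value < 0 || sd$value > 1))
        msg <- c(msg, "point-mass s must lie in [0, 1]")
    else if (sd$type == "beta" &&
             (is.null(sd$shape1) || is.null(sd$shape2) ||
              sd$shape1 <= 0 || sd$shape2 <= 0))
        msg <- c(msg, "beta s-distribution needs positive shape1, shape2")
    dd <- object@depthDistribution
    if (is.null(dd$type) || !dd$type %in% c("point", "nbinom"))
        msg <- c(msg, "depthDistribution$type must be 'point' or 'nbinom'")
    else if (dd$type == "point" && (is.null(dd$value) || dd$value < 0))
        msg <- c(msg, "point-mass depth must be >= 0")
    else if (dd$type == "nbinom" &&
             (is.null(dd$mu) || is.null(dd$size) || dd$mu < 0 || dd$size <= 0))
        msg <- c(msg, "nbinom depth needs mu >= 0 and size > 0")
    if (length(msg)) msg else TRUE
})
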