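#' @rdname ExonModel-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("geneID", function(x) standardGeneric("geneID"))

#' @rdname ExonModel-class
#' @export
setGeneric("transcriptID", function(x) standardGeneric("transcriptID"))

#' @rdname ExonModel-class
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname CassetteEvent-class
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' Junction coordinates in the 0-based half-open convention
#'
#' Junctions are stored internally as 1-based inclusive intron intervals
#' (the \pkg{GenomicRanges} convention); this accessor converts to the
#' 0-based half-open \code{[intron_start, intron_end)} convention used by
#' BED-like junction tables: \code{intron_start = start - 1},
#' \code{intron_end = end}.
#'
#' @param x a [CassetteEvent-class] or [JunctionCounts-class].
#' @return a \code{data.frame} with columns \code{chrom}, \code{intron_start},
#'   \code{intron_end}, \code{strand} (and \code{role} or \code{count}).
#' @export
setGeneric("junctionBounds", function(x) standardGeneric("junctionBounds"))

#' @rdname JunctionCounts-class
#' @param x a \code{JunctionCounts}.
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))

#' @rdname JunctionCounts-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Total junction depth of a triple or result
#'
#' @param x a [JunctionTriple-class] or [PsiResult-class].
#' @return integer, j12 + j13 + j23.
#' @export
setGeneric("junctionDepth", function(x) standardGeneric("junctionDepth"))

#' @rdname PsiResult-class
#' @param x a \code{PsiResult}.
#' @export
setGeneric("psi", function(x) standardGeneric("psi"))

#' @rdname PsiResult-class
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' Match a cassette event against observed junction counts
#'
#' @param counts a [JunctionCounts-class].
#' @param event a [CassetteEvent-class].
#' @param ... passed to methods; see [matchEvent,JunctionCounts,CassetteEvent-method].
#' @return a [JunctionTriple-class].
#' @export
setGeneric("matchEvent", function(counts, event, ...)
    standardGeneric("matchEvent"))

#' Compute PSI for one sample
#'
#' @param x a [JunctionTriple-class] (or three raw counts via the numeric
#'   method).
#' @param config an [AnalysisConfig-class].
#' @param ... passed to methods.
#' @return a [PsiResult-class].
#' @export
setGeneric("computePsi", function(x, config = analysisConfig(), ...)
    standardGeneric("computePsi"))

#' Summarize PSI results over a cohort
#'
#' @param x a list of [PsiResult-class] objects or a per-sample PSI table
#'   from [computePsiTable()].
#' @param config an [AnalysisConfig-class].
#' @param ... passed to methods.
#' @return a [CohortSummary-class].
#' @export
setGeneric("summarizeCohort", function(x, config = analysisConfig(), ...)
    standardGeneric("summarizeCohort"))
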