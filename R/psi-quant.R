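#' @rdname AnalysisConfig-class
#' @param minJunctionDepth,inclusionThreshold,psiVariant see slot
#'   documentation.
#' @export
analysisConfig <- function(minJunctionDepth = 30L, inclusionThreshold = 0.90,
                           psiVariant = c("canonical", "standard")) {
    new("AnalysisConfig", minJunctionDepth = as.integer(minJunctionDepth),
        inclusionThreshold = inclusionThreshold,
        psiVariant = match.arg(psiVariant))
}

#' @rdname PsiResult-class
#' @export
setMethod("psi", "PsiResult", function(x) x@psi)

#' @rdname PsiResult-class
#' @export
setMethod("classification", "PsiResult", function(x) x@classification)

#' @rdname PsiResult-class
#' @export
setMethod("junctionDepth", "PsiResult", function(x) x@depth)

#' @rdname PsiResult-class
#' @export
setMethod("sampleID", "PsiResult", function(x) x@sampleID)

setMethod("show", "PsiResult", function(object) {
    cat(sprintf("PsiResult '%s': depth %d, ", object@sampleID, object@depth))
    if (is.na(object@psi))
        cat("PSI undefined (insufficient depth)")
    else
        cat(sprintf("PSI %.1f%%, %s", 100 * object@psi,
                    object@classification))
    cat(sprintf(", measurable skipping: %s\n", object@measurableSkipping))
})

#' Compute the exon-inclusion PSI statistic for one sample
#'
#' The default \code{"canonical"} definition is the three-count ratio
#' \deqn{PSI = (j_{12} + j_{23}) / (j_{12} + j_{13} + j_{23}),}
#' so a lower PSI reflects increased skipping of the target exon. PSI is
#' computed only when the total junction depth reaches
#' \code{minJunctionDepth} (default 30 reads): below that, the denominator
#' is unstable and the sample is classified \code{insufficient_depth} with
#' an undefined PSI. Whether any skipping read was observed (j13 >= 1) is
#' recorded regardless of the filter. The \code{"standard"} variant uses
#' the MISO-style average-inclusion form
#' ((j12 + j23)/2) / ((j12 + j23)/2 + j13), which weighs the single
#' skipping junction against the \emph{average} of the two inclusion
#' junctions and is therefore never larger than the canonical form.
#'
#' @param x a [JunctionTriple-class], or a numeric vector
#'   \code{c(j12, j13, j23)}.
#' @param config an [AnalysisConfig-class].
#' @param sampleID label stored in the result.
#' @param ... unused.
#' @return a [PsiResult-class].
#' @examples
#' computePsi(junctionTriple(50, 10, 40))   # PSI = 90/100 = 0.90
#' computePsi(junctionTriple(10, 5, 10))    # depth 25 < 30: undefined
#' @export
setMethod("computePsi", "JunctionTriple",
          function(x, config = analysisConfig(), sampleID = "sample", ...) {
    depth <- junctionDepth(x)
    inclusion <- x@j12 + x@j23
    passed <- depth >= config@minJunctionDepth && depth > 0L
    if (passed) {
        p <- if (config@psiVariant == "canonical") {
            inclusion / depth
        } else {
            (inclusion / 2) / (inclusion / 2 + x@j13)
        }
        cls <- if (p >= config@inclusionThreshold) "near_complete_inclusion"
               else "reduced_inclusion"
    } else {
        p <- NA_real_
        cls <- "insufficient_depth"
    }
    new("PsiResult", sampleID = as.character(sampleID), triple = x,
        depth = depth, psi = p, passedDepthFilter = passed,
        measurableSkipping = x@j13 >= 1L, classification = cls)
})

#' @rdname computePsi-JunctionTriple-method
#' @export
setMethod("computePsi", "numeric",
          function(x, config = analysisConfig(), sampleID = "sample", ...) {
    stopifnot(length(x) == 3L)
    if (any(x < 0)) stop("junction counts must be non-negative")
    computePsi(junctionTriple(x[1L], x[2L], x[3L]), config = config,
               sampleID = sampleID)
})

#' Wilson score interval for the inclusion proportion
#'
#' Treats the inclusion reads (j12 + j23) among all junction reads as a
#' binomial draw and returns the Wilson score interval — an uncertainty aid
#' around the PSI point estimate that behaves sensibly at the 0 and 1
#' boundaries and collapses to the point estimate as depth grows.
#'
#' @param triple a [JunctionTriple-class] with depth > 0.
#' @param confidence confidence level, default 0.95.
#' @return named numeric \code{c(low, high)}.
#' @examples
#' psiInterval(junctionTriple(30, 0, 0))  # lower bound ~0.886 at n = 30
#' @export
psiInterval <- function(triple, confidence = 0.95) {
    n <- junctionDepth(triple)
    if (n <= 0L) stop("undefined interval: junction depth is zero")
    k <- triple@j12 + triple@j23
    z <- stats::qnorm(1 - (1 - confidence) / 2)
    phat <- k / n
    denom <- 1 + z^2 / n
    centre <- (phat + z^2 / (2 * n)) / denom
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
    c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Classify a sample by its PSI against the inclusion threshold
#'
#' \code{near_complete_inclusion} when PSI is defined and at or above the
#' threshold (inclusive comparison, default 90 percent),
#' \code{reduced_inclusion} when defined and below it,
#' \code{insufficient_depth} otherwise.
#'
#' @param result a [PsiResult-class].
#' @param config an [AnalysisConfig-class].
#' @return character classification.
#' @export
classifySample <- function(result, config = analysisConfig()) {
    if (is.na(result@psi)) return("insufficient_depth")
    if (result@psi >= config@inclusionThreshold) "near_complete_inclusion"
    else "reduced_inclusion"
}

#' Per-sample PSI table for a set of junction triples
#'
#' Applies [computePsi()] and [psiInterval()] to every row of a triples
#' table. PSI percentages are rounded to one decimal in \code{psi_pct};
#' \code{psi} keeps full precision. Interval bounds are \code{NA} for
#' samples failing the depth filter.
#'
#' @param triples \code{data.frame} with columns \code{sample_id},
#'   \code{j12}, \code{j13}, \code{j23} and optionally \code{cohort}.
#' @param config an [AnalysisConfig-class].
#' @param confidence confidence level for the Wilson interval.
#' @return a \code{data.frame} with columns \code{sample_id} (and
#'   \code{cohort} if present), \code{j12}, \code{j13}, \code{j23},
#'   \code{depth}, \code{psi}, \code{psi_pct}, \code{ci_low},
#'   \code{ci_high}, \code{classification}, \code{measurable_skipping}.
#' @export
computePsiTable <- function(triples, config = analysisConfig(),
                            confidence = 0.95) {
    n <- nrow(triples)
    out <- data.frame(sample_id = as.character(triples$sample_id),
                      j12 = as.integer(triples$j12),
                      j13 = as.integer(triples$j13),
                      j23 = as.integer(triples$j23),
                      stringsAsFactors = FALSE)
    if (!is.null(triples$cohort)) out$cohort <- triples$cohort
    out$depth <- out$j12 + out$j13 + out$j23
    out$psi <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
    out$classification <- character(n)
    out$measurable_skipping <- logical(n)
    for (i in seq_len(n)) {
        tr <- junctionTriple(out$j12[i], out$j13[i], out$j23[i])
        r <- computePsi(tr, config = config, sampleID = out$sample_id[i])
        out$psi[i] <- r@psi
        out$classification[i] <- r@classification
        out$measurable_skipping[i] <- r@measurableSkipping
        if (!is.na(r@psi)) {
            ci <- psiInterval(tr, confidence)
            out$ci_low[i] <- ci[["low"]]
            out$ci_high[i] <- ci[["high"]]
        }
    }
    out$psi_pct <- round(100 * out$psi, 1L)
    ord <- c("sample_id", if (!is.null(out$cohort)) "cohort",
             "j12", "j13", "j23", "depth", "psi", "psi_pct",
             "ci_low", "ci_high", "classification", "measurable_skipping")
    out[, ord]
}
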