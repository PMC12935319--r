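#' @rdname CohortSummary-class
#' @param x a \code{CohortSummary}.
#' @export
asDataFrame <- function(x) {
    stopifnot(is(x, "CohortSummary"))
    data.frame(cohort = x@cohortID, n_total = x@nTotal,
               n_passing_depth = x@nPassingDepth,
               median_psi = x@medianPsi, q1 = x@q1, q3 = x@q3,
               prop_near_complete = x@propNearComplete,
               prop_measurable_skipping = x@propMeasurableSkipping,
               min_psi = x@minPsi, denominator = x@denominator,
               stringsAsFactors = FALSE)
}

setMethod("show", "CohortSummary", function(object) {
    cat(sprintf("CohortSummary '%s': %d/%d samples pass the depth filter\n",
                object@cohortID, object@nPassingDepth, object@nTotal))
    cat(sprintf("  median PSI %.1f%% (IQR %.1f-%.1f), min %.1f%%\n",
                100 * object@medianPsi, 100 * object@q1, 100 * object@q3,
                100 * object@minPsi))
    cat(sprintf("  near-complete inclusion: %.1f%%  measurable skipping: %.1f%% (of %s samples)\n",
                100 * object@propNearComplete,
                100 * object@propMeasurableSkipping, object@denominator))
})

.summarizeFromVectors <- function(cohortID, psiAll, j13All, passed, config,
                                  denominator) {
    nTotal <- length(psiAll)
    nPass <- sum(passed)
    if (nPass == 0L) stop("empty cohort after filtering")
    psiPass <- psiAll[passed]
    # quartiles with linear interpolation between order statistics (type 7)
    qs <- stats::quantile(psiPass, c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
    idx <- if (denominator == "passing") passed else rep(TRUE, nTotal)
    nDen <- sum(idx)
    propNC <- sum(passed & psiAll >= config@inclusionThreshold) / nDen
    propMS <- sum(idx & j13All >= 1L) / nDen
    new("CohortSummary", cohortID = as.character(cohortID),
        nTotal = nTotal, nPassingDepth = nPass,
        medianPsi = qs[2L], q1 = qs[1L], q3 = qs[3L],
        propNearComplete = propNC, propMeasurableSkipping = propMS,
        minPsi = min(psiPass), denominator = denominator)
}

#' Summarize PSI over a cohort
#'
#' Median, quartiles (linear interpolation between order statistics, the
#' usual "type 7" convention) and the minimum are computed over
#' depth-passing samples. The threshold proportions (near-complete
#' inclusion, measurable skipping) are computed over depth-passing samples
#' by default; \code{denominator = "all"} divides by the full cohort size
#' instead, since published summaries do not always state which denominator
#' they use.
#'
#' @param x a list of [PsiResult-class] objects, or a per-sample table from
#'   [computePsiTable()]; the table method summarizes one cohort (filter or
#'   split by its \code{cohort} column first for multi-cohort tables).
#' @param config the [AnalysisConfig-class] whose threshold defines
#'   near-complete inclusion.
#' @param cohortID cohort label for the summary.
#' @param denominator \code{"passing"} (default) or \code{"all"}.
#' @param ... unused.
#' @return a [CohortSummary-class].
#' @export
setMethod("summarizeCohort", "list",
          function(x, config = analysisConfig(), cohortID = "cohort",
                   denominator = c("passing", "all"), ...) {
    denominator <- match.arg(denominator)
    stopifnot(all(vapply(x, is, logical(1), "PsiResult")))
    psiAll <- vapply(x, function(r) r@psi, numeric(1))
    j13 <- vapply(x, function(r) r@triple@j13, integer(1))
    passed <- vapply(x, function(r) r@passedDepthFilter, logical(1))
    .summarizeFromVectors(cohortID, psiAll, j13, passed, config, denominator)
})

#' @rdname summarizeCohort-list-method
#' @export
setMethod("summarizeCohort", "data.frame",
          function(x, config = analysisConfig(), cohortID = NULL,
                   denominator = c("passing", "all"), ...) {
    denominator <- match.arg(denominator)
    if (is.null(cohortID))
        cohortID <- if (!is.null(x$cohort)) as.character(x$cohort[1L])
                    else "cohort"
    .summarizeFromVectors(cohortID, x$psi, x$j13,
                          x$classification != "insufficient_depth",
                          config, denominator)
})

#' Descriptive junction report for low-depth cohorts
#'
#' For cohorts whose junction coverage is too low for stable PSI estimation
#' (such as small post-treatment CAR-T series), the skipping-junction count
#' itself is the reported evidence. The table carries the raw counts, the
#' total depth, a PSI-eligibility flag and the rank of each sample by
#' skipping-read evidence — and deliberately no PSI column, since PSI is
#' unstable at near-zero depth.
#'
#' @param triples \code{data.frame} with columns \code{sample_id},
#'   \code{j12}, \code{j13}, \code{j23}; extra columns (response labels,
#'   metadata) are carried through.
#' @param config an [AnalysisConfig-class]; its depth filter defines
#'   eligibility.
#' @return a \code{data.frame} in input row order with added \code{depth},
#'   \code{psi_eligible} and \code{skipping_rank} columns (rank 1 = most
#'   skipping reads; ties share the minimum rank).
#' @export
junctionReport <- function(triples, config = analysisConfig()) {
    out <- as.data.frame(triples, stringsAsFactors = FALSE)
    if (nrow(out) == 0L) {
        out$depth <- integer(0); out$psi_eligible <- logical(0)
        out$skipping_rank <- integer(0)
        return(out)
    }
    out$depth <- out$j12 + out$j13 + out$j23
    out$psi_eligible <- out$depth >= config@minJunctionDepth & out$depth > 0L
    out$skipping_rank <- as.integer(rank(-out$j13, ties.method = "min"))
    out
}

#' PSI histogram with a threshold line, and its binned counts
#'
#' Draws one histogram panel per cohort on the percentage scale with a
#' dashed vertical line at the classification threshold. Bins are
#' left-closed \code{[b, b + width)} with a default width of one percentage
#' point, so a PSI of exactly 100 falls in the \code{[100, 101)} bin. The
#' binned counts are returned as a plain table so the figure content is
#' testable and exportable.
#'
#' @param psiTable per-sample table from [computePsiTable()]; only
#'   depth-passing samples are drawn. A \code{cohort} column splits panels.
#' @param threshold inclusion threshold as a fraction (drawn at
#'   \code{100 * threshold}).
#' @param binWidth bin width in percentage points.
#' @return a list with \code{plot} (a \pkg{ggplot2} object) and \code{bins}
#'   (\code{data.frame} with \code{cohort}, \code{bin_left},
#'   \code{bin_right}, \code{count}; counts per cohort sum to the number of
#'   depth-passing samples).
#' @export
plotPsiHistogram <- function(psiTable, threshold = 0.90, binWidth = 1) {
    df <- psiTable[!is.na(psiTable$psi), , drop = FALSE]
    if (nrow(df) == 0L) stop("no depth-passing samples to plot")
    if (is.null(df$cohort)) df$cohort <- "cohort"
    breaks <- seq(0, 100 + binWidth, by = binWidth)
    bins <- do.call(rbind, lapply(split(df, df$cohort), function(d) {
        cut_idx <- findInterval(100 * d$psi, breaks,
                                rightmost.closed = FALSE)
        tab <- table(factor(cut_idx, levels = seq_len(length(breaks) - 1L)))
        keep <- tab > 0
        data.frame(cohort = d$cohort[1L],
                   bin_left = breaks[-length(breaks)][keep],
                   bin_right = breaks[-1L][keep],
                   count = as.integer(tab[keep]),
                   stringsAsFactors = FALSE)
    }))
    rownames(bins) <- NULL
    p <- ggplot2::ggplot(bins) +
        ggplot2::geom_rect(ggplot2::aes(xmin = .data$bin_left,
                                        xmax = .data$bin_right,
                                        ymin = 0, ymax = .data$count),
                           fill = "grey35") +
        ggplot2::geom_vline(xintercept = 100 * threshold,
                            linetype = "dashed") +
        ggplot2::facet_wrap(~cohort, scales = "free_y") +
        ggplot2::labs(x = "PSI (%)", y = "Samples") +
        ggplot2::theme_bw()
    list(plot = p, bins = bins)
}

# per-base coverage over a window from the aligned (M/=/X) blocks of a
# SAM/BAM; shares the extraction read filters
.coverageTrack <- function(alignmentPath, chrom, from, to,
                           config = extractionConfig()) {
    aln <- .readAlignments(alignmentPath,
                           list(chrom = chrom, start = from, end = to))
    keep <- !is.na(aln$pos) & !bitwAnd(aln$flag, 0x4) & aln$rname == chrom
    aln <- aln[keep, , drop = FALSE]
    cov <- integer(to - from + 1L)
    for (i in seq_len(nrow(aln))) {
        cg <- .cigarOps(aln$cigar[i])
        refpos <- aln$pos[i]
        for (k in seq_along(cg$op)) {
            op <- cg$op[k]; len <- cg$len[k]
            if (op %in% c("M", "=", "X")) {
                a <- max(refpos, from); b <- min(refpos + len - 1L, to)
                if (a <= b)
                    cov[(a - from + 1L):(b - from + 1L)] <-
                        cov[(a - from + 1L):(b - from + 1L)] + 1L
                refpos <- refpos + len
            } else if (op %in% c("D", "N")) refpos <- refpos + len
        }
    }
    data.frame(pos = from:to, coverage = cov)
}

#' Sashimi-style junction-arc plot
#'
#' Draws the per-base coverage over the event window with one arc per event
#' junction, labelled by its read count; the skipping-junction arc is drawn
#' in a distinct colour below the axis so exon-skipping evidence stands out.
#' Zero-count junctions get no arc. When only counts (no alignment file)
#' are supplied, the coverage track is omitted with a message.
#'
#' @param x a [JunctionTriple-class] (counts-only mode) or a
#'   [JunctionCounts-class]; with \code{alignmentPath}, coverage is computed
#'   from the alignments.
#' @param event the [CassetteEvent-class] to display.
#' @param window optional \code{"chrom:start-end"} display window; must
#'   cover the event (default: the event span plus margins).
#' @param alignmentPath optional SAM/BAM for the coverage track.
#' @param config [ExtractionConfig-class] for coverage filtering.
#' @return a \pkg{ggplot2} object; the junction table used for the arcs is
#'   attached as attribute \code{"arcs"}.
#' @export
plotSashimi <- function(x, event, window = NULL, alignmentPath = NULL,
                        config = extractionConfig()) {
    ev <- junctionBounds(event)
    if (is(x, "JunctionCounts")) {
        tr <- matchEvent(x, event, stranded = config@stranded)
    } else if (is(x, "JunctionTriple")) {
        tr <- x
    } else stop("x must be a JunctionTriple or JunctionCounts")
    span <- c(min(ev$intron_start) - 50L, max(ev$intron_end) + 50L)
    if (!is.null(window)) {
        reg <- .parseRegion(window)
        if (reg$chrom != ev$chrom[1L] || reg$start - 1L > min(ev$intron_start) ||
            reg$end < max(ev$intron_end))
            stop("window does not cover the cassette event")
        span <- c(reg$start, reg$end)
    }
    counts <- tripleCounts(tr)
    arcs <- data.frame(role = ev$role,
                       from = ev$intron_start, to = ev$intron_end,
                       count = as.integer(counts[c("j12", "j13", "j23")]),
                       skipping = ev$role == "skipping",
                       stringsAsFactors = FALSE)
    p <- ggplot2::ggplot()
    if (!is.null(alignmentPath)) {
        cov <- .coverageTrack(alignmentPath, ev$chrom[1L], span[1L], span[2L],
                              config)
        covMax <- max(cov$coverage, 1L)
        p <- p + ggplot2::geom_area(
            data = cov, ggplot2::aes(x = .data$pos, y = .data$coverage),
            fill = "grey70")
    } else {
        message("no alignment file supplied; coverage track omitted")
        covMax <- 10
    }
    drawn <- arcs[arcs$count > 0L, , drop = FALSE]
    if (nrow(drawn)) {
        arcPts <- do.call(rbind, lapply(seq_len(nrow(drawn)), function(i) {
            t <- seq(0, pi, length.out = 60)
            sgn <- if (drawn$skipping[i]) -1 else 1
            h <- covMax * (0.45 + 0.1 * i)
            data.frame(role = drawn$role[i],
                       x = (drawn$from[i] + drawn$to[i]) / 2 +
                           cos(t) * (drawn$to[i] - drawn$from[i]) / 2,
                       y = sgn * sin(t) * h,
                       skipping = drawn$skipping[i])
        }))
        p <- p + ggplot2::geom_path(
            data = arcPts,
            ggplot2::aes(x = .data$x, y = .data$y, group = .data$role,
                         colour = .data$skipping)) +
            ggplot2::geom_label(
                data = data.frame(x = (drawn$from + drawn$to) / 2,
                                  y = ifelse(drawn$skipping, -1, 1) *
                                      covMax * (0.45 + 0.1 *
                                                seq_len(nrow(drawn))),
                                  lab = drawn$count,
                                  skipping = drawn$skipping),
                ggplot2::aes(x = .data$x, y = .data$y, label = .data$lab,
                             colour = .data$skipping), size = 3) +
            ggplot2::scale_colour_manual(
                values = c("FALSE" = "grey30", "TRUE" = "purple"),
                guide = "none")
    }
    p <- p + ggplot2::labs(x = sprintf("%s position", ev$chrom[1L]),
                           y = "Coverage") +
        ggplot2::theme_bw()
    attr(p, "arcs") <- arcs
    p
}
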