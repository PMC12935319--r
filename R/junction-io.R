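#' @rdname ExtractionConfig-class
#' @param minOverhang,minMapq,countDuplicates,countSecondary,stranded see
#'   slot documentation.
#' @export
extractionConfig <- function(minOverhang = 6L, minMapq = 10L,
                             countDuplicates = FALSE, countSecondary = FALSE,
                             stranded = FALSE) {
    new("ExtractionConfig", minOverhang = as.integer(minOverhang),
        minMapq = as.integer(minMapq), countDuplicates = countDuplicates,
        countSecondary = countSecondary, stranded = stranded)
}

#' @rdname JunctionCounts-class
#' @export
setMethod("sampleID", "JunctionCounts", function(x) x@sampleID)

#' @rdname JunctionCounts-class
#' @export
setMethod("provenance", "JunctionCounts", function(x) x@provenance)

#' @rdname JunctionCounts-class
#' @export
setMethod("junctions", "JunctionCounts", function(x) x@junctions)

#' @rdname junctionBounds
#' @export
setMethod("junctionBounds", "JunctionCounts", function(x) {
    j <- x@junctions
    data.frame(chrom = as.character(seqnames(j)),
               intron_start = GenomicRanges::start(j) - 1L,
               intron_end = GenomicRanges::end(j),
               strand = as.character(strand(j)),
               count = if (length(j)) mcols(j)$count else integer(0),
               row.names = NULL)
})

setMethod("show", "JunctionCounts", function(object) {
    cat(sprintf("JunctionCounts for sample '%s' (%s): %d junctions, %d reads\n",
                object@sampleID, object@provenance, length(object@junctions),
                if (length(object@junctions))
                    sum(mcols(object@junctions)$count) else 0L))
})

# assemble a JunctionCounts from parallel coordinate vectors
# (1-based inclusive intron bounds), merging duplicate keys by summation
.makeJunctionCounts <- function(sampleID, provenance, chrom, start, end,
                                strand, count, warnDuplicates = FALSE) {
    if (length(chrom) == 0L) {
        gr <- GRanges()
        mcols(gr)$count <- integer(0)
        return(new("JunctionCounts", sampleID = sampleID,
                   provenance = provenance, junctions = gr))
    }
    key <- paste(chrom, start, end, strand, sep = ":")
    if (anyDuplicated(key)) {
        if (warnDuplicates)
            warning("duplicate junction keys found; counts summed")
        agg <- rowsum(as.numeric(count), key, reorder = FALSE)
        first <- !duplicated(key)
        chrom <- chrom[first]; start <- start[first]; end <- end[first]
        strand <- strand[first]
        count <- as.integer(agg[match(key[first], rownames(agg)), 1L])
    }
    gr <- GRanges(chrom, IRanges(start, end), strand = strand)
    mcols(gr)$count <- as.integer(count)
    o <- order(as.character(seqnames(gr)), GenomicRanges::start(gr),
               GenomicRanges::end(gr))
    new("JunctionCounts", sampleID = sampleID, provenance = provenance,
        junctions = gr[o])
}

# --- CIGAR machinery -------------------------------------------------------

# tokenize one CIGAR string into op letters and lengths
.cigarOps <- function(cigar) {
    toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
    if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar))
        stop("malformed CIGAR: ", cigar)
    list(op = substr(toks, nchar(toks), nchar(toks)),
         len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

# number of reference bases consumed by an alignment
.cigarRefWidth <- function(cigar) {
    cg <- .cigarOps(cigar)
    sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

# Walk one alignment's CIGAR and report every splice (N op) with the 1-based
# inclusive intron interval and the number of aligned (M/=/X) reference
# bases in the segments immediately flanking that splice. Returns NULL for
# alignments whose first or last reference-consuming operation is a splice
# (no anchor at all: unusable evidence).
.walkCigar <- function(pos, cigar) {
    cg <- .cigarOps(cigar)
    refOps <- cg$op %in% c("M", "D", "N", "=", "X")
    if (!any(refOps)) return(data.frame())
    refSeq <- cg$op[refOps]
    if (refSeq[1L] == "N" || refSeq[length(refSeq)] == "N") return(NULL)
    refpos <- as.integer(pos)
    segAligned <- 0L
    istart <- integer(); iend <- integer(); leftOv <- integer()
    for (k in seq_along(cg$op)) {
        op <- cg$op[k]; len <- cg$len[k]
        if (op %in% c("M", "=", "X")) {
            refpos <- refpos + len
            segAligned <- segAligned + len
        } else if (op == "D") {
            refpos <- refpos + len
        } else if (op == "N") {
            istart <- c(istart, refpos)
            iend <- c(iend, refpos + len - 1L)
            leftOv <- c(leftOv, segAligned)
            refpos <- refpos + len
            segAligned <- 0L
        }
        # I, S, H, P consume no reference
    }
    n <- length(istart)
    if (n == 0L) return(data.frame())
    # right overhang of splice i is the aligned count of the following
    # segment: the left overhang recorded at splice i+1, or the final segment
    rightOv <- c(leftOv[-1L], segAligned)[seq_len(n)]
    data.frame(intron_start = istart, intron_end = iend,
               left_overhang = leftOv, right_overhang = rightOv)
}

.parseRegion <- function(region) {
    if (is.null(region)) return(NULL)
    if (is(region, "GRanges")) {
        stopifnot(length(region) == 1L)
        return(list(chrom = as.character(seqnames(region))[1L],
                    start = GenomicRanges::start(region)[1L],
                    end = GenomicRanges::end(region)[1L]))
    }
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4L)
        stop("region must be a GRanges or a 'chrom:start-end' string")
    list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

# read the alignment fields needed for junction extraction from SAM or BAM
.readAlignments <- function(path, reg) {
    if (!file.exists(path)) stop("alignment file not found: ", path)
    if (grepl("\\.bam$", path, ignore.case = TRUE)) {
        what <- c("rname", "pos", "mapq", "cigar", "flag")
        bai <- paste0(path, ".bai")
        if (!is.null(reg) && file.exists(bai)) {
            which <- GRanges(reg$chrom, IRanges(reg$start, reg$end))
            p <- Rsamtools::ScanBamParam(what = what, which = which)
            b <- Rsamtools::scanBam(path, param = p)[[1L]]
        } else {
            p <- Rsamtools::ScanBamParam(what = what)
            b <- Rsamtools::scanBam(path, param = p)[[1L]]
        }
        return(data.frame(rname = as.character(b$rname), pos = b$pos,
                          mapq = b$mapq, cigar = b$cigar, flag = b$flag,
                          stringsAsFactors = FALSE))
    }
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (!length(lines))
        return(data.frame(rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          flag = integer()))
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 11L)
    if (length(bad))
        stop("malformed SAM record at alignment line ", bad[1L])
    data.frame(rname = vapply(f, `[`, "", 3L),
               pos = as.integer(vapply(f, `[`, "", 4L)),
               mapq = as.integer(vapply(f, `[`, "", 5L)),
               cigar = vapply(f, `[`, "", 6L),
               flag = as.integer(vapply(f, `[`, "", 2L)),
               stringsAsFactors = FALSE)
}

.samHasChrom <- function(path, chrom) {
    if (grepl("\\.bam$", path, ignore.case = TRUE)) {
        hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
        return(chrom %in% names(hdr))
    }
    con <- file(path, "r"); on.exit(close(con))
    repeat {
        ln <- readLines(con, n = 1L)
        if (!length(ln) || !startsWith(ln, "@")) return(FALSE)
        if (startsWith(ln, "@SQ") &&
            grepl(paste0("\tSN:", chrom, "(\t|$)"), ln)) return(TRUE)
    }
}

#' Extract splice-junction read counts from a SAM/BAM file
#'
#' Walks the CIGAR string of every retained alignment; each skip (\code{N})
#' operation contributes one junction whose intron interval is delimited by
#' the reference positions consumed before and after the skip. A read
#' supports a junction only if it has at least \code{minOverhang} aligned
#' (M/=/X) reference bases in the segments flanking that specific skip; a
#' read spanning several junctions increments each of them. Unmapped reads
#' are ignored; duplicates and secondary/supplementary alignments are
#' excluded unless enabled in \code{config}; alignments whose CIGAR starts
#' or ends with a skip are dropped with a warning. Counting is read-level:
#' two mates spanning the same junction contribute two reads.
#'
#' @param alignmentPath SAM (plain text) or BAM file. BAM regions use the
#'   index when present, otherwise the whole file is scanned and filtered.
#' @param region optional \code{"chrom:start-end"} string (1-based) or
#'   single \link[GenomicRanges]{GRanges}; only alignments overlapping it
#'   are considered.
#' @param config an [ExtractionConfig-class].
#' @param sampleID sample label for the result; defaults to the file name.
#' @return a [JunctionCounts-class] with provenance
#'   \code{"bam_extraction"}. Junction strand is taken from the alignment
#'   flag when \code{config@stranded}, otherwise \code{"*"}.
#' @export
extractJunctions <- function(alignmentPath, region = NULL,
                             config = extractionConfig(),
                             sampleID = basename(alignmentPath)) {
    reg <- .parseRegion(region)
    if (!is.null(reg) && !.samHasChrom(alignmentPath, reg$chrom))
        stop("unknown reference: ", reg$chrom)
    aln <- .readAlignments(alignmentPath, reg)
    keep <- !is.na(aln$pos) & !bitwAnd(aln$flag, 0x4)
    if (!config@countSecondary)
        keep <- keep & !bitwAnd(aln$flag, 0x100) & !bitwAnd(aln$flag, 0x800)
    if (!config@countDuplicates)
        keep <- keep & !bitwAnd(aln$flag, 0x400)
    mq <- aln$mapq
    keep <- keep & (is.na(mq) | mq == 255L | mq >= config@minMapq)
    aln <- aln[keep, , drop = FALSE]
    if (!is.null(reg) && nrow(aln)) {
        rw <- vapply(aln$cigar, .cigarRefWidth, integer(1), USE.NAMES = FALSE)
        aln <- aln[aln$rname == reg$chrom & aln$pos <= reg$end &
                   (aln$pos + rw - 1L) >= reg$start, , drop = FALSE]
    }
    chrom <- character(); js <- integer(); je <- integer(); str <- character()
    nDangling <- 0L
    for (i in seq_len(nrow(aln))) {
        if (!grepl("N", aln$cigar[i], fixed = TRUE)) next
        w <- .walkCigar(aln$pos[i], aln$cigar[i])
        if (is.null(w)) { nDangling <- nDangling + 1L; next }
        ok <- w$left_overhang >= config@minOverhang &
              w$right_overhang >= config@minOverhang
        w <- w[ok, , drop = FALSE]
        if (!nrow(w)) next
        chrom <- c(chrom, rep(aln$rname[i], nrow(w)))
        js <- c(js, w$intron_start)
        je <- c(je, w$intron_end)
        s <- if (config@stranded) {
            if (bitwAnd(aln$flag[i], 0x10)) "-" else "+"
        } else "*"
        str <- c(str, rep(s, nrow(w)))
    }
    if (nDangling > 0L)
        warning(nDangling, " alignment(s) skipped: CIGAR starts or ends ",
                "with a splice")
    .makeJunctionCounts(sampleID, "bam_extraction", chrom, js, je, str,
                        rep(1L, length(js)))
}

# --- precomputed junction tables -------------------------------------------

#' Read a STAR SJ.out.tab junction table
#'
#' Columns are: chromosome, 1-based first intron base, 1-based last intron
#' base, strand code (0 undefined, 1 \code{+}, 2 \code{-}), intron motif,
#' annotation flag, unique-mapping read count, multi-mapping read count.
#'
#' @param path SJ.out.tab file.
#' @param sampleID sample label; defaults to the file name.
#' @param includeMultimappers add the multi-mapping count to the
#'   unique-mapping count (default uses unique reads only).
#' @return a [JunctionCounts-class] with provenance \code{"star_sj_tab"}.
#' @export
readStarJunctions <- function(path, sampleID = basename(path),
                              includeMultimappers = FALSE) {
    if (!file.exists(path)) stop("junction table not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(.makeJunctionCounts(sampleID, "star_sj_tab", character(),
                                   integer(), integer(), character(),
                                   integer()))
    f <- strsplit(lines, "[\t ]+")
    for (i in seq_along(f)) {
        if (length(f[[i]]) < 8L)
            stop("malformed SJ.out.tab row at line ", i, ": expected >= 8 columns")
        num <- suppressWarnings(as.integer(f[[i]][2:8]))
        if (anyNA(num))
            stop("malformed SJ.out.tab row at line ", i, ": non-integer field")
        if (num[6L] < 0L || num[7L] < 0L)
            stop("negative read count at line ", i)
    }
    chrom <- vapply(f, `[`, "", 1L)
    s <- as.integer(vapply(f, `[`, "", 2L))
    e <- as.integer(vapply(f, `[`, "", 3L))
    code <- as.integer(vapply(f, `[`, "", 4L))
    uniq <- as.integer(vapply(f, `[`, "", 7L))
    multi <- as.integer(vapply(f, `[`, "", 8L))
    str <- c("*", "+", "-")[code + 1L]
    cnt <- if (includeMultimappers) uniq + multi else uniq
    .makeJunctionCounts(sampleID, "star_sj_tab", chrom, s, e, str, cnt)
}

#' Write junction counts in STAR SJ.out.tab layout
#'
#' Counts are written as unique-mapping reads; the motif, annotation and
#' multimapper columns are zero. [readStarJunctions()] inverts this exactly.
#'
#' @param counts a [JunctionCounts-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStarJunctions <- function(counts, path) {
    j <- junctions(counts)
    code <- match(as.character(strand(j)), c("*", "+", "-")) - 1L
    lines <- paste(as.character(seqnames(j)), GenomicRanges::start(j),
                   GenomicRanges::end(j), code, 0L, 0L, mcols(j)$count, 0L,
                   sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read a BED6-like junction table
#'
#' Expects columns chromosome, 0-based intron start, 0-based exclusive
#' intron end, name, score (the read count) and strand, as produced by
#' junction exporters such as recount3/snapcount extracts. Lines starting
#' with \code{#} are skipped; rows with identical coordinates are summed
#' with a warning; zero counts are retained.
#'
#' @param path BED-like file.
#' @param sampleID sample label; defaults to the file name.
#' @return a [JunctionCounts-class] with provenance \code{"bed_table"}.
#' @export
readJunctionBed <- function(path, sampleID = basename(path)) {
    if (!file.exists(path)) stop("junction table not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
        return(.makeJunctionCounts(sampleID, "bed_table", character(),
                                   integer(), integer(), character(),
                                   integer()))
    f <- strsplit(lines, "[\t ]+")
    if (any(lengths(f) < 6L))
        stop("malformed junction BED row at line ",
             which(lengths(f) < 6L)[1L], ": expected 6 columns")
    score <- vapply(f, `[`, "", 5L)
    if (any(grepl("[^0-9-]", score)) ||
        anyNA(suppressWarnings(as.integer(score))))
        stop("non-integer score at line ",
             which(is.na(suppressWarnings(as.integer(score))) |
                   grepl("[^0-9-]", score))[1L])
    .makeJunctionCounts(sampleID, "bed_table",
                        vapply(f, `[`, "", 1L),
                        as.integer(vapply(f, `[`, "", 2L)) + 1L,
                        as.integer(vapply(f, `[`, "", 3L)),
                        vapply(f, `[`, "", 6L),
                        as.integer(score), warnDuplicates = TRUE)
}

#' Write junction counts as a BED6-like table
#'
#' Coordinates are 0-based half-open; the score column carries the count.
#'
#' @param counts a [JunctionCounts-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeJunctionBed <- function(counts, path) {
    b <- junctionBounds(counts)
    lines <- paste(b$chrom, b$intron_start, b$intron_end,
                   sprintf("junction_%d", seq_len(nrow(b))), b$count,
                   b$strand, sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

# --- event matching --------------------------------------------------------

#' @rdname JunctionTriple-class
#' @param j12,j13,j23 non-negative counts for the upstream-inclusion,
#'   skipping and downstream-inclusion junctions.
#' @export
junctionTriple <- function(j12, j13, j23) {
    new("JunctionTriple", j12 = as.integer(j12), j13 = as.integer(j13),
        j23 = as.integer(j23))
}

#' @rdname JunctionTriple-class
#' @param x a \code{JunctionTriple}.
#' @export
setMethod("junctionDepth", "JunctionTriple",
          function(x) x@j12 + x@j13 + x@j23)

#' @rdname JunctionTriple-class
#' @export
tripleCounts <- function(x) {
    stopifnot(is(x, "JunctionTriple"))
    c(j12 = x@j12, j13 = x@j13, j23 = x@j23)
}

setMethod("show", "JunctionTriple", function(object) {
    cat(sprintf("JunctionTriple: j12=%d j13=%d j23=%d (depth %d)\n",
                object@j12, object@j13, object@j23, junctionDepth(object)))
})

#' Look up the three event junctions in a sample's junction counts
#'
#' Exact-coordinate lookup: a junction matches only if its intron interval
#' equals the event junction's interval. An absent junction is a count of
#' zero, mirroring a sample with no evidence for that splice. Strand is
#' compared only when \code{stranded = TRUE}.
#'
#' @param counts a [JunctionCounts-class].
#' @param event a [CassetteEvent-class].
#' @param stranded compare junction strand as well as coordinates.
#' @return a [JunctionTriple-class].
#' @export
setMethod("matchEvent", signature("JunctionCounts", "CassetteEvent"),
          function(counts, event, stranded = FALSE) {
    j <- junctions(counts)
    ev <- junctions(event)
    lookup <- function(i) {
        hit <- as.character(seqnames(j)) == as.character(seqnames(ev))[i] &
               GenomicRanges::start(j) == GenomicRanges::start(ev)[i] &
               GenomicRanges::end(j) == GenomicRanges::end(ev)[i]
        if (stranded)
            hit <- hit & as.character(strand(j)) == as.character(strand(ev))[i]
        if (any(hit)) sum(mcols(j)$count[hit]) else 0L
    }
    junctionTriple(lookup(1L), lookup(2L), lookup(3L))
})

#' List junctions near, but not matching, a cassette event
#'
#' Diagnostic listing of junctions whose intron interval overlaps the event
#' window but matches none of the three event junctions exactly — for
#' example alternative donor/acceptor usage near the target exon. These are
#' never counted toward the PSI triple.
#'
#' @param counts a [JunctionCounts-class].
#' @param event a [CassetteEvent-class].
#' @return a \code{data.frame} in [junctionBounds()] layout.
#' @export
junctionDiagnostics <- function(counts, event) {
    b <- junctionBounds(counts)
    ev <- junctionBounds(event)
    win <- c(min(ev$intron_start), max(ev$intron_end))
    near <- b$chrom == ev$chrom[1L] & b$intron_start < win[2L] &
            b$intron_end > win[1L]
    exact <- logical(nrow(b))
    for (i in seq_len(nrow(ev)))
        exact <- exact | (b$chrom == ev$chrom[i] &
                          b$intron_start == ev$intron_start[i] &
                          b$intron_end == ev$intron_end[i])
    b[near & !exact, , drop = FALSE]
}

# --- triples tables --------------------------------------------------------

#' Read and write per-sample junction triple tables
#'
#' The TSV layout is \code{sample_id, j12, j13, j23} with a header, plus an
#' optional \code{cohort} column.
#'
#' @param path TSV path.
#' @return \code{readTriples}: a \code{data.frame}.
#' @export
readTriples <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "j12", "j13", "j23")
    if (!all(need %in% names(df)))
        stop("triples table must have columns: ", paste(need, collapse = ", "))
    df
}

#' @rdname readTriples
#' @param triples a \code{data.frame} with columns \code{sample_id},
#'   \code{j12}, \code{j13}, \code{j23}.
#' @export
writeTriples <- function(triples, path) {
    utils::write.table(triples, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
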