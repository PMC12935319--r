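# Independent brute-force re-implementation of junction extraction used as
# the oracle: expands every alignment base-by-base along the reference and
# reads junctions off runs of skipped bases, instead of walking CIGAR
# segment arithmetic.

oracleParseSam <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^@", lines) & nzchar(lines)]
    if (!length(lines))
        return(data.frame(rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          flag = integer()))
    f <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(rname = sapply(f, `[`, 3L),
               pos = as.integer(sapply(f, `[`, 4L)),
               mapq = as.integer(sapply(f, `[`, 5L)),
               cigar = sapply(f, `[`, 6L),
               flag = as.integer(sapply(f, `[`, 2L)),
               stringsAsFactors = FALSE)
}

# expand one alignment into a per-reference-base vector of op labels
oracleExpand <- function(cigar) {
    toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    keep <- op %in% c("M", "D", "N", "=", "X")
    lab <- ifelse(op %in% c("M", "=", "X"), "A",
                  ifelse(op == "D", "D", "N"))
    rep(lab[keep], len[keep])
}

# junctions supported by one alignment under the overhang rule
oracleReadJunctions <- function(pos, cigar, minOverhang) {
    bases <- oracleExpand(cigar)
    if (!length(bases)) return(NULL)
    if (bases[1L] == "N" || bases[length(bases)] == "N")
        return("dangling")
    r <- rle(bases)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nIdx <- which(r$values == "N")
    if (!length(nIdx)) return(data.frame())
    # aligned bases in the maximal non-N stretch on each side of an N run
    alignedAround <- function(i, dir) {
        k <- i + dir
        tot <- 0L
        while (k >= 1L && k <= length(r$values) && r$values[k] != "N") {
            if (r$values[k] == "A") tot <- tot + r$lengths[k]
            k <- k + dir
        }
        tot
    }
    out <- do.call(rbind, lapply(nIdx, function(i) {
        if (alignedAround(i, -1L) < minOverhang ||
            alignedAround(i, +1L) < minOverhang) return(NULL)
        data.frame(intron_start = pos + starts[i] - 1L,
                   intron_end = pos + ends[i] - 1L)
    }))
    if (is.null(out)) data.frame() else out
}

# full oracle: same filter semantics as extractJunctions, independent walk
oracleExtract <- function(samPath, minOverhang = 6L, minMapq = 10L,
                          countDuplicates = FALSE, countSecondary = FALSE) {
    aln <- oracleParseSam(samPath)
    res <- list()
    for (i in seq_len(nrow(aln))) {
        fl <- aln$flag[i]
        if (bitwAnd(fl, 0x4)) next
        if (!countSecondary && (bitwAnd(fl, 0x100) || bitwAnd(fl, 0x800)))
            next
        if (!countDuplicates && bitwAnd(fl, 0x400)) next
        mq <- aln$mapq[i]
        if (!is.na(mq) && mq != 255L && mq < minMapq) next
        j <- oracleReadJunctions(aln$pos[i], aln$cigar[i], minOverhang)
        if (is.null(j) || identical(j, "dangling") || nrow(j) == 0L) next
        j$chrom <- aln$rname[i]
        res[[length(res) + 1L]] <- j
    }
    if (!length(res))
        return(data.frame(chrom = character(), intron_start = integer(),
                          intron_end = integer(), count = integer()))
    all <- do.call(rbind, res)
    agg <- aggregate(list(count = rep(1L, nrow(all))),
                     all[c("chrom", "intron_start", "intron_end")], sum)
    agg[order(agg$chrom, agg$intron_start, agg$intron_end), ]
}

# normalize a JunctionCounts to the oracle's table layout for comparison
countsAsTable <- function(jc) {
    b <- junctionBounds(jc)
    # oracle reports 1-based inclusive intron bounds
    out <- data.frame(chrom = b$chrom, intron_start = b$intron_start + 1L,
                      intron_end = b$intron_end, count = b$count)
    out <- out[order(out$chrom, out$intron_start, out$intron_end), ]
    rownames(out) <- NULL
    out
}
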