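# programmatic fixtures: toy GTF annotations and hand-built SAM files

gtfLine <- function(chrom, type, start, end, strand, gene, tx,
                    extra = "") {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s', gene, tx, extra)
    paste(chrom, "test", type, start, end, ".", strand, ".", attrs,
          sep = "\t")
}

# G1: single 4-exon + strand transcript (the worked cassette example)
# G2: one 2-exon and one 4-exon transcript (selection by exon count)
# G3: canonical-tagged short transcript vs untagged long one
# G4: minus-strand mirror of G1
writeToyGtf <- function(path = tempfile(fileext = ".gtf")) {
    ex <- function(gene, tx, starts, ends, strand = "+", chrom = "chr1",
                   extra = "")
        mapply(gtfLine, start = starts, end = ends,
               MoreArgs = list(chrom = chrom, type = "exon",
                               strand = strand, gene = gene, tx = tx,
                               extra = extra))
    lines <- c(
        ex("G1", "G1.t1", c(101, 301, 501, 701), c(200, 400, 600, 800)),
        ex("G2", "G2.small", c(101, 501), c(200, 600)),
        ex("G2", "G2.big", c(101, 301, 501, 701), c(200, 400, 600, 800)),
        ex("G3", "G3.long", c(101, 301, 501, 701, 901),
           c(200, 400, 600, 800, 1000)),
        ex("G3", "G3.cano", c(101, 301, 501), c(200, 400, 600),
           extra = ' tag "Ensembl_canonical";'),
        ex("G4", "G4.t1", c(101, 301, 501, 701), c(200, 400, 600, 800),
           strand = "-"))
    writeLines(lines, path)
    path
}

# write a SAM file from alignment field vectors over one toy contig
writeSam <- function(path, pos, cigar, mapq = 60L, flag = 0L,
                     chrom = "ctg1", contigLen = 5000L,
                     sorted = TRUE) {
    n <- length(pos)
    mapq <- rep_len(mapq, n); flag <- rep_len(flag, n)
    chromv <- rep_len(chrom, n)
    if (sorted) {
        o <- order(chromv, pos)
        pos <- pos[o]; cigar <- cigar[o]; mapq <- mapq[o]
        flag <- flag[o]; chromv <- chromv[o]
    }
    recs <- paste(sprintf("r%04d", seq_len(n)), flag, chromv, pos, mapq,
                  cigar, "*", 0L, 0L, "*", "*", sep = "\t")
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", unique(chrom), contigLen),
                 recs), path)
    path
}

# random alignments with 0-3 splices per read, assorted anchors (some
# shorter than the default overhang), indels, clipping and filterable flags
randomSam <- function(path, nReads = 150L, seed = 1L) {
    set.seed(seed)
    pos <- integer(nReads); cig <- character(nReads)
    mapq <- integer(nReads); flag <- integer(nReads)
    for (i in seq_len(nReads)) {
        nJunc <- sample(0:3, 1L, prob = c(0.2, 0.4, 0.25, 0.15))
        parts <- sprintf("%dM", sample(1:30, 1L))
        for (k in seq_len(nJunc)) {
            if (runif(1) < 0.15)
                parts <- c(parts, sprintf("%d%s", sample(1:5, 1L),
                                          sample(c("I", "D"), 1L)))
            parts <- c(parts, sprintf("%dN", sample(20:300, 1L)),
                       sprintf("%dM", sample(1:30, 1L)))
        }
        if (runif(1) < 0.2) parts <- c(sprintf("%dS", sample(1:10, 1L)), parts)
        if (runif(1) < 0.2) parts <- c(parts, sprintf("%dS", sample(1:10, 1L)))
        pos[i] <- sample(1:2000, 1L)
        cig[i] <- paste(parts, collapse = "")
        mapq[i] <- sample(c(0:60, 255L), 1L)
        flag[i] <- sample(c(0L, 16L, 256L, 1024L), 1L,
                          prob = c(0.6, 0.2, 0.1, 0.1))
    }
    writeSam(path, pos, cig, mapq = mapq, flag = flag)
}

# PsiResult list with given PSI values, built from depth-passing triples
psiResultsFor <- function(psis, depth = 100L, config = analysisConfig()) {
    lapply(seq_along(psis), function(i) {
        inc <- round(psis[i] * depth)
        computePsi(junctionTriple(inc, depth - inc, 0),
                   config = config, sampleID = sprintf("s%02d", i))
    })
}
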