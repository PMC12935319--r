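#' Construct an ExonModel from exon coordinates
#'
#' Builds the transcript exon model directly from coordinates, mainly for
#' simulation and testing; real annotation goes through [loadGeneModel()].
#' Exons may be given in any order; they are arranged in transcription order
#' (ascending genomic coordinate on \code{+}, descending on \code{-}).
#'
#' @param geneID,transcriptID identifiers carried through to derived events.
#' @param chrom chromosome / contig name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param starts,ends 1-based inclusive exon bounds.
#' @return an [ExonModel-class].
#' @examples
#' m <- exonModel("G1", "G1.t1", "chr1", "+",
#'                starts = c(101, 301, 501, 701),
#'                ends   = c(200, 400, 600, 800))
#' exons(m)
#' @export
exonModel <- function(geneID, transcriptID, chrom, strand, starts, ends) {
    stopifnot(length(starts) == length(ends))
    ord <- order(starts, decreasing = identical(strand, "-"))
    gr <- GRanges(chrom, IRanges(starts[ord], ends[ord]), strand = strand)
    mcols(gr)$exon_rank <- seq_along(gr)
    new("ExonModel", geneID = as.character(geneID),
        transcriptID = as.character(transcriptID), exons = gr)
}

#' @rdname ExonModel-class
#' @export
setMethod("geneID", "ExonModel", function(x) x@geneID)

#' @rdname ExonModel-class
#' @export
setMethod("transcriptID", "ExonModel", function(x) x@transcriptID)

#' @rdname ExonModel-class
#' @export
setMethod("exons", "ExonModel", function(x) x@exons)

setMethod("show", "ExonModel", function(object) {
    ex <- object@exons
    cat("ExonModel for gene", object@geneID,
        sprintf("(transcript %s)\n", object@transcriptID))
    cat(sprintf("  %d exons on %s (%s strand), transcription order\n",
                length(ex), as.character(seqnames(ex))[1L],
                as.character(strand(ex))[1L]))
    for (i in seq_along(ex))
        cat(sprintf("  exon %d: %s-%s\n", i, GenomicRanges::start(ex)[i],
                    GenomicRanges::end(ex)[i]))
})

#' Load a gene's exon model from a GTF annotation
#'
#' Reads an Ensembl-dialect GTF and returns the exon structure of one
#' transcript of the requested gene, numbered in transcription order. When
#' the gene has several transcripts and none is requested explicitly, the
#' annotated canonical transcript (a \code{tag} attribute containing
#' \code{Ensembl_canonical} or \code{canonical}) is preferred; otherwise the
#' transcript with the most exons, ties broken by longest genomic span, then
#' lexicographically smallest transcript ID. Exon numbering is
#' transcript-relative: events derived from the model (such as "exon 2"
#' skipping) refer to this transcript's exon order.
#'
#' @param annotationPath path to a GTF file (plain or gzipped).
#' @param gene gene identifier, matched against \code{gene_id} and, if
#'   present, \code{gene_name}.
#' @param transcript optional transcript ID to use instead of automatic
#'   selection.
#' @return an [ExonModel-class].
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste(c("chr1", "toy", "exon", 101, 200, ".", "+", ".",
#'   'gene_id "G1"; transcript_id "G1.t1";'), collapse = "\t"), gtf)
#' ## a one-exon model is loadable, though a cassette event needs >= 3 exons
#' loadGeneModel(gtf, "G1")
#' @export
loadGeneModel <- function(annotationPath, gene, transcript = NULL) {
    if (!file.exists(annotationPath))
        stop("annotation file not found: ", annotationPath)
    anno <- rtracklayer::import(annotationPath, format = "gtf")
    md <- mcols(anno)
    hit <- !is.na(md$gene_id) & md$gene_id == gene
    if (!is.null(md$gene_name))
        hit <- hit | (!is.na(md$gene_name) & md$gene_name == gene)
    if (!any(hit))
        stop("gene not found: ", gene)
    anno <- anno[hit]
    ex <- anno[!is.na(mcols(anno)$type) & mcols(anno)$type == "exon"]
    if (length(ex) == 0L)
        stop("gene ", gene, " has no exon records")
    txid <- as.character(mcols(ex)$transcript_id)
    if (is.null(transcript)) {
        transcript <- .selectTranscript(ex, txid)
    } else if (!transcript %in% txid) {
        stop("transcript not found for gene ", gene, ": ", transcript)
    }
    ex <- ex[txid == transcript]
    strand <- as.character(strand(ex))[1L]
    ord <- order(GenomicRanges::start(ex),
                 decreasing = identical(strand, "-"))
    ex <- ex[ord]
    exonModel(gene, transcript, as.character(seqnames(ex))[1L], strand,
              GenomicRanges::start(ex), GenomicRanges::end(ex))
}

# canonical tag > most exons > longest genomic span > lexicographic ID
.selectTranscript <- function(ex, txid) {
    tags <- mcols(ex)$tag
    if (!is.null(tags)) {
        flat <- vapply(tags, function(t)
            any(grepl("canonical", unlist(t), ignore.case = TRUE)), logical(1))
        cano <- unique(txid[flat])
        if (length(cano) == 1L) return(cano)
        if (length(cano) > 1L) txid_pool <- cano else txid_pool <- unique(txid)
    } else txid_pool <- unique(txid)
    nEx <- vapply(txid_pool, function(t) sum(txid == t), integer(1))
    span <- vapply(txid_pool, function(t) {
        r <- range(GenomicRanges::start(ex[txid == t]),
                   GenomicRanges::end(ex[txid == t]))
        diff(r) + 1L
    }, numeric(1))
    txid_pool[order(-nEx, -span, txid_pool)][1L]
}

#' Write an ExonModel back to GTF
#'
#' Emits one \code{exon} feature line per exon in Ensembl GTF dialect
#' (1-based inclusive coordinates), so that a model round-trips through
#' [loadGeneModel()] unchanged.
#'
#' @param model an [ExonModel-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModelGTF <- function(model, path) {
    ex <- exons(model)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                     geneID(model), transcriptID(model), seq_along(ex))
    lines <- paste(as.character(seqnames(ex)), "skipquant", "exon",
                   GenomicRanges::start(ex), GenomicRanges::end(ex), ".",
                   as.character(strand(ex)), ".", attrs, sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Derive the three junctions of a cassette-exon skipping event
#'
#' For target exon t, returns the upstream inclusion junction
#' (exon t-1 -> t), the skipping junction (exon t-1 -> t+1) and the
#' downstream inclusion junction (exon t -> t+1), each as the genomic
#' interval of the excised intron. On the minus strand, "upstream" refers to
#' transcription order, so the upstream intron has the larger genomic
#' coordinates; the set of genomic intervals is strand-symmetric.
#'
#' @param model an [ExonModel-class] with at least three exons.
#' @param targetExon 1-based exon number of the cassette exon; must have a
#'   flanking exon on both sides.
#' @return a [CassetteEvent-class].
#' @examples
#' m <- exonModel("G1", "G1.t1", "chr1", "+",
#'                starts = c(101, 301, 501, 701),
#'                ends   = c(200, 400, 600, 800))
#' ev <- deriveCassetteEvent(m, 2)
#' junctionBounds(ev)
#' @export
deriveCassetteEvent <- function(model, targetExon) {
    ex <- exons(model)
    t <- as.integer(targetExon)
    if (length(ex) < 3L)
        stop("not a cassette exon: model has fewer than 3 exons")
    if (is.na(t) || t <= 1L || t >= length(ex))
        stop("not a cassette exon: target exon must have flanking exons ",
             "on both sides")
    chrom <- as.character(seqnames(ex))[1L]
    str <- as.character(strand(ex))[1L]
    intronBetween <- function(i, j) { # i precedes j in transcription order
        if (str == "+")
            c(GenomicRanges::end(ex)[i] + 1L, GenomicRanges::start(ex)[j] - 1L)
        else
            c(GenomicRanges::end(ex)[j] + 1L, GenomicRanges::start(ex)[i] - 1L)
    }
    up <- intronBetween(t - 1L, t)
    sk <- intronBetween(t - 1L, t + 1L)
    dn <- intronBetween(t, t + 1L)
    b <- rbind(up, sk, dn)
    if (any(b[, 1L] > b[, 2L]))
        stop("adjacent exons leave no intron; cannot define junctions")
    j <- GRanges(chrom, IRanges(b[, 1L], b[, 2L]), strand = str)
    names(j) <- c("inclusion_upstream", "skipping", "inclusion_downstream")
    new("CassetteEvent", targetExon = t, geneID = geneID(model),
        transcriptID = transcriptID(model), junctions = j)
}

#' @rdname CassetteEvent-class
#' @param x a \code{CassetteEvent}.
#' @export
setMethod("junctions", "CassetteEvent", function(x) x@junctions)

#' @rdname junctionBounds
#' @export
setMethod("junctionBounds", "CassetteEvent", function(x) {
    j <- x@junctions
    data.frame(role = names(j),
               chrom = as.character(seqnames(j)),
               intron_start = GenomicRanges::start(j) - 1L,
               intron_end = GenomicRanges::end(j),
               strand = as.character(strand(j)),
               row.names = NULL)
})

setMethod("show", "CassetteEvent", function(object) {
    cat(sprintf("CassetteEvent: exon %d of %s (%s)\n", object@targetExon,
                object@geneID, object@transcriptID))
    b <- junctionBounds(object)
    for (i in seq_len(nrow(b)))
        cat(sprintf("  %-21s %s:[%d,%d) %s\n", b$role[i], b$chrom[i],
                    b$intron_start[i], b$intron_end[i], b$strand[i]))
})

#' Export a cassette event as BED6-like junction lines
#'
#' One line per junction in 0-based half-open coordinates with the junction
#' role in the name column; the score column is 0.
#'
#' @param event a [CassetteEvent-class].
#' @param path output path, or \code{NULL} to return the lines.
#' @return the BED lines, invisibly when written to a file.
#' @export
writeEventBed <- function(event, path = NULL) {
    b <- junctionBounds(event)
    lines <- paste(b$chrom, b$intron_start, b$intron_end, b$role, 0L,
                   b$strand, sep = "\t")
    if (is.null(path)) return(lines)
    writeLines(lines, path)
    invisible(lines)
}
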