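permissive <- extractionConfig(minOverhang = 1L, minMapq = 0L)

test_that("a single spliced read yields the hand-walked junction", {
    sam <- writeSam(tempfile(fileext = ".sam"), pos = 101L,
                    cigar = "20M100N30M")
    jc <- extractJunctions(sam)
    b <- junctionBounds(jc)
    expect_equal(nrow(b), 1L)
    # 20M consumes 101-120, so the intron is 121-220 1-based,
    # [120, 220) in the 0-based half-open convention
    expect_equal(b$intron_start, 120L)
    expect_equal(b$intron_end, 220L)
    expect_equal(b$count, 1L)
})

test_that("short anchors below minOverhang do not support a junction", {
    sam <- writeSam(tempfile(fileext = ".sam"), pos = 101L,
                    cigar = "3M100N47M")
    expect_equal(nrow(junctionBounds(extractJunctions(sam))), 0L)
    # the same read passes a permissive overhang
    expect_equal(junctionBounds(extractJunctions(sam, config = permissive))$count,
                 1L)
    # overhang is per splice: only the well-anchored splice of a two-splice
    # read is counted
    sam2 <- writeSam(tempfile(fileext = ".sam"), pos = 101L,
                     cigar = "20M100N4M200N30M")
    b2 <- junctionBounds(extractJunctions(sam2))
    expect_equal(nrow(b2), 0L)  # 4M segment fails both adjacent splices
})

test_that("a read spanning several junctions increments each key", {
    sam <- writeSam(tempfile(fileext = ".sam"), pos = rep(101L, 2L),
                    cigar = rep("20M100N20M200N10M", 2L))
    b <- junctionBounds(extractJunctions(sam))
    expect_equal(nrow(b), 2L)
    expect_equal(b$intron_start + 1L, c(121L, 241L))  # 1-based first base
    expect_equal(b$intron_end, c(220L, 440L))
    expect_equal(b$count, c(2L, 2L))
})

test_that("flag and MAPQ filters control which reads are counted", {
    path <- tempfile(fileext = ".sam")
    writeSam(path, pos = rep(101L, 5L), cigar = rep("20M100N30M", 5L),
             mapq = c(60L, 5L, 255L, 60L, 60L),
             flag = c(0L, 0L, 0L, 1024L, 256L))
    # default: MAPQ 5 dropped, 255 treated as unavailable and kept,
    # duplicate and secondary dropped
    expect_equal(junctionBounds(extractJunctions(path))$count, 2L)
    cfg <- extractionConfig(minMapq = 0L, countDuplicates = TRUE,
                            countSecondary = TRUE)
    expect_equal(junctionBounds(extractJunctions(path, config = cfg))$count,
                 5L)
})

test_that("alignments starting or ending in a splice are skipped with warning", {
    path <- tempfile(fileext = ".sam")
    writeSam(path, pos = c(101L, 101L),
             cigar = c("100N30M", "20M100N30M"))
    expect_warning(jc <- extractJunctions(path), "splice")
    expect_equal(junctionBounds(jc)$count, 1L)
})

test_that("region filtering restricts counting and validates the chromosome", {
    path <- tempfile(fileext = ".sam")
    writeSam(path, pos = c(101L, 1001L),
             cigar = c("20M100N30M", "20M100N30M"))
    all <- junctionBounds(extractJunctions(path))
    expect_equal(nrow(all), 2L)
    one <- junctionBounds(extractJunctions(path, region = "ctg1:1-500"))
    expect_equal(nrow(one), 1L)
    expect_equal(one$intron_start, 120L)
    expect_error(extractJunctions(path, region = "chrZ:1-500"),
                 "unknown reference")
})

test_that("SAM and BAM extraction agree", {
    sam <- writeSam(tempfile(fileext = ".sam"), pos = c(101L, 101L, 501L),
                    cigar = c("20M100N30M", "20M100N30M", "10M50N40M"))
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
    a <- junctionBounds(extractJunctions(sam))
    b <- junctionBounds(extractJunctions(bam))
    expect_equal(a, b)
    # indexed region query matches too
    br <- junctionBounds(extractJunctions(bam, region = "ctg1:1-400"))
    expect_equal(br, a[a$intron_start == 120L, ], ignore_attr = TRUE)
})

test_that("extraction counts are invariant to read order", {
    pos <- c(101L, 901L, 501L, 101L, 701L)
    cig <- c("20M100N30M", "15M60N35M", "10M50N40M", "20M100N30M",
             "25M80N25M")
    s1 <- writeSam(tempfile(fileext = ".sam"), pos, cig, sorted = TRUE)
    s2 <- writeSam(tempfile(fileext = ".sam"), rev(pos), rev(cig),
                   sorted = FALSE)
    expect_equal(junctionBounds(extractJunctions(s1)),
                 junctionBounds(extractJunctions(s2)))
})

test_that("STAR SJ.out.tab rows convert coordinates and counts correctly", {
    path <- tempfile()
    writeLines("chr16\t28932000\t28932100\t1\t1\t1\t21\t3", path)
    jc <- readStarJunctions(path)
    b <- junctionBounds(jc)
    expect_identical(provenance(jc), "star_sj_tab")
    expect_equal(b$intron_start, 28931999L)  # 0-based half-open
    expect_equal(b$intron_end, 28932100L)
    expect_equal(b$count, 21L)               # unique-mapping reads only
    expect_equal(b$strand, "+")
    withMulti <- readStarJunctions(path, includeMultimappers = TRUE)
    expect_equal(junctionBounds(withMulti)$count, 24L)
})

test_that("SJ.out.tab parse errors carry line numbers and empty files work", {
    empty <- tempfile(); file.create(empty)
    expect_length(junctions(readStarJunctions(empty)), 0L)
    bad <- tempfile()
    writeLines(c("chr1\t100\t200\t1\t1\t1\t5\t0", "chr1\tx\t200"), bad)
    expect_error(readStarJunctions(bad), "line 2")
    neg <- tempfile()
    writeLines("chr1\t100\t200\t1\t1\t1\t-5\t0", neg)
    expect_error(readStarJunctions(neg), "negative")
})

test_that("STAR table write/read round-trips counts and coordinates", {
    sam <- writeSam(tempfile(fileext = ".sam"), pos = c(101L, 101L, 501L),
                    cigar = c("20M100N30M", "20M100N30M", "10M50N40M"))
    jc <- extractJunctions(sam)
    path <- tempfile()
    writeStarJunctions(jc, path)
    back <- readStarJunctions(path)
    expect_equal(junctionBounds(back)[c("chrom", "intron_start",
                                        "intron_end", "count")],
                 junctionBounds(jc)[c("chrom", "intron_start",
                                      "intron_end", "count")])
})

test_that("BED-like junction tables parse, sum duplicates and keep zeros", {
    path <- tempfile()
    writeLines(c("# comment",
                 "chr16\t28931999\t28932100\tj\t13\t+",
                 "chr16\t100\t200\ta\t5\t+",
                 "chr16\t100\t200\tb\t7\t+",
                 "chr16\t900\t1000\tz\t0\t+"), path)
    expect_warning(jc <- readJunctionBed(path), "summed")
    b <- junctionBounds(jc)
    expect_identical(provenance(jc), "bed_table")
    expect_equal(b$count[b$intron_start == 28931999L], 13L)
    expect_equal(b$count[b$intron_start == 100L], 12L)
    expect_equal(b$count[b$intron_start == 900L], 0L)
    bad <- tempfile()
    writeLines("chr1\t100\t200\tj\tNAN\t+", bad)
    expect_error(readJunctionBed(bad), "non-integer score")
})

test_that("matchEvent performs exact lookup with absent keys as zero", {
    ev <- deriveCassetteEvent(toyGeneModel(), 2)
    bed <- tempfile()
    # only the skipping junction, 21 reads ([500,1400) on the toy model)
    writeLines("ctg1\t500\t1400\tskip\t21\t+", bed)
    tr <- matchEvent(suppressWarnings(readJunctionBed(bed)), ev)
    expect_equal(unname(tripleCounts(tr)), c(0L, 21L, 0L))
    # empty map
    empty <- tempfile(); file.create(empty)
    tr0 <- matchEvent(readJunctionBed(empty), ev)
    expect_equal(unname(tripleCounts(tr0)), c(0L, 0L, 0L))
    # all three junctions present
    full <- tempfile()
    writeLines(c("ctg1\t500\t800\tu\t15\t+",
                 "ctg1\t500\t1400\ts\t1\t+",
                 "ctg1\t1100\t1400\td\t14\t+"), full)
    tr3 <- matchEvent(readJunctionBed(full), ev)
    expect_equal(unname(tripleCounts(tr3)), c(15L, 1L, 14L))
    # off-by-one coordinates never match
    off <- tempfile()
    writeLines("ctg1\t501\t1400\ts\t9\t+", off)
    expect_equal(unname(tripleCounts(matchEvent(readJunctionBed(off), ev))),
                 c(0L, 0L, 0L))
})

test_that("stranded matching compares strand only when asked", {
    ev <- deriveCassetteEvent(toyGeneModel(), 2)   # + strand event
    bed <- tempfile()
    writeLines("ctg1\t500\t1400\ts\t8\t-", bed)
    jc <- readJunctionBed(bed)
    expect_equal(tripleCounts(matchEvent(jc, ev))[["j13"]], 8L)
    expect_equal(tripleCounts(matchEvent(jc, ev, stranded = TRUE))[["j13"]],
                 0L)
})

test_that("junctionDiagnostics lists near-miss junctions without counting them", {
    ev <- deriveCassetteEvent(toyGeneModel(), 2)
    bed <- tempfile()
    writeLines(c("ctg1\t500\t1400\ts\t10\t+",
                 "ctg1\t510\t1390\tnear\t3\t+"), bed)
    jc <- readJunctionBed(bed)
    d <- junctionDiagnostics(jc, ev)
    expect_equal(nrow(d), 1L)
    expect_equal(d$intron_start, 510L)
    expect_equal(tripleCounts(matchEvent(jc, ev))[["j13"]], 10L)
})
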