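test_that("degenerate single-class profile yields exact full-length miRNAs", {
    rs <- get_toy_refset()
    prof <- compositionProfile("wt_male", read_count = 100, seed = 4)
    prof@classFractions[] <- 0
    prof@classFractions["miRNA"] <- 1
    lib <- simulateSmallRnaReads(prof, rs)
    reads <- libraryReads(lib)
    expect_equal(nrow(reads), 100L)
    expect_true(all(reads$true_class == "miRNA"))
    mir <- as.character(classRecords(rs, "miRNA"))
    expect_true(all(reads$sequence == mir[reads$true_source]))
})

test_that("a positive fraction without reference records is an error", {
    rs <- get_toy_refset()
    empty_genes <- rs
    empty_genes@genes <- rs@genes[0, ]
    prof <- compositionProfile("wt_male", read_count = 50, seed = 1)
    expect_error(simulateSmallRnaReads(prof, empty_genes), "endo_siRNA")
})

test_that("truth-label class fractions recover the profile within 4 SDs", {
    rs <- get_toy_refset()
    set.seed(77)
    for (rep in 1:3) {
        f <- stats::runif(7); f <- f / sum(f)
        prof <- compositionProfile("wt_male", read_count = 100000,
                                   seed = 100 + rep)
        prof@classFractions[] <- f
        lib <- simulateSmallRnaReads(prof, rs)
        obs <- table(factor(libraryReads(lib)$true_class,
                            levels = names(prof@classFractions))) / 1e5
        sd4 <- 4 * sqrt(f * (1 - f) / 1e5)
        expect_true(all(abs(as.numeric(obs) - f) <= sd4 + 1e-12))
    }
})

test_that("tDR length histogram matches the two-mode mixture (chi-square)", {
    rs <- get_toy_refset()
    prof <- compositionProfile("wt_sperm", read_count = 100000, seed = 31)
    prof@classFractions[] <- 0
    prof@classFractions["tDR"] <- 1
    lib <- simulateSmallRnaReads(prof, rs)
    lens <- nchar(libraryReads(lib)$sequence)
    fm <- prof@fragmentModel
    # expected mixture: round(Normal) clipped to [18,40]; tRNA-length
    # truncation never binds (all mature tRNAs exceed 40 nt)
    grid <- 18:40
    pmode <- function(m, s) {
        p <- stats::pnorm(grid + 0.5, m, s) - stats::pnorm(grid - 0.5, m, s)
        p[1] <- stats::pnorm(18.5, m, s)
        p[length(p)] <- stats::pnorm(39.5, m, s, lower.tail = FALSE)
        p
    }
    p <- fm@longModeWeight * pmode(fm@halfLengthMean, fm@halfLengthSd) +
        (1 - fm@longModeWeight) * pmode(fm@shortLengthMean, fm@shortLengthSd)
    obs <- table(factor(lens, levels = grid))
    keep <- p * length(lens) >= 5
    ob <- as.numeric(obs[keep]); pk <- p[keep]
    if (any(!keep)) {
        ob <- c(ob, sum(obs[!keep])); pk <- c(pk, sum(p[!keep]))
    }
    chi <- suppressWarnings(stats::chisq.test(ob, p = pk, rescale.p = TRUE))
    expect_gt(chi$p.value, 0.01)
})

test_that("tDR reads are anchored at the mature ends; halves behave", {
    rs <- get_toy_refset()
    prof <- compositionProfile("wt_sperm", read_count = 3000, seed = 12)
    prof@classFractions[] <- 0
    prof@classFractions["tDR"] <- 1
    reads <- libraryReads(simulateSmallRnaReads(prof, rs))
    tr <- matureTRNAs(rs)
    sq <- stats::setNames(tr$sequence, tr$trna_id)
    five <- reads$true_half == "five_prime"
    expect_true(all(startsWith(sq[reads$true_source[five]],
                               reads$sequence[five])))
    expect_true(all(endsWith(sq[reads$true_source[!five]],
                             reads$sequence[!five])))
    expect_true(all(endsWith(reads$sequence[!five], "CCA")))
})

test_that("synthetic endo-siRNAs are antisense and G-biased at 22/26 nt", {
    rs <- get_toy_refset()
    prof <- compositionProfile("wt_male", read_count = 5000, seed = 8)
    prof@classFractions[] <- 0
    prof@classFractions["endo_siRNA"] <- 1
    reads <- libraryReads(simulateSmallRnaReads(prof, rs))
    expect_true(all(nchar(reads$sequence) %in% c(22L, 26L)))
    gfrac <- mean(substr(reads$sequence, 1, 1) == "G")
    expect_gt(gfrac, 0.8)  # forced 0.8 plus chance G at unforced positions
    idx <- get_toy_index()
    asn <- classifyReads(reads[, 1:2], idx, rs)
    expect_true(mean(asn$class == "endo_siRNA") > 0.999)
})

test_that("fixed seed reproduces the library byte for byte", {
    rs <- get_toy_refset()
    prof <- compositionProfile("wt_sperm", read_count = 500, seed = 99)
    f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
    writeFastq(simulateSmallRnaReads(prof, rs), f1)
    writeFastq(simulateSmallRnaReads(prof, rs), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("FASTQ and truth round-trip", {
    rs <- get_toy_refset()
    lib <- simulateSmallRnaReads(compositionProfile("wt_male", read_count = 50),
                                 rs, seed = 6)
    fq <- tempfile(fileext = ".fq")
    writeFastq(lib, fq)
    expect_equal(length(readLines(fq)), 200L)
    back <- readFastq(fq)
    expect_equal(back$sequence, libraryReads(lib)$sequence)
    expect_equal(back$read_id, libraryReads(lib)$read_id)
    tt <- tempfile(fileext = ".tsv")
    writeTruth(lib, tt)
    truth <- read.delim(tt)
    expect_equal(nrow(truth), 50L)
})

test_that("planted embryo fold changes concentrate around 2^log2fc", {
    prof <- expressionProfile("two_cell")
    # dispersion -> 0 limit: empirical mean ratio approaches the planted fold
    prof@dispersion <- 1e-6
    se <- simulateEmbryoCounts(prof, seed = 5)
    counts <- SummarizedExperiment::assay(se, "counts")
    cond <- SummarizedExperiment::colData(se)$condition
    planted <- S4Vectors::metadata(se)$planted_de
    ife <- counts["ife-2", ]
    r <- mean(ife[cond == "treatment"]) / mean(ife[cond == "control"])
    expect_equal(r, 2.5, tolerance = 0.06)
    expect_equal(sort(unique(planted$log2fc)),
                 sort(unique(c(log2(2.5), 1.3, -2))))
})

test_that("embryo tables are reproducible and TSV round-trips", {
    prof <- expressionProfile("eight_cell")
    se1 <- simulateEmbryoCounts(prof, seed = 3)
    se2 <- simulateEmbryoCounts(prof, seed = 3)
    expect_identical(SummarizedExperiment::assay(se1, "counts"),
                     SummarizedExperiment::assay(se2, "counts"))
    path <- tempfile(fileext = ".tsv")
    writeCountTable(se1, path)
    back <- readCountTable(path)
    expect_equal(SummarizedExperiment::assay(back, "counts"),
                 SummarizedExperiment::assay(se1, "counts"))
    expect_equal(SummarizedExperiment::colData(back)$condition,
                 SummarizedExperiment::colData(se1)$condition)
    expect_equal(S4Vectors::metadata(back)$stage, "eight_cell")
})
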