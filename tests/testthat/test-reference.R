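test_that("a minimal valid reference loads with normalized sequences", {
    trnas <- data.frame(trna_id = "t1", isoacceptor = "Gly-GCC",
                        sequence = paste0(strrep("A", 33), "GCC",
                                          strrep("g", 33), "cca"),
                        anticodon_start = 34L, anticodon_end = 36L)
    rs <- makeReferenceSet(c(chrI = paste0(strrep("acgt", 15))),
                           list(rRNA = c(r1 = "AACCGGTT"),
                                miRNA = c(m1 = strrep("AC", 11)),
                                piRNA = c(p1 = paste0("T", strrep("G", 20)))),
                           trnas)
    expect_s4_class(rs, "ReferenceSet")
    expect_equal(length(genomeContigs(rs)), 1L)
    expect_equal(nrow(matureTRNAs(rs)), 1L)
    expect_equal(matureTRNAs(rs)$length, 72L)
    # U -> T and uppercasing
    rs2 <- makeReferenceSet(c(chrI = "ACGU"), list(rRNA = c(r1 = "uuuuu"),
                            miRNA = c(m1 = "AAAA"), piRNA = c(p1 = "TTTT")),
                            trnas)
    expect_equal(as.character(genomeContigs(rs2)[["chrI"]]), "ACGT")
    expect_equal(as.character(classRecords(rs2, "rRNA")[["r1"]]), "TTTTT")
})

test_that("missing CCA is appended; other invariant violations are rejected", {
    base <- paste0(strrep("A", 33), "GCC", strrep("G", 33))
    t_no_cca <- data.frame(trna_id = "t1", isoacceptor = "Gly-GCC",
                           sequence = base, anticodon_start = 34L,
                           anticodon_end = 36L)
    rs <- makeReferenceSet(c(c1 = "ACGT"), list(rRNA = c(r1 = "ACGT"),
                           miRNA = c(m1 = "ACGT"), piRNA = c(p1 = "ACGT")),
                           t_no_cca)
    expect_equal(matureTRNAs(rs)$length, nchar(base) + 3L)
    expect_true(endsWith(matureTRNAs(rs)$sequence, "CCA"))

    bad_span <- transform(t_no_cca, anticodon_end = 38L)
    expect_error(makeReferenceSet(c(c1 = "ACGT"),
                                  list(rRNA = c(r1 = "ACGT"),
                                       miRNA = c(m1 = "ACGT"),
                                       piRNA = c(p1 = "ACGT")), bad_span),
                 "anticodon")
    bad_anti <- transform(t_no_cca, isoacceptor = "Glu-CTC")
    expect_error(makeReferenceSet(c(c1 = "ACGT"),
                                  list(rRNA = c(r1 = "ACGT"),
                                       miRNA = c(m1 = "ACGT"),
                                       piRNA = c(p1 = "ACGT")), bad_anti),
                 "isoacceptor")
    na_coord <- transform(t_no_cca, anticodon_start = NA_integer_)
    expect_error(makeReferenceSet(c(c1 = "ACGT"),
                                  list(rRNA = c(r1 = "ACGT"),
                                       miRNA = c(m1 = "ACGT"),
                                       piRNA = c(p1 = "ACGT")), na_coord),
                 "t1")
    expect_error(makeReferenceSet(c(c1 = "ACXT"),
                                  list(rRNA = c(r1 = "ACGT"),
                                       miRNA = c(m1 = "ACGT"),
                                       piRNA = c(p1 = "ACGT")), t_no_cca),
                 "position")
})

test_that("write/load round-trips a ReferenceSet exactly", {
    rs <- make_mini_refset()
    dir <- withr::local_tempdir()
    writeReferenceSet(rs, dir)
    rs2 <- readReferenceSet(dir)
    expect_equal(as.character(genomeContigs(rs2)),
                 as.character(genomeContigs(rs)))
    expect_equal(matureTRNAs(rs2), matureTRNAs(rs))
    expect_equal(geneAnnotations(rs2), geneAnnotations(rs))
    for (cl in c("rRNA", "miRNA", "piRNA"))
        expect_equal(as.character(classRecords(rs2, cl)),
                     as.character(classRecords(rs, cl)))
})

test_that("exact index queries find substrings and reject absent reads", {
    rs <- make_mini_refset()
    idx <- buildClassIndex(rs, 0L)
    mi <- as.character(classRecords(rs, "miRNA")[["m2"]])
    q <- substr(mi, 1, 22)
    h <- queryIndex(idx, q)
    hm <- h[h$space == "miRNA", ]
    expect_equal(nrow(hm), 1L)
    expect_equal(hm$record_id, "m2")
    expect_equal(hm$mm, 0L)
    expect_equal(hm$strand, "+")
    # a read absent everywhere: alphabet trick guarantees no match
    h0 <- queryIndex(idx, strrep("A", 25))
    expect_equal(nrow(h0[h0$space != "genome", ]), 0L)
})

test_that("index queries equal the sliding-window Hamming oracle", {
    rs <- make_mini_refset()
    for (mm in c(0L, 1L)) {
        idx <- buildClassIndex(rs, mm)
        set.seed(42 + mm)
        # half random (mostly unmatched), half planted from the references
        reads <- c(vapply(1:5, function(i) rand_dna(25), ""),
                   vapply(1:5, function(i) {
                       ctg <- as.character(genomeContigs(rs)[[1]])
                       p <- sample(nchar(ctg) - 25L, 1L)
                       s <- substr(ctg, p, p + 24L)
                       if (i %% 2) s else {
                           # plant one substitution
                           q <- sample(25L, 1L)
                           substr(s, q, q) <- sample(setdiff(c("A","C","G","T"),
                                                     substr(s, q, q)), 1L)
                           s
                       }
                   }, ""))
        got <- queryIndex(idx, reads, mm)
        for (r in reads) {
            want <- oracle_hits(r, rs, mm)
            g <- got[got$seq == r, c("space", "record_id", "start", "strand",
                                     "mm")]
            if (is.null(want)) {
                expect_equal(nrow(g), 0L)
            } else {
                ord <- function(d) d[do.call(order, d), , drop = FALSE]
                expect_equal(ord(as.data.frame(g)),
                             ord(want), ignore_attr = TRUE)
            }
        }
    }
})

test_that("identical mature tRNA sequences collapse to one indexed record", {
    rs <- make_mini_refset()
    idx <- buildClassIndex(rs, 0L)
    expect_equal(sort(idx@collapseMap$trna_id), c("tG1", "tG2", "tS1"))
    expect_equal(length(unique(idx@collapseMap$rep_id)), 2L)
    tg <- matureTRNAs(rs)
    q <- substr(tg$sequence[1], 1, 30)
    h <- queryIndex(idx, q)
    expect_equal(nrow(h[h$space == "tRNA", ]), 1L)  # one rep, not two members
})
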