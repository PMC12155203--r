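test_that("adapter trimming removes the 3' adapter and size-filters", {
    adapter <- "TGGAATTCTCGGGTGCCAAGG"
    insert22 <- strrep("AC", 11)
    reads <- data.frame(read_id = c("a", "b"),
                        sequence = c(paste0(insert22, adapter),
                                     paste0(strrep("G", 15), adapter)))
    out <- trimAndFilter(reads, adapter)
    expect_equal(out$read_id, "a")
    expect_equal(out$sequence, insert22)  # 15 nt insert discarded
})

test_that("trimming equals the leftmost-prefix-match oracle on random inserts", {
    adapter <- "TGGAATTCTCGGGTGCCAAGG"
    set.seed(11)
    cases <- replicate(100, {
        ins <- rand_dna(sample(10:45, 1))
        alen <- sample(0:nchar(adapter), 1)
        paste0(ins, substr(adapter, 1, alen))
    })
    reads <- data.frame(read_id = as.character(seq_along(cases)),
                        sequence = cases)
    got <- trimAndFilter(reads, adapter)
    want <- vapply(cases, oracle_trim, "", adapter = adapter)
    keep <- nchar(want) >= 18 & nchar(want) <= 40
    expect_equal(got$sequence, unname(want[keep]))
    expect_equal(got$read_id, as.character(which(keep)))
})

test_that("class priority: rRNA beats tRNA; unmatched reads are unassigned", {
    # craft a reference where one 25-mer occurs in both an rRNA and a tRNA
    set.seed(5)
    shared <- rand_dna(25)
    trna_seq <- paste0(rand_dna(8), shared, "GCC", rand_dna(30))
    trnas <- data.frame(trna_id = "t1", isoacceptor = "Gly-GCC",
                        sequence = trna_seq,
                        anticodon_start = 34L, anticodon_end = 36L)
    rs <- makeReferenceSet(
        c(c1 = rand_dna(200)),
        list(rRNA = c(r1 = paste0(rand_dna(40), shared, rand_dna(40))),
             miRNA = c(m1 = rand_dna(22)), piRNA = c(p1 = rand_dna(21))),
        trnas)
    idx <- buildClassIndex(rs, 0L)
    asn <- classifyReads(data.frame(read_id = c("x", "y"),
                                    sequence = c(shared, rand_dna(30))),
                         idx, rs)
    expect_equal(asn$class[asn$read_id == "x"], "rRNA")
    y <- asn[asn$read_id == "y", ]
    expect_equal(y$class, "unassigned")
    expect_true(is.na(y$record_id))
})

test_that("classifier equals the brute-force oracle on a mixed library", {
    rs <- make_mini_refset()
    idx <- buildClassIndex(rs, 0L)
    prof <- compositionProfile("wt_male", read_count = 1000, seed = 3)
    # mini refset lacks most isoacceptors; reweight onto its two families
    fm <- prof@fragmentModel
    fm@isoacceptorWeights <- c("Gly-GCC" = 0.6, "Ser-AGA" = 0.4)
    prof@fragmentModel <- fm
    lib <- simulateSmallRnaReads(prof, rs)
    reads <- libraryReads(lib)
    asn <- classifyReads(reads[, c("read_id", "sequence")], idx, rs)
    one <- asn[!duplicated(asn$read_id), ]
    want <- vapply(reads$sequence, oracle_class, "", refset = rs)
    expect_equal(one$class[match(reads$read_id, one$read_id)], unname(want))
})

test_that("permuting read order never changes an assignment", {
    rs <- make_mini_refset()
    idx <- buildClassIndex(rs, 0L)
    prof <- compositionProfile("wt_male", read_count = 300, seed = 9)
    fm <- prof@fragmentModel
    fm@isoacceptorWeights <- c("Gly-GCC" = 0.6, "Ser-AGA" = 0.4)
    prof@fragmentModel <- fm
    reads <- libraryReads(simulateSmallRnaReads(prof, rs))[, 1:2]
    a1 <- classifyReads(reads, idx, rs)
    set.seed(1)
    a2 <- classifyReads(reads[sample(nrow(reads)), ], idx, rs)
    key <- function(a) a[order(a$read_id, a$record_id, a$start, a$strand),
                         c("read_id", "class", "record_id", "start", "strand",
                           "mm", "weight")]
    expect_equal(key(a1), key(a2), ignore_attr = TRUE)
})

test_that("multimapping weights are conserved and counts add up", {
    rs <- make_mini_refset()
    idx <- buildClassIndex(rs, 0L)
    # read matching the duplicated tRNA pair: one collapsed target, weight 1
    tg <- matureTRNAs(rs)$sequence[1]
    asn <- classifyReads(data.frame(read_id = "r", sequence = substr(tg, 1, 28)),
                         idx, rs)
    expect_equal(sum(asn$weight), 1)
    expect_equal(asn$class, "tRNA")

    prof <- compositionProfile("wt_male", read_count = 2000, seed = 21)
    fm <- prof@fragmentModel
    fm@isoacceptorWeights <- c("Gly-GCC" = 0.6, "Ser-AGA" = 0.4)
    prof@fragmentModel <- fm
    reads <- libraryReads(simulateSmallRnaReads(prof, rs))[, 1:2]
    asn <- classifyReads(reads, idx, rs)
    cc <- countClasses(asn)
    w <- tapply(asn$weight, asn$read_id, sum)
    expect_true(all(abs(w - 1) < 1e-9))  # per-read weights sum to 1
    expect_equal(sum(classCountValues(cc)), totalGenomeMapping(cc))
    n_un <- length(unique(asn$read_id[asn$class == "unassigned"]))
    expect_equal(totalGenomeMapping(cc) + n_un, nrow(reads))
})

test_that("rpm normalization follows its three denominators", {
    counts <- c(rRNA = 600000, miRNA = 0, tRNA = 100, piRNA = 0,
                endo_siRNA = 399900, mRNA_frag = 0, other_genomic = 0)
    cc <- new("ClassCounts", counts = counts,
              totalGenomeMapping = 1e6, totalInput = 1e6)
    expect_equal(rpmValues(normalizeCounts(cc, "genome"))[["tRNA"]], 100)
    expect_equal(rpmValues(normalizeCounts(cc, "genome_minus_rRNA"))[["tRNA"]],
                 250)
    expect_equal(rpmValues(normalizeCounts(cc, "class_total",
                                           class_label = "rRNA"))[["rRNA"]],
                 1e6)
    empty <- new("ClassCounts",
                 counts = stats::setNames(numeric(7), names(counts)),
                 totalGenomeMapping = 0, totalInput = 0)
    expect_error(normalizeCounts(empty, "genome"), "denominator")
})

test_that("excluding rRNA from the denominator never shrinks non-rRNA rpm", {
    rs <- get_toy_refset()
    idx <- get_toy_index()
    lib <- simulateSmallRnaReads(compositionProfile("rnst2_del_male",
                                                    read_count = 20000), rs,
                                 seed = 2)
    cc <- countClasses(classifyReads(libraryReads(lib)[, 1:2], idx, rs))
    g <- rpmValues(normalizeCounts(cc, "genome"))
    gm <- rpmValues(normalizeCounts(cc, "genome_minus_rRNA"))
    non_r <- setdiff(names(g), "rRNA")
    expect_true(all(gm[non_r] >= g[non_r]))
})
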