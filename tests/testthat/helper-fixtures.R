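# shared fixtures, built once per test run

.fixtures <- new.env()

get_toy_refset <- function() {
    if (is.null(.fixtures$refset)) .fixtures$refset <- toyReferenceSet()
    .fixtures$refset
}

get_toy_index <- function() {
    if (is.null(.fixtures$index))
        .fixtures$index <- buildClassIndex(get_toy_refset(), 0L)
    .fixtures$index
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a compact hand-buildable reference for oracle comparisons: 1 contig with
# three genes, one rRNA, three miRNAs, three tRNAs (two of them identical in
# sequence, exercising isodecoder collapsing), two piRNAs
make_mini_refset <- function(seed = 101) {
    set.seed(seed)
    g1 <- rand_dna(400); g2 <- rand_dna(350); g3 <- rand_dna(300)
    contig <- paste0(rand_dna(150), g1, rand_dna(100), g2, rand_dna(120),
                     g3, rand_dna(80))
    genes <- data.frame(
        gene_id = c("gA", "gB", "gC"),
        contig = "ctg1",
        start = c(151, 151 + 400 + 100, 151 + 400 + 100 + 350 + 120),
        end = c(550, 1000, 1320),
        strand = c("+", "-", "+"))
    body <- paste0(rand_dna(33), "GCC", rand_dna(36))  # anticodon at 34-36
    trnas <- data.frame(
        trna_id = c("tG1", "tG2", "tS1"),
        isoacceptor = c("Gly-GCC", "Gly-GCC", "Ser-AGA"),
        sequence = c(body, body, paste0(rand_dna(33), "AGA", rand_dna(34))),
        anticodon_start = 34L, anticodon_end = 36L)
    makeReferenceSet(
        stats::setNames(contig, "ctg1"),
        list(rRNA = c(rr1 = rand_dna(300)),
             miRNA = stats::setNames(vapply(1:3, function(i) rand_dna(22), ""),
                                     paste0("m", 1:3)),
             piRNA = stats::setNames(paste0("T", c(rand_dna(20), rand_dna(20))),
                                     paste0("p", 1:2))),
        trnas, genes)
}

# independent hit oracle: scan every reference with gregexpr (0 mm) or a
# position-by-position Hamming count (<= 1 mm); no shared code with the index
oracle_hits <- function(read, refset, max_mm = 0L) {
    out <- NULL
    spaces <- list(rRNA = refset@classes$rRNA, miRNA = refset@classes$miRNA,
                   tRNA = refset@classes$tRNA, piRNA = refset@classes$piRNA)
    scan_seq <- function(subject, read, max_mm) {
        n <- nchar(subject); L <- nchar(read)
        if (n < L) return(NULL)
        if (max_mm == 0L) {
            m <- gregexpr(read, subject, fixed = TRUE)[[1]]
            if (m[1] == -1L) return(NULL)
            # gregexpr skips overlapping matches; rescan manually
            starts <- which(vapply(seq_len(n - L + 1L), function(i)
                substr(subject, i, i + L - 1L) == read, TRUE))
            return(data.frame(start = starts, mm = 0L))
        }
        sv <- utf8ToInt(subject); rv <- utf8ToInt(read)
        hits <- lapply(seq_len(n - L + 1L), function(i) {
            d <- sum(sv[i:(i + L - 1L)] != rv)
            if (d <= max_mm) data.frame(start = i, mm = d) else NULL
        })
        do.call(rbind, hits)
    }
    for (sp in names(spaces)) {
        seqs <- spaces[[sp]]
        if (sp == "tRNA") {
            # mirror the documented collapsing of identical mature sequences
            keep <- !duplicated(as.character(seqs))
            seqs <- seqs[keep]
        }
        for (i in seq_along(seqs)) {
            h <- scan_seq(as.character(seqs[[i]]), read, max_mm)
            if (!is.null(h))
                out <- rbind(out, data.frame(space = sp,
                                             record_id = names(seqs)[i],
                                             start = h$start, strand = "+",
                                             mm = h$mm))
        }
    }
    for (i in seq_along(refset@genome)) {
        ctg <- names(refset@genome)[i]
        s <- as.character(refset@genome[[i]])
        n <- nchar(s)
        h <- scan_seq(s, read, max_mm)
        if (!is.null(h))
            out <- rbind(out, data.frame(space = "genome", record_id = ctg,
                                         start = h$start, strand = "+",
                                         mm = h$mm))
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        h <- scan_seq(rc, read, max_mm)
        if (!is.null(h))
            out <- rbind(out, data.frame(space = "genome", record_id = ctg,
                                         start = n - h$start - nchar(read) + 2L,
                                         strand = "-", mm = h$mm))
    }
    out
}

# independent class-priority oracle built on oracle_hits
oracle_class <- function(read, refset, max_mm = 0L) {
    h <- oracle_hits(read, refset, max_mm)
    if (is.null(h)) return("unassigned")
    for (cl in c("rRNA", "miRNA", "tRNA", "piRNA"))
        if (any(h$space == cl)) return(cl)
    g <- h[h$space == "genome", , drop = FALSE]
    g <- g[g$mm == min(g$mm), , drop = FALSE]
    genes <- refset@genes
    labels <- vapply(seq_len(nrow(g)), function(i) {
        rs <- g$start[i]; re <- g$start[i] + nchar(read) - 1L
        ov <- genes$contig == g$record_id[i] & genes$start <= re &
            genes$end >= rs
        if (!any(ov)) return("other_genomic")
        if (any(genes$strand[ov] != g$strand[i])) "endo_siRNA" else "mRNA_frag"
    }, "")
    if (any(labels == "endo_siRNA")) "endo_siRNA"
    else if (any(labels == "mRNA_frag")) "mRNA_frag"
    else "other_genomic"
}

# hand implementation of leftmost-adapter-prefix trimming for oracle checks
oracle_trim <- function(seq, adapter, min_overlap = 6L) {
    n <- nchar(seq)
    for (i in seq_len(max(n - min_overlap + 1L, 0L))) {
        k <- min(n - i + 1L, nchar(adapter))
        if (k >= min_overlap &&
            substr(seq, i, i + k - 1L) == substr(adapter, 1L, k))
            return(substr(seq, 1L, i - 1L))
    }
    seq
}
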