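#' Load a composition profile from YAML
#'
#' @param path YAML file; see the packaged profiles under
#'   \code{system.file("extdata/profiles", package = "tdrprofiler")} for the
#'   schema.
#' @param read_count,seed Optional overrides.
#' @return A \linkS4class{CompositionProfile}.
#' @export
loadCompositionProfile <- function(path, read_count = NULL, seed = NULL) {
    y <- yaml::read_yaml(path)
    fm <- y$fragment_model
    frag <- new("FragmentModel",
                fivePrimeFraction = fm$five_prime_fraction,
                halfLengthMean = fm$half_length_mean,
                halfLengthSd = fm$half_length_sd,
                shortLengthMean = fm$short_length_mean,
                shortLengthSd = fm$short_length_sd,
                longModeWeight = fm$long_mode_weight,
                isoacceptorWeights = unlist(fm$isoacceptor_weights))
    sm <- y$sirna_model
    new("CompositionProfile",
        name = y$name,
        classFractions = unlist(y$class_fractions)[PROFILE_CLASSES],
        fragmentModel = frag,
        rrnaModel = y$rrna_model,
        sirnaModel = list(lengthWeights = unlist(sm$length_weights),
                          gFraction = sm$g_fraction),
        readCount = as.integer(read_count %||% y$read_count),
        seed = as.integer(seed %||% y$seed))
}

#' Packaged composition profiles
#'
#' Fixture profiles whose tDR class fraction and 5' half fraction are set to
#' the study conditions they emulate: \code{wt_sperm} (tDR 13.8\% of
#' genome-mapping reads, 62\% 5'), \code{wt_male} (3.3\%, 56\%),
#' \code{rnst2_del_male} (8.6\%, 86\%), \code{rnst2_het_male} (3.5\%,
#' 62.3\%), \code{rnst2_het_female} (2.2\%, tRNA-half mode dominated).
#' Remaining parameters (length means/SDs, rRNA fragment skew, class make-up
#' of the non-tDR remainder) are fixture choices recorded in the YAML files.
#'
#' @param name One of the profile names above.
#' @param read_count,seed Optional overrides of the packaged values.
#' @return A \linkS4class{CompositionProfile}.
#' @export
compositionProfile <- function(name, read_count = NULL, seed = NULL) {
    path <- system.file("extdata", "profiles", paste0(name, ".yaml"),
                        package = "tdrprofiler")
    if (path == "")
        stop("no packaged composition profile named '", name, "'")
    loadCompositionProfile(path, read_count = read_count, seed = seed)
}

sample_idx <- function(n, size, prob = NULL) {
    sample.int(n, size, replace = TRUE, prob = prob)
}

#' Simulate a small-RNA library from a composition profile
#'
#' Reads are drawn per the profile's class fractions. tDR reads are contiguous
#' substrings of mature tRNAs anchored at position 1 (5') or at the CCA
#' terminus (3'), with lengths from the two-mode fragment model clipped to
#' 18-40 nt; rRNA fragments are uniform-start substrings of rRNA records with
#' lengths skewed small; miRNA and piRNA reads are full-length records;
#' endo-siRNA reads are antisense substrings of annotated genes (22/26 nt,
#' biased to a 5' G); mRNA fragments are sense substrings of genes;
#' unassigned reads are random sequences verified absent from every reference.
#' Ground-truth labels are recorded for every read.
#'
#' @param profile A \linkS4class{CompositionProfile}.
#' @param refset A \linkS4class{ReferenceSet} with at least one usable record
#'   for every class of nonzero fraction.
#' @param seed Overrides the profile seed.
#' @return A \linkS4class{SyntheticLibrary}.
#' @export
simulateSmallRnaReads <- function(profile, refset, seed = profile@seed) {
    validObject(profile)
    n <- profile@readCount
    f <- profile@classFractions
    check_usable(profile, refset)
    with_seed(seed, {
        cls <- sample(names(f), n, replace = TRUE, prob = f)
        seqs <- character(n)
        src <- rep(NA_character_, n)
        half <- rep(NA_character_, n)
        for (cl in unique(cls)) {
            idx <- which(cls == cl)
            gen <- switch(cl,
                tDR = gen_tdr(length(idx), profile@fragmentModel, refset),
                rRNA_frag = gen_rrna(length(idx), profile@rrnaModel, refset),
                miRNA = gen_full(length(idx), refset@classes$miRNA),
                piRNA = gen_full(length(idx), refset@classes$piRNA),
                endo_siRNA = gen_sirna(length(idx), profile@sirnaModel, refset),
                mRNA_frag = gen_mrna(length(idx), refset),
                unassigned = gen_unassigned(length(idx), refset))
            seqs[idx] <- gen$seq
            src[idx] <- gen$source
            if (!is.null(gen$half)) half[idx] <- gen$half
        }
        reads <- data.frame(
            read_id = sprintf("read_%07d", seq_len(n)),
            sequence = seqs, true_class = cls, true_source = src,
            true_half = half, stringsAsFactors = FALSE)
        new("SyntheticLibrary", reads = reads, profile = profile)
    })
}

check_usable <- function(profile, refset) {
    f <- profile@classFractions
    avail <- c(rRNA_frag = length(refset@classes$rRNA),
               tDR = nrow(refset@trnas),
               miRNA = length(refset@classes$miRNA),
               piRNA = length(refset@classes$piRNA),
               endo_siRNA = nrow(refset@genes),
               mRNA_frag = nrow(refset@genes),
               unassigned = 1L)
    bad <- names(f)[f > 0 & avail[names(f)] == 0L]
    if (length(bad))
        stop("class fraction > 0 with no usable reference records: ",
             paste(bad, collapse = ", "))
}

gen_tdr <- function(k, fm, refset) {
    tr <- refset@trnas
    iso <- sample(names(fm@isoacceptorWeights), k, replace = TRUE,
                  prob = fm@isoacceptorWeights)
    fam <- split(seq_len(nrow(tr)), tr$isoacceptor)
    missing <- setdiff(unique(iso), names(fam))
    if (length(missing))
        stop("fragment model weights name unknown isoacceptor(s): ",
             paste(missing, collapse = ", "))
    ri <- integer(k)
    for (fname in unique(iso)) {
        sel <- iso == fname
        members <- fam[[fname]]
        ri[sel] <- members[sample_idx(length(members), sum(sel))]
    }
    long <- stats::runif(k) < fm@longModeWeight
    len <- round(stats::rnorm(k,
                              ifelse(long, fm@halfLengthMean, fm@shortLengthMean),
                              ifelse(long, fm@halfLengthSd, fm@shortLengthSd)))
    len <- pmin(pmax(len, 18L), 40L, tr$length[ri])
    five <- stats::runif(k) < fm@fivePrimeFraction
    L <- tr$length[ri]
    seqs <- ifelse(five,
                   substring(tr$sequence[ri], 1L, len),
                   substring(tr$sequence[ri], L - len + 1L, L))
    list(seq = seqs, source = tr$trna_id[ri],
         half = ifelse(five, "five_prime", "three_prime"))
}

gen_rrna <- function(k, rrna_model, refset) {
    recs <- refset@classes$rRNA
    w <- Biostrings::width(recs)
    ri <- sample_idx(length(recs), k, prob = w)
    len <- round(stats::rnorm(k, rrna_model$length_mean %||% 22,
                              rrna_model$length_sd %||% 4))
    len <- pmin(pmax(len, 18L), 40L, w[ri])
    start <- 1L + floor(stats::runif(k) * (w[ri] - len + 1L))
    seqs <- substring(as.character(recs)[ri], start, start + len - 1L)
    list(seq = seqs, source = names(recs)[ri])
}

gen_full <- function(k, recs) {
    ri <- sample_idx(length(recs), k)
    list(seq = as.character(recs)[ri], source = names(recs)[ri])
}

gene_plus_seq <- function(refset) {
    ge <- refset@genes
    contigs <- as.character(refset@genome)
    substring(contigs[ge$contig], ge$start, ge$end)
}

gen_sirna <- function(k, sm, refset) {
    ge <- refset@genes
    gseq <- gene_plus_seq(refset)
    lens <- as.integer(names(sm$lengthWeights))
    len <- lens[sample_idx(length(lens), k, prob = sm$lengthWeights)]
    gi <- sample_idx(nrow(ge), k)
    force_g <- stats::runif(k) < sm$gFraction
    draw <- function(sel) {
        glen <- nchar(gseq[gi[sel]])
        p <- 1L + floor(stats::runif(length(sel)) * (glen - len[sel] + 1L))
        sub <- substring(gseq[gi[sel]], p, p + len[sel] - 1L)
        # antisense to the mRNA: reads on "+" genes come from the "-" strand
        ifelse(ge$strand[gi[sel]] == "+", revcomp_chr(sub), sub)
    }
    seqs <- draw(seq_len(k))
    # rejection-sample positions until the biased subset starts with G
    for (i in 1:60) {
        redo <- which(force_g & substring(seqs, 1L, 1L) != "G")
        if (!length(redo)) break
        seqs[redo] <- draw(redo)
    }
    list(seq = seqs, source = ge$gene_id[gi])
}

gen_mrna <- function(k, refset, length_mean = 24, length_sd = 4) {
    ge <- refset@genes
    gseq <- gene_plus_seq(refset)
    gi <- sample_idx(nrow(ge), k)
    len <- round(stats::rnorm(k, length_mean, length_sd))
    len <- pmin(pmax(len, 18L), 40L)
    glen <- nchar(gseq[gi])
    p <- 1L + floor(stats::runif(k) * (glen - len + 1L))
    sub <- substring(gseq[gi], p, p + len - 1L)
    seqs <- ifelse(ge$strand[gi] == "+", sub, revcomp_chr(sub))
    list(seq = seqs, source = ge$gene_id[gi])
}

gen_unassigned <- function(k, refset) {
    haystack <- paste(c(as.character(refset@genome),
                        revcomp_chr(as.character(refset@genome)),
                        unlist(lapply(refset@classes, as.character))),
                      collapse = "|")
    nts <- c("A", "C", "G", "T")
    draw <- function(m) {
        len <- sample_idx(23L, m) + 17L
        vapply(len, function(L)
            paste(nts[sample_idx(4L, L)], collapse = ""), "")
    }
    seqs <- draw(k)
    for (i in 1:20) {
        clash <- which(vapply(seqs, function(s)
            grepl(s, haystack, fixed = TRUE), TRUE))
        if (!length(clash)) break
        seqs[clash] <- draw(length(clash))
    }
    list(seq = seqs, source = rep(NA_character_, k))
}

#' Library accessors
#'
#' @param library A \linkS4class{SyntheticLibrary}.
#' @return \code{libraryReads}: the reads + truth \code{data.frame};
#'   \code{libraryProfile}: the generating profile.
#' @export
libraryReads <- function(library) library@reads

#' @rdname libraryReads
#' @export
libraryProfile <- function(library) library@profile

#' Write a library as 4-line FASTQ (constant Phred33 quality)
#'
#' @param library A \linkS4class{SyntheticLibrary} or a \code{data.frame}
#'   with \code{read_id}, \code{sequence}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFastq <- function(library, path) {
    reads <- if (is(library, "SyntheticLibrary")) library@reads else library
    lines <- character(4L * nrow(reads))
    lines[seq(1, by = 4, length.out = nrow(reads))] <- paste0("@", reads$read_id)
    lines[seq(2, by = 4, length.out = nrow(reads))] <- reads$sequence
    lines[seq(3, by = 4, length.out = nrow(reads))] <- "+"
    lines[seq(4, by = 4, length.out = nrow(reads))] <-
        strrep("I", nchar(reads$sequence))
    writeLines(lines, path)
    invisible(path)
}

#' Read a 4-line FASTQ into a reads data.frame
#'
#' @param path FASTQ path.
#' @return \code{data.frame} with \code{read_id}, \code{sequence}.
#' @export
readFastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               sequence = as.character(x), stringsAsFactors = FALSE)
}

#' @rdname writeFastq
#' @export
writeTruth <- function(library, path) {
    utils::write.table(library@reads, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
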