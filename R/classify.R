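#' Trim 3' adapters and size-filter reads
#'
#' The 3' adapter is removed at the leftmost position where the remainder of
#' the read matches a prefix of the adapter of at least \code{min_overlap} nt
#' (the read may end before the full adapter). Reads outside
#' \code{[min_len, max_len]} after trimming are discarded.
#'
#' @param reads \code{data.frame} with columns \code{read_id},
#'   \code{sequence}.
#' @param adapter Adapter sequence (5' end ligated to the read's 3' end).
#' @param min_len,max_len Retained size range, default 18-40 nt.
#' @param min_overlap Minimum adapter prefix length to call a match.
#' @return Filtered \code{data.frame} of trimmed reads.
#' @export
trimAndFilter <- function(reads, adapter, min_len = 18L, max_len = 40L,
                          min_overlap = 6L) {
    stopifnot(nchar(adapter) >= 1L)
    adapter <- normalize_nucleotides(adapter, "adapter")
    seqs <- toupper(reads$sequence)
    trimmed <- vapply(seqs, function(s) {
        n <- nchar(s)
        for (i in seq_len(max(n - min_overlap + 1L, 0L))) {
            k <- min(n - i + 1L, nchar(adapter))
            if (k >= min_overlap &&
                substring(s, i, i + k - 1L) == substring(adapter, 1L, k))
                return(substring(s, 1L, i - 1L))
        }
        s
    }, "", USE.NAMES = FALSE)
    keep <- nchar(trimmed) >= min_len & nchar(trimmed) <= max_len
    data.frame(read_id = reads$read_id[keep], sequence = trimmed[keep],
               stringsAsFactors = FALSE)
}

#' Assign reads to small-RNA classes by sequential class priority
#'
#' Each read is matched against the class references in the fixed priority
#' order rRNA, miRNA, tRNA, piRNA: the first class with at least one hit at
#' the allowed mismatch level wins. Reads with no class hit are matched to the
#' genome (both strands): an antisense overlap of an annotated gene gives
#' \code{endo_siRNA}, a sense overlap \code{mRNA_frag}, a genomic hit with
#' neither \code{other_genomic}; reads matching nothing are
#' \code{unassigned}. Within the winning class, minimal-mismatch hits share
#' weight equally. When a genomic read overlaps genes on both strands the
#' antisense call (endo_siRNA) wins.
#'
#' @param reads \code{data.frame} with columns \code{read_id},
#'   \code{sequence}.
#' @param index A \linkS4class{SequenceIndex} built from \code{refset}.
#' @param refset The \linkS4class{ReferenceSet} behind the index.
#' @param max_mismatches Defaults to the index setting.
#' @return \code{data.frame} with one row per (read, target): \code{read_id},
#'   \code{length}, \code{first_nt}, \code{class}, \code{record_id},
#'   \code{start}, \code{strand}, \code{mm}, \code{weight}, \code{gene_id}
#'   (the overlapped gene for endo_siRNA/mRNA_frag targets, else NA).
#'   Unassigned reads keep one row with NA target and weight 1.
#' @export
classifyReads <- function(reads, index, refset,
                          max_mismatches = index@maxMismatches) {
    useq <- unique(reads$sequence)
    hits <- queryIndex(index, useq, max_mismatches)
    ucls <- classify_unique(useq, hits, refset)
    out <- ucls[data.table::data.table(read_id = reads$read_id,
                                       seq = reads$sequence),
                on = "seq", allow.cartesian = TRUE]
    out[, `:=`(length = nchar(seq), first_nt = substring(seq, 1L, 1L))]
    data.table::setcolorder(out, c("read_id", "length", "first_nt", "class",
                                   "record_id", "start", "strand", "mm",
                                   "weight", "gene_id", "seq"))
    as.data.frame(out[, !"seq"][order(match(read_id, reads$read_id))])
}

# classify unique sequences given their index hits; returns a data.table keyed
# by seq with one row per retained target
classify_unique <- function(useq, hits, refset) {
    res <- list()
    remaining <- useq
    for (cl in SMALL_RNA_CLASSES) {
        h <- hits[hits$space == cl & hits$seq %in% remaining, ]
        if (nrow(h)) {
            h <- data.table::as.data.table(h)
            h[, minmm := min(mm), by = seq]
            h <- h[mm == minmm][, minmm := NULL]
            h[, `:=`(class = cl, weight = 1 / .N, gene_id = NA_character_),
              by = seq]
            res[[cl]] <- h[, .(seq, class, record_id, start, strand, mm,
                               weight, gene_id)]
            remaining <- setdiff(remaining, unique(h$seq))
        }
    }
    g <- hits[hits$space == "genome" & hits$seq %in% remaining, ]
    if (nrow(g)) {
        g <- data.table::as.data.table(g)
        g[, minmm := min(mm), by = seq]
        g <- g[mm == minmm][, minmm := NULL]
        g <- annotate_gene_overlap(g, refset)
        g[, cls_hit := ifelse(!is.na(gene_id) & orientation == "antisense",
                              "endo_siRNA",
                       ifelse(!is.na(gene_id), "mRNA_frag", "other_genomic"))]
        prio <- c(endo_siRNA = 1L, mRNA_frag = 2L, other_genomic = 3L)
        g[, class := names(prio)[min(prio[cls_hit])], by = seq]
        g <- g[cls_hit == class]
        g[, weight := 1 / .N, by = seq]
        res$genome <- g[, .(seq, class, record_id, start, strand, mm, weight,
                            gene_id)]
        remaining <- setdiff(remaining, unique(g$seq))
    }
    if (length(remaining)) {
        res$unassigned <- data.table::data.table(
            seq = remaining, class = "unassigned", record_id = NA_character_,
            start = NA_integer_, strand = NA_character_, mm = NA_integer_,
            weight = 1, gene_id = NA_character_)
    }
    out <- data.table::rbindlist(res)
    data.table::setkey(out, seq)
    out
}

# label each genome hit with the overlapped gene (if any) and orientation
annotate_gene_overlap <- function(g, refset) {
    genes <- refset@genes
    g[, gene_id := NA_character_]
    g[, orientation := NA_character_]
    if (!nrow(genes) || !nrow(g)) return(g)
    reads_gr <- GenomicRanges::GRanges(
        g$record_id, IRanges::IRanges(g$start, g$start + nchar(g$seq) - 1L),
        strand = g$strand)
    genes_gr <- GenomicRanges::GRanges(
        genes$contig, IRanges::IRanges(genes$start, genes$end),
        strand = genes$strand)
    ov <- GenomicRanges::findOverlaps(reads_gr, genes_gr, ignore.strand = TRUE)
    if (length(ov)) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        same <- g$strand[qh] == genes$strand[sh]
        # antisense overlap preferred when a hit touches genes on both strands
        ord <- order(qh, same)  # antisense (FALSE) sorts first
        first <- !duplicated(qh[ord])
        qi <- qh[ord][first]; si <- sh[ord][first]
        g$gene_id[qi] <- genes$gene_id[si]
        g$orientation[qi] <- ifelse(g$strand[qi] == genes$strand[si],
                                    "sense", "antisense")
    }
    g
}

#' Classify a single read
#'
#' Convenience wrapper around \code{\link{classifyReads}}.
#' @inheritParams classifyReads
#' @param read \code{list} or one-row \code{data.frame} with \code{read_id},
#'   \code{sequence}.
#' @return One assignment \code{data.frame} (possibly several target rows).
#' @export
assignClass <- function(read, index, refset,
                        max_mismatches = index@maxMismatches) {
    classifyReads(data.frame(read_id = read$read_id,
                             sequence = read$sequence),
                  index, refset, max_mismatches)
}

#' Sum weighted read counts per class
#'
#' @param assignments Output of \code{\link{classifyReads}}.
#' @return A \linkS4class{ClassCounts}: weighted counts over the seven
#'   assigned classes; \code{totalGenomeMapping} is their sum (reads matching
#'   only a class reference still count as genome-mapping) and
#'   \code{totalInput} the number of distinct input reads.
#' @export
countClasses <- function(assignments) {
    a <- data.table::as.data.table(assignments)
    assigned <- a[class != "unassigned",
                  .(count = sum(weight)), by = class]
    counts <- stats::setNames(numeric(length(ASSIGNED_CLASSES)),
                              ASSIGNED_CLASSES)
    counts[assigned$class] <- assigned$count
    new("ClassCounts", counts = counts,
        totalGenomeMapping = sum(counts),
        totalInput = length(unique(a$read_id)))
}

#' Reads-per-million normalization
#'
#' rpm = 1e6 * count / denominator, where the denominator is total
#' genome-mapping reads (\code{"genome"}), genome-mapping minus rRNA-mapping
#' reads (\code{"genome_minus_rRNA"}), or the weighted total of one class
#' (\code{"class_total"}).
#'
#' @param counts A \linkS4class{ClassCounts}, or a named numeric of feature
#'   counts together with \code{class_counts} supplying the denominators.
#' @param denominator_kind One of \code{genome}, \code{genome_minus_rRNA},
#'   \code{class_total}.
#' @param class_label For \code{class_total}: which class supplies the
#'   denominator.
#' @param class_counts \linkS4class{ClassCounts} carrying denominators when
#'   \code{counts} is a plain named vector.
#' @return A \linkS4class{NormalizedCounts}.
#' @export
normalizeCounts <- function(counts,
                            denominator_kind = c("genome",
                                                 "genome_minus_rRNA",
                                                 "class_total"),
                            class_label = NULL, class_counts = NULL) {
    denominator_kind <- match.arg(denominator_kind)
    cc <- if (is(counts, "ClassCounts")) counts else class_counts
    if (is.null(cc))
        stop("need a ClassCounts object to derive the denominator")
    denom <- switch(denominator_kind,
        genome = cc@totalGenomeMapping,
        genome_minus_rRNA = cc@totalGenomeMapping - cc@counts[["rRNA"]],
        class_total = {
            if (is.null(class_label))
                stop("class_total normalization needs class_label")
            cc@counts[[class_label]]
        })
    if (!isTRUE(denom > 0))
        stop("zero denominator for ", denominator_kind, " normalization")
    values <- if (is(counts, "ClassCounts")) counts@counts else counts
    new("NormalizedCounts", values = 1e6 * values / denom,
        denominatorKind = denominator_kind, denominator = denom)
}

#' @rdname normalizeCounts
#' @param x A \linkS4class{NormalizedCounts}.
#' @export
rpmValues <- function(x) x@values

#' Per-class percentages of genome-mapping reads
#'
#' @param counts A \linkS4class{ClassCounts}.
#' @return Named numeric, percentages summing to 100.
#' @export
classPercentages <- function(counts) {
    100 * counts@counts / counts@totalGenomeMapping
}

#' @rdname countClasses
#' @param counts A \linkS4class{ClassCounts}.
#' @export
totalGenomeMapping <- function(counts) counts@totalGenomeMapping

#' @rdname countClasses
#' @export
classCountValues <- function(counts) counts@counts
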