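#' Construct a ReferenceSet from in-memory components
#'
#' Sequences are uppercased and U is converted to T. Mature tRNA records whose
#' sequence lacks the terminal CCA get it appended (with \code{length} updated);
#' all other invariant violations are rejected, never silently repaired.
#'
#' @param genome Named character vector or \link[Biostrings]{DNAStringSet} of
#'   contigs.
#' @param classes Named list (\code{rRNA}, \code{miRNA}, \code{tRNA},
#'   \code{piRNA}) of named character vectors or \code{DNAStringSet}s. The
#'   \code{tRNA} entry may be omitted: it is then derived from \code{trnas}.
#' @param trnas \code{data.frame} with columns \code{trna_id},
#'   \code{isoacceptor}, \code{sequence}, \code{anticodon_start},
#'   \code{anticodon_end} (1-based inclusive on the mature sense sequence).
#' @param genes \code{data.frame} with columns \code{gene_id}, \code{contig},
#'   \code{start}, \code{end}, \code{strand}.
#' @return A validated \linkS4class{ReferenceSet}.
#' @export
makeReferenceSet <- function(genome, classes, trnas,
                             genes = data.frame(gene_id = character(),
                                                contig = character(),
                                                start = integer(),
                                                end = integer(),
                                                strand = character())) {
    if (!is(genome, "DNAStringSet")) {
        genome <- stats::setNames(normalize_nucleotides(unlist(genome), "contig"),
                                  names(genome))
        genome <- Biostrings::DNAStringSet(genome)
    }
    trnas <- prepare_trna_table(trnas)
    cls <- list()
    for (cl in SMALL_RNA_CLASSES) {
        if (cl == "tRNA" && is.null(classes[[cl]])) {
            x <- stats::setNames(trnas$sequence, trnas$trna_id)
        } else {
            x <- classes[[cl]]
            if (is.null(x)) x <- character()
            if (is(x, "DNAStringSet")) x <- stats::setNames(as.character(x), names(x))
            x <- stats::setNames(normalize_nucleotides(x, paste(cl, "record")),
                                 names(x))
        }
        cls[[cl]] <- Biostrings::DNAStringSet(x)
    }
    new("ReferenceSet", genome = genome, classes = cls, trnas = trnas,
        genes = as.data.frame(genes))
}

prepare_trna_table <- function(trnas) {
    trnas <- as.data.frame(trnas)
    need <- c("trna_id", "isoacceptor", "sequence", "anticodon_start",
              "anticodon_end")
    miss <- setdiff(need, names(trnas))
    if (length(miss))
        stop("tRNA table lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(trnas) == 0L) {
        trnas$isodecoder_index <- integer()
        trnas$length <- integer()
        return(trnas[c("trna_id", "isoacceptor", "isodecoder_index", "sequence",
                       "anticodon_start", "anticodon_end", "length")])
    }
    bad <- is.na(trnas$anticodon_start) | is.na(trnas$anticodon_end)
    if (any(bad))
        stop("missing anticodon coordinates for tRNA '",
             trnas$trna_id[which(bad)[1L]], "'")
    seqs <- stats::setNames(trnas$sequence, trnas$trna_id)
    trnas$sequence <- unname(normalize_nucleotides(seqs, "tRNA"))
    no_cca <- substring(trnas$sequence, nchar(trnas$sequence) - 2L) != "CCA"
    trnas$sequence[no_cca] <- paste0(trnas$sequence[no_cca], "CCA")
    trnas$length <- nchar(trnas$sequence)
    if (is.null(trnas$isodecoder_index))
        trnas$isodecoder_index <- stats::ave(seq_len(nrow(trnas)),
                                             trnas$isoacceptor,
                                             FUN = seq_along)
    span <- trnas$anticodon_end - trnas$anticodon_start
    if (any(span != 2L))
        stop("anticodon_end - anticodon_start must be 2 (tRNA '",
             trnas$trna_id[which(span != 2L)[1L]], "')")
    trnas[c("trna_id", "isoacceptor", "isodecoder_index", "sequence",
            "anticodon_start", "anticodon_end", "length")]
}

#' Load a ReferenceSet from files
#'
#' @param genome_fasta FASTA of genome contigs.
#' @param class_fastas Named list/vector of FASTA paths for \code{rRNA},
#'   \code{miRNA} and \code{piRNA} (tRNAs come from \code{trna_table}).
#' @param trna_table TSV with columns \code{trna_id}, \code{isoacceptor},
#'   \code{sequence}, \code{anticodon_start}, \code{anticodon_end}.
#' @param gene_annotation TSV with columns \code{gene_id}, \code{contig},
#'   \code{start}, \code{end}, \code{strand}, or a GFF3 file (gene features;
#'   \code{ID=} or \code{gene_id=} attribute).
#' @return A \linkS4class{ReferenceSet}.
#' @export
loadReferenceSet <- function(genome_fasta, class_fastas, trna_table,
                             gene_annotation = NULL) {
    genome <- Biostrings::readDNAStringSet(genome_fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    classes <- lapply(class_fastas, function(p) {
        x <- Biostrings::readDNAStringSet(p)
        names(x) <- sub("\\s.*$", "", names(x))
        x
    })
    trnas <- utils::read.delim(trna_table, stringsAsFactors = FALSE)
    genes <- if (is.null(gene_annotation)) {
        data.frame(gene_id = character(), contig = character(),
                   start = integer(), end = integer(), strand = character())
    } else read_gene_annotation(gene_annotation)
    makeReferenceSet(genome, classes, trnas, genes)
}

read_gene_annotation <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("^##gff", first) || length(strsplit(first, "\t")[[1]]) == 9L) {
        gff <- utils::read.delim(path, header = FALSE, comment.char = "#",
                                 stringsAsFactors = FALSE)
        gff <- gff[gff[[3]] == "gene", , drop = FALSE]
        ids <- sub(".*(?:ID|gene_id)=([^;]+).*", "\\1", gff[[9]])
        data.frame(gene_id = ids, contig = gff[[1]],
                   start = as.integer(gff[[4]]), end = as.integer(gff[[5]]),
                   strand = gff[[7]], stringsAsFactors = FALSE)
    } else {
        g <- utils::read.delim(path, stringsAsFactors = FALSE)
        g[c("gene_id", "contig", "start", "end", "strand")]
    }
}

#' Write a ReferenceSet to a directory of plain-text files
#'
#' Writes genome.fa, rRNA.fa, miRNA.fa, piRNA.fa, trnas.tsv and genes.tsv so
#' that \code{\link{loadReferenceSet}} round-trips the object.
#' @param refset A \linkS4class{ReferenceSet}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeReferenceSet <- function(refset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(refset@genome, file.path(dir, "genome.fa"))
    for (cl in c("rRNA", "miRNA", "piRNA"))
        Biostrings::writeXStringSet(refset@classes[[cl]],
                                    file.path(dir, paste0(cl, ".fa")))
    utils::write.table(refset@trnas, file.path(dir, "trnas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(refset@genes, file.path(dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeReferenceSet
#' @export
readReferenceSet <- function(dir) {
    loadReferenceSet(file.path(dir, "genome.fa"),
                     list(rRNA = file.path(dir, "rRNA.fa"),
                          miRNA = file.path(dir, "miRNA.fa"),
                          piRNA = file.path(dir, "piRNA.fa")),
                     file.path(dir, "trnas.tsv"),
                     file.path(dir, "genes.tsv"))
}

#' Accessors for ReferenceSet components
#'
#' @param refset A \linkS4class{ReferenceSet}.
#' @return \code{genomeContigs}: a \code{DNAStringSet}; \code{classRecords}: a
#'   \code{DNAStringSet} for one class; \code{matureTRNAs} and
#'   \code{geneAnnotations}: \code{data.frame}s.
#' @export
genomeContigs <- function(refset) refset@genome

#' @rdname genomeContigs
#' @param class_label One of rRNA, miRNA, tRNA, piRNA.
#' @export
classRecords <- function(refset, class_label) {
    stopifnot(class_label %in% SMALL_RNA_CLASSES)
    refset@classes[[class_label]]
}

#' @rdname genomeContigs
#' @export
matureTRNAs <- function(refset) refset@trnas

#' @rdname genomeContigs
#' @export
geneAnnotations <- function(refset) refset@genes

# enumerate all substrings of lengths lo..hi of one sequence as a data.table
enumerate_substrings <- function(seq_chr, record_id, lo, hi) {
    n <- nchar(seq_chr)
    out <- vector("list", hi - lo + 1L)
    k <- 0L
    for (L in lo:hi) {
        if (n < L) next
        k <- k + 1L
        starts <- seq_len(n - L + 1L)
        out[[k]] <- data.table::data.table(
            seq = substring(seq_chr, starts, starts + L - 1L),
            record_id = record_id, start = starts)
    }
    data.table::rbindlist(out[seq_len(k)])
}

#' Build the class/genome substring index used for read assignment
#'
#' Enumerates every substring in the read-length range of each class reference
#' (sense strand only: reads are cloned from the mature RNA) and of the genome
#' (both strands: antisense endo-siRNA calls need minus-strand hits). Identical
#' mature tRNA sequences are collapsed to one representative before indexing.
#'
#' @param refset A \linkS4class{ReferenceSet}.
#' @param max_mismatches 0 or 1; 1-mismatch queries enumerate the read's
#'   substitution neighbourhood against the exact index.
#' @param length_range Read lengths to index, default \code{c(18, 40)}.
#' @return A \linkS4class{SequenceIndex}.
#' @export
buildClassIndex <- function(refset, max_mismatches = 0L,
                            length_range = c(18L, 40L)) {
    stopifnot(max_mismatches %in% c(0L, 1L))
    lo <- as.integer(length_range[1]); hi <- as.integer(length_range[2])
    if (sum(vapply(refset@classes, length, 1L)) == 0L)
        stop("cannot build an index over empty references")

    collapse <- collapse_trnas(refset@trnas)
    classTables <- list()
    for (cl in SMALL_RNA_CLASSES) {
        seqs <- refset@classes[[cl]]
        if (cl == "tRNA") {
            reps <- collapse$reps
            seqs <- Biostrings::DNAStringSet(stats::setNames(reps$sequence,
                                                             reps$rep_id))
        }
        tabs <- lapply(seq_along(seqs), function(i)
            enumerate_substrings(as.character(seqs[[i]]), names(seqs)[i], lo, hi))
        tab <- data.table::rbindlist(tabs)
        if (nrow(tab)) tab[, strand := "+"] else tab <- empty_hits_dt()
        data.table::setkey(tab, seq)
        classTables[[cl]] <- tab
    }

    gtabs <- list()
    for (i in seq_along(refset@genome)) {
        contig <- names(refset@genome)[i]
        s <- as.character(refset@genome[[i]])
        n <- nchar(s)
        plus <- enumerate_substrings(s, contig, lo, hi)
        if (nrow(plus)) plus[, strand := "+"]
        minus <- enumerate_substrings(revcomp_chr(s), contig, lo, hi)
        if (nrow(minus)) {
            # position i..i+L-1 on the revcomp corresponds to plus-strand
            # leftmost coordinate n - i - L + 2
            minus[, start := n - start - nchar(seq) + 2L]
            minus[, strand := "-"]
        }
        gtabs[[i]] <- data.table::rbindlist(list(plus, minus))
    }
    genomeTable <- data.table::rbindlist(gtabs)
    if (!nrow(genomeTable)) genomeTable <- empty_hits_dt()
    data.table::setkey(genomeTable, seq)

    new("SequenceIndex", classTables = classTables, genomeTable = genomeTable,
        maxMismatches = as.integer(max_mismatches),
        lengthRange = c(lo, hi), collapseMap = collapse$map)
}

empty_hits_dt <- function() {
    data.table::data.table(seq = character(), record_id = character(),
                           start = integer(), strand = character(),
                           key = "seq")
}

# collapse identical mature tRNA sequences to one representative record
collapse_trnas <- function(trnas) {
    if (nrow(trnas) == 0L)
        return(list(reps = data.frame(rep_id = character(),
                                      sequence = character()),
                    map = data.frame(rep_id = character(),
                                     trna_id = character(),
                                     isoacceptor = character())))
    grp <- match(trnas$sequence, unique(trnas$sequence))
    rep_idx <- !duplicated(grp)
    reps <- data.frame(rep_id = trnas$trna_id[rep_idx],
                       sequence = trnas$sequence[rep_idx])
    map <- data.frame(rep_id = reps$rep_id[grp],
                      trna_id = trnas$trna_id,
                      isoacceptor = trnas$isoacceptor,
                      stringsAsFactors = FALSE)
    list(reps = reps, map = map)
}

# all 1-substitution neighbours of each sequence (including itself at mm=0)
mismatch_neighbourhood <- function(seqs) {
    nts <- c("A", "C", "G", "T")
    out <- list(data.table::data.table(query = seqs, variant = seqs, mm = 0L))
    lens <- nchar(seqs)
    for (pos in seq_len(max(lens))) {
        idx <- which(lens >= pos)
        if (!length(idx)) next
        orig <- substring(seqs[idx], pos, pos)
        for (nt in nts) {
            keep <- orig != nt
            if (!any(keep)) next
            v <- seqs[idx][keep]
            substring(v, pos, pos) <- nt
            out[[length(out) + 1L]] <- data.table::data.table(
                query = seqs[idx][keep], variant = v, mm = 1L)
        }
    }
    data.table::rbindlist(out)
}

#' Query the index with read sequences
#'
#' @param index A \linkS4class{SequenceIndex}.
#' @param seqs Character vector of read sequences.
#' @param max_mismatches Defaults to the index's setting.
#' @return \code{data.table} with columns \code{seq} (the query), \code{space}
#'   (class label or \code{"genome"}), \code{record_id}, \code{start},
#'   \code{strand}, \code{mm}. Empty when nothing matches.
#' @export
queryIndex <- function(index, seqs, max_mismatches = index@maxMismatches) {
    stopifnot(max_mismatches %in% c(0L, 1L))
    useqs <- unique(seqs)
    probe <- if (max_mismatches == 0L) {
        data.table::data.table(query = useqs, variant = useqs, mm = 0L)
    } else mismatch_neighbourhood(useqs)
    data.table::setkey(probe, variant)
    spaces <- c(index@classTables, list(genome = index@genomeTable))
    hits <- lapply(names(spaces), function(sp) {
        tab <- spaces[[sp]]
        m <- tab[probe, on = c(seq = "variant"), nomatch = NULL,
                 allow.cartesian = TRUE]
        if (!nrow(m)) return(NULL)
        data.table::data.table(seq = m$query, space = sp,
                               record_id = m$record_id, start = m$start,
                               strand = m$strand, mm = m$mm)
    })
    out <- data.table::rbindlist(hits)
    if (!nrow(out))
        return(data.table::data.table(seq = character(), space = character(),
                                      record_id = character(), start = integer(),
                                      strand = character(), mm = integer()))
    # a sequence may reach the same hit via several neighbourhood probes
    # (mm=0 self plus substitutions reverting elsewhere cannot collide, but a
    # variant can equal the original when the read has N; keep minimal mm)
    out <- out[, .(mm = min(mm)),
               by = .(seq, space, record_id, start, strand)]
    out[]
}
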