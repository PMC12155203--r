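#' @import methods
#' @importFrom S4Vectors metadata
NULL

SMALL_RNA_CLASSES <- c("rRNA", "miRNA", "tRNA", "piRNA")
ASSIGNED_CLASSES <- c(SMALL_RNA_CLASSES, "endo_siRNA", "mRNA_frag", "other_genomic")
ALL_CLASSES <- c(ASSIGNED_CLASSES, "unassigned")
PROFILE_CLASSES <- c("rRNA_frag", "tDR", "miRNA", "piRNA", "endo_siRNA",
                     "mRNA_frag", "unassigned")

#' Reference collection for small-RNA classification
#'
#' Holds the genome contigs, the four class-annotated sequence collections
#' (rRNA, miRNA, tRNA, piRNA), mature tRNA records with anticodon coordinates,
#' and gene intervals used for endo-siRNA / mRNA-fragment calls.
#'
#' Mature tRNA sequences always terminate in the non-templated CCA; records
#' supplied without it have CCA appended at load time (3' tDRs in real
#' libraries end in CCA and would otherwise be unmappable). Anticodon
#' coordinates are 1-based inclusive positions of the anticodon triplet on the
#' mature sense sequence; the isoacceptor name carries the anticodon written
#' 5'->3' (Gly-GCC means triplet GCC at \code{anticodon_start..anticodon_end}).
#'
#' @slot genome A \link[Biostrings]{DNAStringSet} of genome contigs.
#' @slot classes Named list of \code{DNAStringSet}s, one per class
#'   (\code{rRNA}, \code{miRNA}, \code{tRNA}, \code{piRNA}).
#' @slot trnas \code{data.frame} with columns \code{trna_id},
#'   \code{isoacceptor}, \code{isodecoder_index}, \code{sequence},
#'   \code{anticodon_start}, \code{anticodon_end}, \code{length}.
#' @slot genes \code{data.frame} of gene intervals with columns
#'   \code{gene_id}, \code{contig}, \code{start}, \code{end}, \code{strand}
#'   (1-based inclusive).
#' @exportClass ReferenceSet
setClass("ReferenceSet", representation(
    genome = "DNAStringSet",
    classes = "list",
    trnas = "data.frame",
    genes = "data.frame"
))

setValidity("ReferenceSet", function(object) {
    msg <- character()
    gn <- names(object@genome)
    if (length(object@genome) == 0L) msg <- c(msg, "genome has no contigs")
    if (anyDuplicated(gn)) msg <- c(msg, "contig names are not unique")
    if (any(Biostrings::width(object@genome) == 0L))
        msg <- c(msg, "genome contains an empty contig")
    if (!setequal(names(object@classes), SMALL_RNA_CLASSES))
        msg <- c(msg, "classes must be named rRNA, miRNA, tRNA, piRNA")
    for (cl in names(object@classes)) {
        if (anyDuplicated(names(object@classes[[cl]])))
            msg <- c(msg, sprintf("duplicate record ids in class %s", cl))
    }
    tr <- object@trnas
    need <- c("trna_id", "isoacceptor", "isodecoder_index", "sequence",
              "anticodon_start", "anticodon_end", "length")
    if (!all(need %in% names(tr))) {
        msg <- c(msg, "trnas table lacks required columns")
    } else if (nrow(tr) > 0L) {
        if (anyDuplicated(tr$trna_id)) msg <- c(msg, "duplicate trna_id")
        if (any(tr$anticodon_end - tr$anticodon_start != 2L))
            msg <- c(msg, "anticodon must span exactly 3 nt")
        if (any(tr$anticodon_start < 1L | tr$anticodon_end > tr$length))
            msg <- c(msg, "anticodon coordinates out of bounds")
        if (any(nchar(tr$sequence) != tr$length))
            msg <- c(msg, "tRNA length column disagrees with sequence")
        if (any(substring(tr$sequence, tr$length - 2L, tr$length) != "CCA"))
            msg <- c(msg, "mature tRNA sequence must end in CCA")
        anti <- substring(tr$sequence, tr$anticodon_start, tr$anticodon_end)
        named <- sub("^[^-]+-", "", tr$isoacceptor)
        if (any(anti != named))
            msg <- c(msg, "anticodon at stated coordinates disagrees with isoacceptor name")
    }
    ge <- object@genes
    if (nrow(ge) > 0L) {
        if (!all(ge$contig %in% gn)) {
            msg <- c(msg, "gene interval on unknown contig")
        } else {
            w <- stats::setNames(Biostrings::width(object@genome), gn)
            if (any(ge$start < 1L | ge$end > w[ge$contig]))
                msg <- c(msg, "gene interval outside its contig")
        }
        if (!all(ge$strand %in% c("+", "-")))
            msg <- c(msg, "gene strand must be + or -")
    }
    if (length(msg)) msg else TRUE
})

#' Substring lookup index over a ReferenceSet
#'
#' Enumeration index over all substrings (read-length range) of the class
#' references (sense strand only) and of the genome (both strands), supporting
#' exact and 1-mismatch queries. Identical mature tRNA sequences are collapsed
#' to a single representative record before indexing; the membership map keeps
#' isodecoders recoverable.
#'
#' @slot classTables Named list of \code{data.table}s (seq, record_id, start,
#'   strand), one per small-RNA class.
#' @slot genomeTable \code{data.table} (seq, record_id, start, strand) over
#'   genome substrings; minus-strand rows carry plus-strand leftmost starts.
#' @slot maxMismatches Integer, 0 or 1.
#' @slot lengthRange Integer vector of length 2, the indexed read lengths.
#' @slot collapseMap \code{data.frame} mapping representative tRNA record ids
#'   to member isodecoder ids.
#' @exportClass SequenceIndex
setClass("SequenceIndex", representation(
    classTables = "list",
    genomeTable = "ANY",
    maxMismatches = "integer",
    lengthRange = "integer",
    collapseMap = "data.frame"
))

#' Per-class weighted read counts
#'
#' @slot counts Named numeric of weighted read counts over the seven assigned
#'   classes (rRNA, miRNA, tRNA, piRNA, endo_siRNA, mRNA_frag, other_genomic).
#' @slot totalGenomeMapping Sum over the assigned classes. Reads hitting only
#'   a class reference (e.g. a CCA-terminal tDR) count as genome-mapping.
#' @slot totalInput Number of input reads including unassigned.
#' @exportClass ClassCounts
setClass("ClassCounts", representation(
    counts = "numeric",
    totalGenomeMapping = "numeric",
    totalInput = "numeric"
))

setValidity("ClassCounts", function(object) {
    msg <- character()
    if (!setequal(names(object@counts), ASSIGNED_CLASSES))
        msg <- c(msg, "counts must cover exactly the seven assigned classes")
    if (any(object@counts < -1e-9)) msg <- c(msg, "negative class count")
    if (abs(sum(object@counts) - object@totalGenomeMapping) > 1e-6)
        msg <- c(msg, "class counts do not sum to totalGenomeMapping")
    if (object@totalGenomeMapping > object@totalInput + 1e-6)
        msg <- c(msg, "totalGenomeMapping exceeds totalInput")
    if (length(msg)) msg else TRUE
})

#' Reads-per-million normalized counts
#'
#' @slot values Named numeric, rpm per class or feature.
#' @slot denominatorKind One of \code{genome}, \code{genome_minus_rRNA},
#'   \code{class_total}.
#' @slot denominator The count used as denominator.
#' @exportClass NormalizedCounts
setClass("NormalizedCounts", representation(
    values = "numeric",
    denominatorKind = "character",
    denominator = "numeric"
))

#' tDR fragment model for the synthetic library generator
#'
#' A two-mode length mixture: a "half" mode (tRNA-halves, 31-36 nt with a
#' 36 nt shoulder) and a "trimmed" mode (<30 nt fragments), plus the 5'/3'
#' side probability and isoacceptor sampling weights. Generated lengths are
#' clipped to the cloned size range 18-40 nt.
#'
#' @exportClass FragmentModel
setClass("FragmentModel", representation(
    fivePrimeFraction = "numeric",
    halfLengthMean = "numeric",
    halfLengthSd = "numeric",
    shortLengthMean = "numeric",
    shortLengthSd = "numeric",
    longModeWeight = "numeric",
    isoacceptorWeights = "numeric"
))

setValidity("FragmentModel", function(object) {
    msg <- character()
    p <- c(object@fivePrimeFraction, object@longModeWeight)
    if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must be in [0,1]")
    w <- object@isoacceptorWeights
    if (length(w) == 0L || is.null(names(w)))
        msg <- c(msg, "isoacceptorWeights must be a named vector")
    else if (abs(sum(w) - 1) > 1e-6)
        msg <- c(msg, "isoacceptorWeights must sum to 1")
    if (length(msg)) msg else TRUE
})

#' Generative parameters of a synthetic small-RNA library
#'
#' @slot name Profile name.
#' @slot classFractions Named numeric over \code{rRNA_frag, tDR, miRNA,
#'   piRNA, endo_siRNA, mRNA_frag, unassigned}, summing to 1.
#' @slot fragmentModel A \linkS4class{FragmentModel}.
#' @slot rrnaModel List: \code{lengthMean}, \code{lengthSd} (fragment lengths
#'   skewed small, uniform start, first nucleotide follows the reference).
#' @slot sirnaModel List: \code{lengthWeights} (named over 22, 26),
#'   \code{gFraction} (probability of a 5' G), antisense by construction.
#' @slot readCount Number of reads to draw.
#' @slot seed Integer seed (overridable at simulation time).
#' @exportClass CompositionProfile
setClass("CompositionProfile", representation(
    name = "character",
    classFractions = "numeric",
    fragmentModel = "FragmentModel",
    rrnaModel = "list",
    sirnaModel = "list",
    readCount = "integer",
    seed = "integer"
))

setValidity("CompositionProfile", function(object) {
    msg <- character()
    f <- object@classFractions
    if (!setequal(names(f), PROFILE_CLASSES))
        msg <- c(msg, "classFractions must cover exactly the seven profile classes")
    if (any(f < 0)) msg <- c(msg, "negative class fraction")
    if (abs(sum(f) - 1) > 1e-9) msg <- c(msg, "classFractions must sum to 1")
    if (object@readCount <= 0L) msg <- c(msg, "readCount must be positive")
    if (length(msg)) msg else TRUE
})

#' Synthetic small-RNA library with ground truth
#'
#' @slot reads \code{data.frame}: read_id, sequence, true_class, true_source,
#'   true_half (NA unless tDR).
#' @slot profile The generating \linkS4class{CompositionProfile}.
#' @exportClass SyntheticLibrary
setClass("SyntheticLibrary", representation(
    reads = "data.frame",
    profile = "CompositionProfile"
))

setValidity("SyntheticLibrary", function(object) {
    msg <- character()
    if (nrow(object@reads) != object@profile@readCount)
        msg <- c(msg, "read count disagrees with profile readCount")
    if (!all(c("read_id", "sequence", "true_class", "true_source",
               "true_half") %in% names(object@reads)))
        msg <- c(msg, "reads table lacks truth columns")
    if (length(msg)) msg else TRUE
})

#' Generative parameters of a synthetic single-embryo count table
#'
#' Counts are drawn negative-binomially around per-gene baseline means;
#' planted differentially expressed genes have their treatment-condition mean
#' scaled by \code{2^log2fc}. Gene groups (histone, fbxb, hsp, ribosomal) are
#' named member sets used by the group-shift analysis.
#'
#' @exportClass ExpressionProfile
setClass("ExpressionProfile", representation(
    stage = "character",
    geneMeans = "numeric",
    geneLengths = "numeric",
    groups = "list",
    plantedDe = "data.frame",
    dispersion = "numeric",
    nControl = "integer",
    nTreatment = "integer",
    seed = "integer"
))

setValidity("ExpressionProfile", function(object) {
    msg <- character()
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
    if (object@nControl < 2L || object@nTreatment < 2L)
        msg <- c(msg, "need at least 2 embryos per condition")
    if (length(object@geneMeans) != length(object@geneLengths))
        msg <- c(msg, "geneMeans and geneLengths lengths differ")
    if (nrow(object@plantedDe) > 0L &&
        !all(object@plantedDe$gene_id %in% names(object@geneMeans)))
        msg <- c(msg, "planted DE gene absent from geneMeans")
    if (length(msg)) msg else TRUE
})

#' Coordinated shift of a gene group in log2 fold change
#'
#' @slot group Group name.
#' @slot members Member gene ids (after intersecting expressed genes).
#' @slot log2fc Per-member log2 fold changes.
#' @slot medianGroup,medianBackground,medianShift Medians of group, of the
#'   complement, and their difference.
#' @slot ksStatistic,ksP Two-sample Kolmogorov-Smirnov comparison of the group
#'   log2FC distribution against all remaining genes.
#' @exportClass GroupShift
setClass("GroupShift", representation(
    group = "character",
    members = "character",
    log2fc = "numeric",
    medianGroup = "numeric",
    medianBackground = "numeric",
    medianShift = "numeric",
    ksStatistic = "numeric",
    ksP = "numeric"
))

setMethod("show", "ReferenceSet", function(object) {
    cat("ReferenceSet\n")
    cat(sprintf("  genome: %d contig(s), %d nt\n", length(object@genome),
                sum(Biostrings::width(object@genome))))
    for (cl in SMALL_RNA_CLASSES)
        cat(sprintf("  %-6s: %d record(s)\n", cl, length(object@classes[[cl]])))
    cat(sprintf("  mature tRNAs: %d (%d isoacceptor families)\n",
                nrow(object@trnas), length(unique(object@trnas$isoacceptor))))
    cat(sprintf("  genes: %d interval(s)\n", nrow(object@genes)))
})

setMethod("show", "ClassCounts", function(object) {
    cat("ClassCounts\n")
    pct <- 100 * object@counts / max(object@totalGenomeMapping, 1)
    for (cl in ASSIGNED_CLASSES)
        cat(sprintf("  %-13s %12.1f  (%5.2f%% of genome-mapping)\n",
                    cl, object@counts[[cl]], pct[[cl]]))
    cat(sprintf("  genome-mapping %10.1f / %s input reads\n",
                object@totalGenomeMapping, format(object@totalInput)))
})

setMethod("show", "CompositionProfile", function(object) {
    cat(sprintf("CompositionProfile '%s' (%d reads, seed %d)\n",
                object@name, object@readCount, object@seed))
    f <- object@classFractions
    cat("  fractions:", paste(sprintf("%s=%.3f", names(f), f), collapse = " "),
        "\n")
    fm <- object@fragmentModel
    cat(sprintf("  tDR model: 5' %.3f, half %g+/-%g nt (w=%.2f), short %g+/-%g nt\n",
                fm@fivePrimeFraction, fm@halfLengthMean, fm@halfLengthSd,
                fm@longModeWeight, fm@shortLengthMean, fm@shortLengthSd))
})

setMethod("show", "SyntheticLibrary", function(object) {
    cat(sprintf("SyntheticLibrary '%s': %d reads\n", object@profile@name,
                nrow(object@reads)))
    print(round(100 * prop.table(table(object@reads$true_class)), 2))
})

setMethod("show", "GroupShift", function(object) {
    cat(sprintf("GroupShift '%s': %d genes, median log2FC %.3f (background %.3f)\n",
                object@group, length(object@members), object@medianGroup,
                object@medianBackground))
    cat(sprintf("  KS D = %.4f, p = %.3g\n", object@ksStatistic, object@ksP))
})

setMethod("show", "ExpressionProfile", function(object) {
    cat(sprintf("ExpressionProfile stage=%s: %d genes, n=%d vs %d, dispersion %.3g\n",
                object@stage, length(object@geneMeans), object@nControl,
                object@nTreatment, object@dispersion))
    if (nrow(object@plantedDe))
        cat(sprintf("  planted DE: %d up, %d down\n",
                    sum(object@plantedDe$log2fc > 0),
                    sum(object@plantedDe$log2fc < 0)))
})
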