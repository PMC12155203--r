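#' Length by first-nucleotide matrix
#'
#' Counts reads by (length 18-40, first nucleotide A/C/G/T) over a chosen
#' scope: all reads, tRNA-assigned, or rRNA-assigned. The first nucleotide is
#' taken from the read sequence as sequenced, not from the reference. Weighted
#' by multimapping weight within scope; the marginal over nucleotides at a
#' length is the length histogram.
#'
#' @param assignments Output of \code{\link{classifyReads}}.
#' @param scope One of \code{"all"}, \code{"tRNA"}, \code{"rRNA"}.
#' @param length_range Rows of the matrix, default 18-40.
#' @return Numeric matrix, rows = lengths, columns = A, C, G, T.
#' @export
lengthFirstNtMatrix <- function(assignments, scope = c("all", "tRNA", "rRNA"),
                                length_range = c(18L, 40L)) {
    scope <- match.arg(scope)
    a <- data.table::as.data.table(assignments)
    if (scope != "all") a <- a[class == scope]
    lens <- length_range[1]:length_range[2]
    nts <- c("A", "C", "G", "T")
    m <- matrix(0, length(lens), length(nts), dimnames = list(lens, nts))
    if (nrow(a)) {
        tab <- a[first_nt %in% nts & length %in% lens,
                 .(w = sum(weight)), by = .(length, first_nt)]
        m[cbind(match(tab$length, lens), match(tab$first_nt, nts))] <- tab$w
    }
    m
}

# central anticodon position: the split point between 5' and 3' sides
anticodon_split <- function(anticodon_start) anticodon_start + 1L

#' Assign a tRNA-mapping read to the 5' or 3' half
#'
#' The mature tRNA is split at the central anticodon position
#' (\code{anticodon_start + 1}); the read is labelled by the side holding the
#' strict majority of its aligned positions (the split position itself counts
#' to neither side); an exact tie goes to \code{five_prime}.
#'
#' @param start 1-based start of the read on the mature sequence.
#' @param width Aligned length in nt.
#' @param anticodon_start 1-based start of the anticodon triplet.
#' @param trna_length Mature tRNA length (including CCA).
#' @return \code{"five_prime"} or \code{"three_prime"} (vectorized).
#' @export
assignHalf <- function(start, width, anticodon_start, trna_length) {
    end <- start + width - 1L
    if (any(start < 1L | end > trna_length))
        stop("read maps outside the mature tRNA")
    split <- anticodon_split(anticodon_start)
    left <- pmax(0L, pmin(end, split - 1L) - start + 1L)
    right <- pmax(0L, end - pmax(start, split + 1L) + 1L)
    ifelse(right > left, "three_prime", "five_prime")
}

# tRNA-assigned rows joined with the representative record's anticodon info
trna_rows <- function(assignments, refset) {
    a <- data.table::as.data.table(assignments)[class == "tRNA"]
    if (!nrow(a)) return(a)
    tr <- data.table::as.data.table(refset@trnas)
    a <- tr[, .(record_id = trna_id, isoacceptor, anticodon_start,
                trna_length = length)][a, on = "record_id"]
    if (anyNA(a$anticodon_start))
        stop("tRNA assignment targets a record absent from the reference")
    a[, half := assignHalf(start, length, anticodon_start, trna_length)]
    a
}

#' Weighted 5'/3' half fractions over tRNA-assigned reads
#'
#' @param assignments Output of \code{\link{classifyReads}}.
#' @param refset The \linkS4class{ReferenceSet} (anticodon coordinates).
#' @return List with \code{five_prime} and \code{three_prime} percentages
#'   (summing to 100) and \code{n_reads}, the weighted number of tRNA-assigned
#'   reads. With no tRNA reads the fractions are NA and \code{n_reads} 0.
#' @export
halfFractions <- function(assignments, refset) {
    a <- trna_rows(assignments, refset)
    if (!nrow(a))
        return(list(five_prime = NA_real_, three_prime = NA_real_,
                    n_reads = 0))
    w5 <- sum(a$weight[a$half == "five_prime"])
    tot <- sum(a$weight)
    list(five_prime = 100 * w5 / tot, three_prime = 100 * (tot - w5) / tot,
         n_reads = tot)
}

#' Per-position read depth across a mature tRNA isoacceptor
#'
#' Sums weighted coverage over the member isodecoders of one isoacceptor
#' family. Members of equal length are summed positionally. When member
#' lengths differ by at most 2 nt they are right-aligned at the CCA end
#' (the discriminator end is the stable landmark); otherwise the longest
#' member defines the axis and shorter members are left-aligned.
#'
#' @param assignments Output of \code{\link{classifyReads}}.
#' @param refset The \linkS4class{ReferenceSet}.
#' @param isoacceptor Family name, e.g. \code{"Gly-GCC"}.
#' @param align \code{"auto"} applies the rule above; \code{"left"} or
#'   \code{"right"} force one convention.
#' @return Numeric depth vector along the family axis.
#' @export
coverageProfile <- function(assignments, refset, isoacceptor,
                            align = c("auto", "left", "right")) {
    align <- match.arg(align)
    tr <- refset@trnas
    fam <- tr[tr$isoacceptor == isoacceptor, ]
    if (!nrow(fam)) stop("unknown isoacceptor: ", isoacceptor)
    axis_len <- max(fam$length)
    if (align == "auto")
        align <- if (max(fam$length) - min(fam$length) <= 2L) "right" else "left"
    a <- trna_rows(assignments, refset)
    depth <- numeric(axis_len)
    if (!nrow(a)) return(depth)
    a <- as.data.frame(a)
    a <- a[a$isoacceptor == isoacceptor, , drop = FALSE]
    if (!nrow(a)) return(depth)
    offset <- if (align == "right") axis_len - a$trna_length
              else rep(0L, nrow(a))
    for (i in seq_len(nrow(a))) {
        pos <- (a$start[i]:(a$start[i] + a$length[i] - 1L)) + offset[i]
        depth[pos] <- depth[pos] + a$weight[i]
    }
    depth
}

#' Long/short tDR split per tRNA
#'
#' Splits tRNA-assigned reads into tRNA-halves-sized (>= 31 nt) and trimmed
#' (<= 30 nt; reads of exactly 30 nt count as short, matching the "<30 nt
#' fragment" notion of short tDRs) per isodecoder or isoacceptor, and
#' normalizes both as reads per million of tRNA-mapping reads.
#'
#' @param assignments Output of \code{\link{classifyReads}}.
#' @param refset The \linkS4class{ReferenceSet}.
#' @param by \code{"isodecoder"} (collapsed representative records) or
#'   \code{"isoacceptor"} (families).
#' @param rpm Also report rpm columns (errors when no tRNA reads exist).
#' @return \code{data.frame}: grouping id, \code{long_count},
#'   \code{short_count}, and (if \code{rpm}) \code{long_rpm},
#'   \code{short_rpm}.
#' @export
sizeSplit <- function(assignments, refset, by = c("isodecoder", "isoacceptor"),
                      rpm = TRUE) {
    by <- match.arg(by)
    a <- trna_rows(assignments, refset)
    if (!nrow(a)) {
        if (rpm) stop("no tRNA-mapping reads: rpm denominator is zero")
        return(data.frame(id = character(), long_count = numeric(),
                          short_count = numeric()))
    }
    a[, id := if (by == "isodecoder") record_id else isoacceptor]
    tab <- a[, .(long_count = sum(weight[length >= 31L]),
                 short_count = sum(weight[length <= 30L])), by = id]
    out <- as.data.frame(tab)
    if (rpm) {
        denom <- sum(a$weight)
        out$long_rpm <- 1e6 * out$long_count / denom
        out$short_rpm <- 1e6 * out$short_count / denom
    }
    out[order(out$id), , drop = FALSE]
}
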