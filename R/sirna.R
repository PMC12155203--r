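#' Per-gene antisense (endo-siRNA) counts
#'
#' Sums weighted endo-siRNA assignments per overlapped gene and normalizes to
#' reads per million of total genome-mapping reads (the scatter-plot
#' convention; pass \code{denominator_kind = "genome_minus_rRNA"} for the
#' rRNA-excluded scheme). Genes with only sense-mapping reads are absent.
#'
#' @param assignments Output of \code{\link{classifyReads}}.
#' @param denominator_kind \code{"genome"} (default) or
#'   \code{"genome_minus_rRNA"}.
#' @param detail Also return the per-gene (length, first nucleotide) count
#'   breakdown as the \code{"detail"} attribute.
#' @return \code{data.frame}: \code{gene_id}, \code{count}, \code{rpm}.
#' @export
perGeneAntisenseCounts <- function(assignments,
                                   denominator_kind = c("genome",
                                                        "genome_minus_rRNA"),
                                   detail = FALSE) {
    denominator_kind <- match.arg(denominator_kind)
    a <- data.table::as.data.table(assignments)
    cc <- countClasses(assignments)
    denom <- if (denominator_kind == "genome") cc@totalGenomeMapping
             else cc@totalGenomeMapping - cc@counts[["rRNA"]]
    si <- a[class == "endo_siRNA" & !is.na(gene_id)]
    tab <- si[, .(count = sum(weight)), by = gene_id]
    out <- as.data.frame(tab[order(gene_id)])
    out$rpm <- 1e6 * out$count / denom
    if (detail) {
        attr(out, "detail") <- as.data.frame(
            si[, .(count = sum(weight)), by = .(gene_id, length, first_nt)])
    }
    out
}

#' Extract strict 22G-RNAs (or 26G-RNAs) from assignments
#'
#' Retains exactly the reads satisfying all three conditions of the strict
#' endo-siRNA definition: antisense to an annotated gene, the stated length,
#' and the stated 5' nucleotide (the read's first base as sequenced). The
#' default extracts 22G-RNAs; \code{length = 26} gives the 26G class;
#' \code{filter = "all"} keeps every antisense gene-mapping read.
#'
#' @param assignments Output of \code{\link{classifyReads}}.
#' @param length Read length required, default 22.
#' @param first_nt Required 5' nucleotide, default \code{"G"}.
#' @param filter Shorthand: \code{"22G"}, \code{"26G"} or \code{"all"}
#'   (overrides \code{length}/\code{first_nt}).
#' @return The filtered assignment \code{data.frame} (same columns); applying
#'   the filter twice is a no-op.
#' @export
extractSiRNA <- function(assignments, length = 22L, first_nt = "G",
                         filter = NULL) {
    if (!is.null(filter)) {
        filter <- match.arg(filter, c("22G", "26G", "all"))
        if (filter == "all") {
            keep <- assignments$class == "endo_siRNA"
            return(assignments[keep, , drop = FALSE])
        }
        length <- if (filter == "22G") 22L else 26L
        first_nt <- "G"
    }
    keep <- assignments$class == "endo_siRNA" &
        assignments$length == length &
        assignments$first_nt == first_nt
    assignments[keep, , drop = FALSE]
}

#' @rdname extractSiRNA
#' @export
extract22G <- function(assignments) extractSiRNA(assignments, 22L, "G")
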