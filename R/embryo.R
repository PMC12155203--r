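#' Packaged single-embryo expression profiles
#'
#' Deterministically constructed generative profiles over a shared universe of
#' 6000 genes (baseline means log-normal over four orders of magnitude;
#' named groups: histone \code{his-*}, \code{fbxb-*}, \code{hsp-*}, ribosomal
#' \code{rpl-*}/\code{rps-*}).
#'
#' \describe{
#'   \item{\code{two_cell}}{n = 30 control vs 25 treatment embryos; planted
#'     effects: \code{ife-2} up at log2(2.5), 35 further genes up at +1.3
#'     (kept moderate so planted fold changes are measured with little
#'     compositional distortion of the TPM denominator), and 2 genes down at
#'     -2 (2 down + 36 up in total).}
#'   \item{\code{eight_cell}}{n = 20 vs 26; planted: 106 genes down at -2.5
#'     (33 histone, 20 fbxb, 53 others) and 16 genes up at +2.}
#'   \item{\code{null}}{n = 30 vs 25, no planted effects, baseline means
#'     floored at 5 counts so the large-sample t approximation holds; used for
#'     type-I calibration checks.}
#' }
#'
#' Effect sizes and the dispersions (0.01 at the two-cell stage, whose
#' fixture is a low-dispersion, high-power comparison so planted fold changes
#' are recovered tightly; 0.05 elsewhere) are fixture choices giving
#' detection power approximately 1 at these sample sizes.
#'
#' @param name \code{"two_cell"}, \code{"eight_cell"} or \code{"null"}.
#' @return An \linkS4class{ExpressionProfile}.
#' @export
expressionProfile <- function(name = c("two_cell", "eight_cell", "null")) {
    name <- match.arg(name)
    uni <- with_seed(20240118L, {
        ids <- c("ife-2",
                 sprintf("his-%d", 1:40), sprintf("fbxb-%d", 1:30),
                 sprintf("hsp-%d", 1:20), sprintf("rpl-%d", 1:35),
                 sprintf("rps-%d", 1:25))
        ids <- c(ids, sprintf("gene-%04d", seq_len(6000L - length(ids))))
        means <- stats::rlnorm(length(ids), meanlog = log(30), sdlog = 1.3)
        names(means) <- ids
        lengths <- stats::setNames(sample(500:3000, length(ids), replace = TRUE),
                                   ids)
        grouped <- grepl("^(his|fbxb|hsp|rpl|rps)-", ids) | ids == "ife-2"
        # planted genes must be comfortably expressed for high-power recovery
        pool <- ids[!grouped]
        planted_pool <- sample(pool, 200L)
        means[c(planted_pool, "ife-2", sprintf("his-%d", 1:40),
                sprintf("fbxb-%d", 1:30))] <- stats::runif(271L, 50, 300)
        means["ife-2"] <- 250
        list(ids = ids, means = means, lengths = lengths,
             pool = planted_pool)
    })
    groups <- list(histone = sprintf("his-%d", 1:40),
                   fbxb = sprintf("fbxb-%d", 1:30),
                   hsp = sprintf("hsp-%d", 1:20),
                   ribosomal = c(sprintf("rpl-%d", 1:35),
                                 sprintf("rps-%d", 1:25)))
    planted <- switch(name,
        two_cell = data.frame(
            gene_id = c("ife-2", uni$pool[1:35], uni$pool[36:37]),
            log2fc = c(log2(2.5), rep(1.3, 35), rep(-2, 2))),
        eight_cell = data.frame(
            gene_id = c(sprintf("his-%d", 1:33), sprintf("fbxb-%d", 1:20),
                        uni$pool[38:90], uni$pool[91:106]),
            log2fc = c(rep(-2.5, 106), rep(2, 16))),
        null = data.frame(gene_id = character(), log2fc = numeric()))
    means <- uni$means
    if (name == "null") means <- pmax(means, 5)
    n <- switch(name, two_cell = c(30L, 25L), eight_cell = c(20L, 26L),
                null = c(30L, 25L))
    disp <- if (name == "two_cell") 0.01 else 0.05
    new("ExpressionProfile", stage = name, geneMeans = means,
        geneLengths = uni$lengths, groups = groups, plantedDe = planted,
        dispersion = disp, nControl = n[1], nTreatment = n[2],
        seed = 1L)
}

#' Simulate a single-embryo count table
#'
#' Counts are negative-binomial around each gene's baseline mean; planted
#' genes have the treatment-condition mean multiplied by \code{2^log2fc}.
#'
#' @param profile An \linkS4class{ExpressionProfile}.
#' @param seed Overrides the profile seed.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment}: assay
#'   \code{counts} (genes x embryos), \code{rowData$gene_length},
#'   \code{colData$condition} (\code{control}/\code{treatment}), and metadata
#'   \code{stage}, \code{planted_de}, \code{groups}, \code{seed}.
#' @export
simulateEmbryoCounts <- function(profile, seed = profile@seed) {
    validObject(profile)
    nC <- profile@nControl; nT <- profile@nTreatment
    mu <- profile@geneMeans
    muT <- mu
    if (nrow(profile@plantedDe)) {
        pd <- profile@plantedDe
        muT[pd$gene_id] <- muT[pd$gene_id] * 2^pd$log2fc
    }
    size <- 1 / profile@dispersion
    with_seed(seed, {
        counts <- cbind(
            matrix(stats::rnbinom(length(mu) * nC, mu = mu, size = size),
                   ncol = nC),
            matrix(stats::rnbinom(length(mu) * nT, mu = muT, size = size),
                   ncol = nT))
        rownames(counts) <- names(mu)
        colnames(counts) <- c(sprintf("control_%02d", seq_len(nC)),
                              sprintf("treatment_%02d", seq_len(nT)))
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            rowData = S4Vectors::DataFrame(
                gene_length = unname(profile@geneLengths)),
            colData = S4Vectors::DataFrame(
                condition = rep(c("control", "treatment"), c(nC, nT)),
                row.names = colnames(counts)),
            metadata = list(stage = profile@stage,
                            planted_de = profile@plantedDe,
                            groups = profile@groups,
                            seed = as.integer(seed)))
    })
}

#' Transcripts-per-million normalization
#'
#' TPM_g = 1e6 * (count_g / length_g) / sum_j (count_j / length_j) per embryo;
#' every column of the result sums to 1e6.
#'
#' @param x A \code{SummarizedExperiment} with a \code{counts} assay and
#'   \code{rowData$gene_length}, or a counts matrix.
#' @param gene_lengths Required when \code{x} is a matrix.
#' @return Same shape as the input: an SE gains a \code{tpm} assay, a matrix
#'   in yields a TPM matrix.
#' @export
tpmNormalize <- function(x, gene_lengths = NULL) {
    se <- NULL
    if (is(x, "SummarizedExperiment")) {
        se <- x
        counts <- SummarizedExperiment::assay(se, "counts")
        gene_lengths <- SummarizedExperiment::rowData(se)$gene_length
    } else counts <- x
    stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
    rate <- counts / gene_lengths
    tot <- colSums(rate)
    zero <- tot == 0
    if (any(zero))
        stop("embryo with zero total counts: ",
             paste(colnames(counts)[zero], collapse = ", "))
    tpm <- sweep(rate, 2, tot, "/") * 1e6
    if (is.null(se)) return(tpm)
    SummarizedExperiment::assays(se)$tpm <- tpm
    se
}

#' Differential expression by fold change and Welch t-test
#'
#' Per gene: condition mean TPMs, log2 fold change of (mean + pseudocount),
#' and a two-tailed unpaired Welch t-test on log2(TPM + pseudocount). A gene
#' is flagged \code{up} when log2FC > \code{lfc_cut} and p <= \code{p_cut},
#' \code{down} when log2FC < -\code{lfc_cut} and p <= \code{p_cut}, else
#' \code{ns}. Raw p-values are thresholded by default; set
#' \code{adjust = "BH"} for Benjamini-Hochberg. Genes with identical
#' zero-variance values in both conditions get p = 1 by convention.
#'
#' @param x SummarizedExperiment (TPM computed if absent) or TPM matrix.
#' @param condition Condition labels per column (taken from colData when
#'   \code{x} is an SE).
#' @param condition_a,condition_b Reference and comparison condition; log2FC
#'   is b over a.
#' @param lfc_cut,p_cut Thresholds, default 1 and 0.01.
#' @param pseudocount Added before logs, default 1.
#' @param adjust \code{"none"} (default) or a \code{\link[stats]{p.adjust}}
#'   method.
#' @return \code{data.frame}: \code{gene_id}, \code{mean_a}, \code{mean_b},
#'   \code{log2fc}, \code{p}, \code{flag}.
#' @export
differentialExpression <- function(x, condition = NULL,
                                   condition_a = "control",
                                   condition_b = "treatment",
                                   lfc_cut = 1, p_cut = 0.01,
                                   pseudocount = 1, adjust = "none") {
    if (is(x, "SummarizedExperiment")) {
        if (!"tpm" %in% SummarizedExperiment::assayNames(x))
            x <- tpmNormalize(x)
        condition <- SummarizedExperiment::colData(x)$condition
        tpm <- SummarizedExperiment::assay(x, "tpm")
    } else tpm <- x
    stopifnot(length(condition) == ncol(tpm))
    ia <- which(condition == condition_a)
    ib <- which(condition == condition_b)
    if (length(ia) < 2L || length(ib) < 2L)
        stop("need at least 2 embryos per condition")
    la <- log2(tpm[, ia, drop = FALSE] + pseudocount)
    lb <- log2(tpm[, ib, drop = FALSE] + pseudocount)
    p <- welch_rows(la, lb)
    mean_a <- rowMeans(tpm[, ia, drop = FALSE])
    mean_b <- rowMeans(tpm[, ib, drop = FALSE])
    log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
    if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
    flag <- rep("ns", nrow(tpm))
    flag[log2fc > lfc_cut & p <= p_cut] <- "up"
    flag[log2fc < -lfc_cut & p <= p_cut] <- "down"
    data.frame(gene_id = rownames(tpm), mean_a = mean_a, mean_b = mean_b,
               log2fc = log2fc, p = p, flag = flag,
               row.names = NULL, stringsAsFactors = FALSE)
}

# row-wise Welch t-test p-values (two-tailed); degenerate rows -> p = 1
welch_rows <- function(a, b) {
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    t <- (mb - ma) / sqrt(se2)
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    p[se2 == 0 & ma == mb] <- 1
    p[se2 == 0 & ma != mb] <- 0
    p
}

#' Coordinated shift of a gene group
#'
#' Compares the log2 fold-change distribution of a gene group against all
#' remaining genes with a two-sample Kolmogorov-Smirnov test and reports the
#' group and background medians.
#'
#' @param de Output of \code{\link{differentialExpression}}.
#' @param group Character vector of member gene ids (intersected with the
#'   expressed genes in \code{de}).
#' @param name Label for the group.
#' @return A \linkS4class{GroupShift}.
#' @export
groupShift <- function(de, group, name = "group") {
    members <- intersect(group, de$gene_id)
    if (!length(members)) stop("group has no genes in the expressed set")
    ing <- de$gene_id %in% members
    if (all(ing)) stop("group covers all genes: empty complement")
    gx <- de$log2fc[ing]; bx <- de$log2fc[!ing]
    ks <- suppressWarnings(stats::ks.test(gx, bx))
    new("GroupShift", group = name, members = members, log2fc = gx,
        medianGroup = stats::median(gx), medianBackground = stats::median(bx),
        medianShift = stats::median(gx) - stats::median(bx),
        ksStatistic = unname(ks$statistic), ksP = ks$p.value)
}

#' @rdname groupShift
#' @param x A \linkS4class{GroupShift}.
#' @export
groupShiftStats <- function(x) {
    data.frame(group = x@group, n = length(x@members),
               median_log2fc = x@medianGroup,
               median_background = x@medianBackground,
               median_shift = x@medianShift,
               ks_statistic = x@ksStatistic, ks_p = x@ksP)
}

#' Paired fold-change (rescue) comparison
#'
#' Joins two differential-expression results on their shared gene universe
#' and counts, per gene group, the genes falling in the concordant quadrants
#' (down in both or up in both comparisons) - the signature of expression
#' rescued by interfering with tDR function.
#'
#' @param de_x,de_y Two \code{\link{differentialExpression}} outputs (e.g.
#'   mutant-vs-WT and GFP-vs-anti-tDR).
#' @param groups Named list of gene-id vectors to tabulate.
#' @return List: \code{table} (gene_id, log2fc_x, log2fc_y, quadrant) and
#'   \code{concordance} per group (n, concordant count and fraction).
#' @export
rescueComparison <- function(de_x, de_y, groups = list()) {
    shared <- intersect(de_x$gene_id, de_y$gene_id)
    if (!length(shared)) stop("disjoint gene sets")
    x <- de_x$log2fc[match(shared, de_x$gene_id)]
    y <- de_y$log2fc[match(shared, de_y$gene_id)]
    quadrant <- ifelse(x < 0 & y < 0, "lower_left",
                ifelse(x > 0 & y > 0, "upper_right",
                ifelse(x == 0 | y == 0, "axis", "discordant")))
    tab <- data.frame(gene_id = shared, log2fc_x = x, log2fc_y = y,
                      quadrant = quadrant, stringsAsFactors = FALSE)
    conc <- lapply(names(groups), function(g) {
        m <- tab[tab$gene_id %in% groups[[g]], , drop = FALSE]
        data.frame(group = g, n = nrow(m),
                   concordant = sum(m$quadrant %in%
                                    c("lower_left", "upper_right")),
                   fraction = if (nrow(m)) mean(m$quadrant %in%
                                    c("lower_left", "upper_right")) else NA_real_)
    })
    list(table = tab, concordance = do.call(rbind, conc))
}

#' Write / read an embryo count table as TSV
#'
#' Layout: a \code{# stage:} and \code{# condition:} header pair, then a
#' gene x embryo matrix with \code{gene_id} and \code{gene_length} as the
#' first two columns.
#'
#' @param se A SummarizedExperiment from \code{\link{simulateEmbryoCounts}}.
#' @param path Output TSV.
#' @return Invisibly the path / the re-read SummarizedExperiment.
#' @export
writeCountTable <- function(se, path) {
    counts <- SummarizedExperiment::assay(se, "counts")
    cond <- SummarizedExperiment::colData(se)$condition
    stage <- S4Vectors::metadata(se)$stage %||% "unknown"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# stage: ", stage),
                 paste0("# condition: ", paste(cond, collapse = "\t"))), con)
    df <- data.frame(gene_id = rownames(counts),
                     gene_length = SummarizedExperiment::rowData(se)$gene_length,
                     counts, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
    hdr <- readLines(path, n = 2L)
    stage <- sub("^# stage: ", "", hdr[1])
    cond <- strsplit(sub("^# condition: ", "", hdr[2]), "\t")[[1]]
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE)
    counts <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(counts) <- df$gene_id
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_length = df$gene_length),
        colData = S4Vectors::DataFrame(condition = cond,
                                       row.names = colnames(counts)),
        metadata = list(stage = stage))
}
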