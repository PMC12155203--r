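#' Build and validate a pipeline run configuration
#'
#' @param profiles Composition profile names (packaged) or YAML paths.
#' @param expression_profiles Expression profile names
#'   (\code{\link{expressionProfile}}).
#' @param out_dir Output directory.
#' @param adapter Optional 3' adapter to trim before classification.
#' @param mismatches Classifier mismatch tolerance (0 or 1).
#' @param normalization rpm denominator for the class table.
#' @param lfc_cut,p_cut Differential-expression thresholds.
#' @param read_count Override of the profiles' read counts.
#' @param seed Master seed; every stage derives from it.
#' @return Validated config list of class \code{tdr_run_config}.
#' @export
runConfig <- function(profiles = "wt_male", expression_profiles = character(),
                      out_dir = tempfile("tdr_run_"), adapter = NULL,
                      mismatches = 0L,
                      normalization = c("genome", "genome_minus_rRNA"),
                      lfc_cut = 1, p_cut = 0.01, read_count = NULL,
                      seed = 1L) {
    normalization <- match.arg(normalization)
    stopifnot(lfc_cut > 0, p_cut > 0, mismatches %in% c(0L, 1L))
    structure(list(profiles = profiles,
                   expression_profiles = expression_profiles,
                   out_dir = out_dir, adapter = adapter,
                   mismatches = as.integer(mismatches),
                   normalization = normalization,
                   lfc_cut = lfc_cut, p_cut = p_cut,
                   read_count = read_count, seed = as.integer(seed)),
              class = "tdr_run_config")
}

resolve_profile <- function(p, read_count, seed) {
    if (file.exists(p)) loadCompositionProfile(p, read_count, seed)
    else compositionProfile(p, read_count, seed)
}

#' Run the full pipeline: simulate, classify, quantify, test
#'
#' For each composition profile: simulates the library, classifies with the
#' sequential class-priority rule, and computes class percentages, rpm table,
#' 5'/3' half fractions, length x first-nucleotide matrix, per-tRNA size
#' splits and the strict 22G count. For each expression profile: simulates
#' the embryo table, TPM-normalizes, runs differential expression and the
#' gene-group shift tests. All tables are written as TSV under
#' \code{out_dir}; a machine-readable JSON summary (stamped with the seed and
#' a config fingerprint) aggregates the headline numbers. Re-running the same
#' config reproduces the summary byte for byte.
#'
#' @param config From \code{\link{runConfig}}.
#' @param refset Reference to classify against, default
#'   \code{\link{toyReferenceSet}()}.
#' @return Invisibly, the summary list.
#' @export
runPipeline <- function(config, refset = toyReferenceSet()) {
    stopifnot(inherits(config, "tdr_run_config"))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    index <- buildClassIndex(refset, config$mismatches)
    summary <- list(seed = config$seed,
                    config_hash = config_fingerprint(as.character(jsonlite::toJSON(
                        unclass(config)[setdiff(names(config), "out_dir")],
                        auto_unbox = TRUE, null = "null"))),
                    profiles = list(), expression = list())

    for (i in seq_along(config$profiles)) {
        pname <- config$profiles[i]
        prof <- resolve_profile(pname, config$read_count,
                                config$seed + i - 1L)
        lib <- simulateSmallRnaReads(prof, refset)
        reads <- lib@reads[c("read_id", "sequence")]
        if (!is.null(config$adapter))
            reads <- trimAndFilter(reads, config$adapter)
        asn <- classifyReads(reads, index, refset)
        cc <- countClasses(asn)
        rpm <- normalizeCounts(cc, config$normalization)
        hf <- halfFractions(asn, refset)
        ss <- sizeSplit(asn, refset, by = "isoacceptor",
                        rpm = cc@counts[["tRNA"]] > 0)
        lm <- lengthFirstNtMatrix(asn, "tRNA")
        g22 <- extract22G(asn)
        base <- file.path(config$out_dir, prof@name)
        hdr <- sprintf("# seed: %d  config: %s", config$seed,
                       summary$config_hash)
        write_tsv_with_header(data.frame(class = names(cc@counts),
                                         count = unname(cc@counts),
                                         pct = unname(classPercentages(cc)),
                                         rpm = unname(rpm@values)),
                              paste0(base, "_class_counts.tsv"), hdr)
        write_tsv_with_header(ss, paste0(base, "_size_split.tsv"), hdr)
        write_tsv_with_header(data.frame(length = rownames(lm), lm,
                                         check.names = FALSE),
                              paste0(base, "_length_firstnt.tsv"), hdr)
        summary$profiles[[prof@name]] <- list(
            class_pct = as.list(round(classPercentages(cc), 4)),
            tdr_pct = unname(round(classPercentages(cc)[["tRNA"]], 4)),
            five_prime_pct = round(hf$five_prime, 4),
            n_tdr_reads = round(hf$n_reads, 2),
            n_22g = round(sum(g22$weight), 2),
            reads = nrow(reads))
    }

    for (ename in config$expression_profiles) {
        eprof <- expressionProfile(ename)
        se <- simulateEmbryoCounts(eprof, seed = config$seed)
        se <- tpmNormalize(se)
        de <- differentialExpression(se, lfc_cut = config$lfc_cut,
                                     p_cut = config$p_cut)
        shifts <- lapply(names(eprof@groups), function(g)
            groupShiftStats(groupShift(de, eprof@groups[[g]], g)))
        shifts <- do.call(rbind, shifts)
        base <- file.path(config$out_dir, ename)
        hdr <- sprintf("# seed: %d  config: %s", config$seed,
                       summary$config_hash)
        write_tsv_with_header(de, paste0(base, "_de.tsv"), hdr)
        write_tsv_with_header(shifts, paste0(base, "_group_shifts.tsv"), hdr)
        summary$expression[[ename]] <- list(
            n_up = sum(de$flag == "up"), n_down = sum(de$flag == "down"),
            group_median_log2fc = stats::setNames(
                as.list(round(shifts$median_log2fc, 4)), shifts$group))
    }

    if (length(config$profiles) >= 2L) {
        nm <- names(summary$profiles)
        summary$comparison <- list(
            pair = nm[1:2],
            tdr_pct_delta = summary$profiles[[nm[2]]]$tdr_pct -
                summary$profiles[[nm[1]]]$tdr_pct,
            five_prime_pct_delta = summary$profiles[[nm[2]]]$five_prime_pct -
                summary$profiles[[nm[1]]]$five_prime_pct)
    }

    writeRunSummary(summary, file.path(config$out_dir, "summary.json"))
    invisible(summary)
}

write_tsv_with_header <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname runPipeline
#' @param summary Summary list from \code{runPipeline}.
#' @param path JSON output path.
#' @export
writeRunSummary <- function(summary, path) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
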