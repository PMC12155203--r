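# internal helpers

# run expr with a temporary RNG state seeded from `seed`; restores the caller's
# stream afterwards so simulation calls do not perturb user code
with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# uppercase, U->T, validate alphabet; `what` names the offending record in errors
normalize_nucleotides <- function(x, what = "sequence") {
    x <- toupper(x)
    x <- gsub("U", "T", x, fixed = TRUE)
    bad <- regexpr("[^ACGTN]", x)
    if (any(bad > 0L)) {
        i <- which(bad > 0L)[1L]
        stop(sprintf("non-ACGTU character at position %d of %s '%s'",
                     bad[i], what, names(x)[i] %||% i), call. = FALSE)
    }
    x
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

revcomp_chr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 31-ary polynomial rolling fingerprint of a string, mod a Mersenne prime;
# stamps run summaries so outputs can be tied to the exact configuration
config_fingerprint <- function(x) {
    h <- 0
    for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}
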