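# Seed plumbing: one master seed, per-stage streams derived deterministically
# so each stage is individually reproducible.

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed plus a stage tag to an integer seed
#' below 2^31, so independent simulation stages (population, mode labels,
#' genotypes, noise, bin counts, within-bin draws, ...) get reproducible
#' streams without sharing state.
#'
#' @param seed integer master seed, or `NULL` (returns `NULL`).
#' @param tag character stage label.
#' @return integer seed, or `NULL` if `seed` is `NULL`.
#' @export
deriveSeed <- function(seed, tag) {
    if (is.null(seed)) return(NULL)
    h <- 0
    for (k in utf8ToInt(as.character(tag)))
        h <- (h * 131 + k) %% 2147483629
    as.integer((abs(as.numeric(seed)) * 2654435.0 + h) %% 2147483629) + 1L
}

# Evaluate expr under a local seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

stopifnotScalar <- function(x, name, lower = -Inf, upper = Inf,
                            openLower = FALSE, openUpper = FALSE,
                            integer = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name))
    lo <- if (openLower) x > lower else x >= lower
    hi <- if (openUpper) x < upper else x <= upper
    if (!lo || !hi)
        stop(sprintf("'%s' = %g is outside its valid range", name, x))
    if (integer && x != round(x))
        stop(sprintf("'%s' must be an integer", name))
    invisible(TRUE)
}
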