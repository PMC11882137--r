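# Internal helpers: reproducible seeding and small array utilities.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Derive a child seed from a parent seed and a salt
#'
#' Deterministic integer mixing so that every random draw in a pipeline traces
#' back to one global seed. The result is always in `[0, 2^31 - 2]`.
#'
#' @param seed Parent integer seed.
#' @param salt Integer or character salt (e.g. a subject index or stage name).
#' @return A derived integer seed.
#' @examples
#' deriveSeed(42, 1) != deriveSeed(42, 2)
#' @export
deriveSeed <- function(seed, salt) {
    if (is.character(salt))
        salt <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
    m <- 2147483647 # 2^31 - 1, prime
    s <- (as.double(seed) %% m)
    a <- (as.double(salt) %% m)
    # two rounds of multiply-add mixing mod 2^31-1
    s <- (s * 48271 + a * 16807 + 12345) %% m
    s <- (s * 69621 + 987654321) %% m
    as.integer(s)
}

# Stop unless `x` is a single finite number.
assertScalar <- function(x, name) {
    if (length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
    invisible(x)
}

# Shape equality for arrays/volumes.
sameShape <- function(a, b) identical(dim(a), dim(b))

# Physical voxel volume in mL for a spacing triple in mm.
voxelVolumeML <- function(spacing) prod(spacing) / 1000
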