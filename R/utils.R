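#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. All randomness in the package
## flows through `with_seed()` so no function disturbs the caller's RNG
## state and identical seeds give byte-identical output.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derived from a global seed and a stage name.
# Polynomial string hash folded into [0, 2^31 - 2]; adding stages never
# perturbs the seed of an existing stage.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Validate a probability vector that must sum to 1 (within tolerance).
check_proportions <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("'%s' must be probabilities in [0, 1]", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop(sprintf("'%s' must sum to 1 (got %.6f)", what, sum(p)), call. = FALSE)
  }
  invisible(p)
}

# Dense numeric matrix from any supported expression container.
as_dense <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# Library-size normalize to `scale` counts per cell, then log1p.
# Genes are rows, cells are columns throughout the package.
lognorm_counts <- function(counts, scale = 1e4) {
  counts <- as_dense(counts)
  libsize <- colSums(counts)
  libsize[libsize == 0] <- 1
  log1p(sweep(counts, 2, libsize / scale, "/"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
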