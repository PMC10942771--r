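# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Extract a genes x cells matrix from a SingleCellExperiment or pass a
# matrix-like through unchanged.
.get_assay <- function(x, assay = "counts") {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, assay)
  } else {
    x
  }
}

# x*log(x/y) with the 0*log(0) = 0 convention, vectorized.
.xlogxy <- function(x, y) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log(x[nz] / y[nz])
  out
}

.stopifnot_named <- function(x, what) {
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop(what, " must be a fully named vector", call. = FALSE)
  }
}
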