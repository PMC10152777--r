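#' @keywords internal
"_PACKAGE"

# Internal assertion helper: fail with a clean, caller-attributed message.
.fail <- function(...) stop(..., call. = FALSE)

.check <- function(cond, ...) {
  if (!isTRUE(cond)) .fail(...)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that no exported function mutates global randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + stage * 104729) %% 2147483647)
}

# Coerce input to a dense numeric matrix with cell/gene dimnames, validating
# the ExpressionMatrix invariants (unique ids, finite nonnegative values).
as_expression_matrix <- function(x, what = "expression matrix") {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  .check(is.matrix(x) && is.numeric(x), what, " must be a numeric matrix")
  .check(all(is.finite(x)), what, " contains non-finite values")
  .check(all(x >= 0), what, " contains negative values")
  if (is.null(rownames(x))) rownames(x) <- paste0("cell_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("gene_", seq_len(ncol(x)))
  .check(!anyDuplicated(rownames(x)), what, " has duplicate cell identifiers")
  .check(!anyDuplicated(colnames(x)), what, " has duplicate gene identifiers")
  x
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
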