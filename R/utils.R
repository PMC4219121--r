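# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded internals never perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
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
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit substream seed from a master seed so results for one unit
# (e.g. one gene in the screen) do not depend on processing order. Kept below
# 2^31 - 1 to stay a valid R integer.
derive_seed <- function(master, index) {
  as.integer((as.double(master) + 7919 * as.double(index)) %% 2147483629 + 1)
}

# Stable numeric key for an identifier string (polynomial rolling hash), so
# substreams follow the entity itself rather than its processing position.
id_hash <- function(id) {
  Reduce(function(h, c) (h * 131 + c) %% 2147483647, utf8ToInt(id), accumulate = FALSE, 0)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%0%` <- function(x, y) if (length(x) == 0L) y else x

stopifnot_expression_matrix <- function(x, arg = "expr") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (features x samples).", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry feature rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    abort(sprintf("Duplicate feature id in `%s`: '%s'.", arg, dup))
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1L]
    abort(sprintf("Duplicate sample id in `%s`: '%s'.", arg, dup))
  }
  if (any(is.infinite(x))) {
    abort(sprintf("`%s` contains non-finite values; only finite or NA allowed.", arg))
  }
  invisible(x)
}
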