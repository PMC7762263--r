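# Internal helpers shared across modules.

# Stable "natural" ordering of node labels: numeric order when every label
# parses as a number, lexicographic otherwise. Keeps integer-labelled graphs
# in the order a human expects ("2" before "10") while staying total for
# arbitrary string labels.
natural_order <- function(labels) {
  labels <- as.character(labels)
  suppressWarnings(num <- as.numeric(labels))
  if (!anyNA(num)) order(num, labels) else order(labels)
}

natural_sort <- function(labels) {
  as.character(labels)[natural_order(labels)]
}

# First element of `labels` under natural order.
natural_min <- function(labels) {
  natural_sort(labels)[1L]
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
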