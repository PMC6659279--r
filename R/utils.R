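# internal helpers

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive n_iter per-iteration seeds from one master seed; indexed by the
# iteration counter and reported in per-iteration tables.
derive_seeds <- function(master_seed, n_iter) {
  with_local_seed(master_seed, sample.int(.Machine$integer.max - 1L, n_iter))
}

# Taxon-name normalisation used for matching between trait tables and tree
# tip labels: underscores and spaces are interchangeable, case ignored.
normalize_taxon <- function(x) tolower(gsub("_", " ", trimws(x)))
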