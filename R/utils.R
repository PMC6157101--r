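`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a per-replicate seed below 2^31 from a base seed and an index.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 2654435761 + index * 97) %%
               (.Machine$integer.max - 1)) + 1L
}

## Reorder a subject-indexed container to a given id order (subset allowed).
reorderSubjects <- function(x, ids) {
  if (is(x, "GenotypeMatrix")) {
    genotypeMatrix(x@values[ids, , drop = FALSE], ids, x@snpIds)
  } else if (is(x, "MethylationMatrix")) {
    methylationMatrix(x@values[ids, , drop = FALSE], ids, x@cpgIds,
                      x@valueType)
  } else if (is(x, "KinshipMatrix")) {
    kinshipMatrix(x@values[ids, ids, drop = FALSE], ids)
  } else {
    stop("unsupported container for reorderSubjects")
  }
}

## Strip a leading 'chr' prefix from chromosome names.
normChrom <- function(x) sub("^[Cc]hr", "", as.character(x))
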