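# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# ISO-8601-ish compact system timestamp for output filenames; a counter suffix
# resolves within-second collisions so no file is ever overwritten.
timestampedPath <- function(folder, prefix, ext = "csv") {
  stamp <- format(Sys.time(), "%Y%m%dT%H%M%S")
  path <- file.path(folder, sprintf("%s_%s.%s", prefix, stamp, ext))
  k <- 1
  while (file.exists(path)) {
    path <- file.path(folder, sprintf("%s_%s_%d.%s", prefix, stamp, k, ext))
    k <- k + 1
  }
  path
}
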