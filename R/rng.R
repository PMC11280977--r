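#' Derive a reproducible sub-seed from a global seed and labels
#'
#' Expands one global seed into independent per-component seeds by hashing the
#' seed together with an arbitrary sequence of labels (subject id, lesion id,
#' reader id, repeat index, ...). The hash is a plain 31-bit polynomial rolling
#' hash, so the mapping is stable across platforms and R versions.
#'
#' @param seed Integer global seed.
#' @param ... Labels (coerced to character) identifying the component.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "subject03", "R1", 2)
derive_seed <- function(seed, ...) {
  labels <- paste(
    c(as.character(seed), vapply(list(...), as.character, character(1))),
    collapse = "/"
  )
  h <- 0
  for (b in utf8ToInt(labels)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
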