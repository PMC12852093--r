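# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed (< 2^31) from a master seed plus labels,
# so that data split, sampler, and weight init each get their own stream.
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    sum(utf8ToInt(paste(as.character(p), collapse = "|")))
  }, numeric(1))
  s <- as.numeric(seed) %% 2147483629
  for (p in c(parts, 1)) {
    s <- (s * 69069 + p + 1) %% 2147483629
  }
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_taxembed <- function(..., class) {
  stop(structure(
    class = c(class, "taxembed_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
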