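#' Derive a reproducible child seed
#'
#' Folds a root seed together with arbitrary integer/character tags into a
#' deterministic 31-bit seed, so that every stage of a pipeline (per-field,
#' per-round, per-fold ...) draws from its own stream while the whole run is
#' reproducible from a single integer.
#'
#' @param seed Integer root seed.
#' @param ... Integer or character tags identifying the consumer.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "")) else as.integer(p)
  }), use.names = FALSE)
  h <- as.double(seed) %% 2147483647
  for (p in parts) h <- (h * 48271 + as.double(p) + 11) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
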