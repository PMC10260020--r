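# internal helpers: seeded sub-streams, argument checks

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All generator randomness goes through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a deterministic 31-bit sub-seed from (seed, tag) so that independent
# parts of a generator (lipid positions, species, protein schedule, noise)
# draw from non-interfering streams: changing how many numbers one stream
# consumes never perturbs another.
substream_seed <- function(seed, tag) {
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% 1000000007
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 + h) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
  invisible(x)
}
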