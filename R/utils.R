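#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' All randomness in the pipeline flows from a single master seed. Each stage
#' (null models, permutation tests, data generation, ...) receives its own
#' stream through this fixed splitting scheme, so stages can be re-run in
#' isolation and still reproduce the pipeline bit for bit.
#'
#' @param master single integer master seed.
#' @param stage non-negative integer stage index.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- ((abs(as.numeric(master)) %% m) * 48271 + as.numeric(stage) * 16807 + 1) %% m
  as.integer(s + (s == 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
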