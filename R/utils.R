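# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators never
#' perturb the global random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Streams for different purposes (pathway sampling, per-condition target
#' draws, ...) must be independent yet fully determined by the master seed.
#' A small multiplicative string hash keeps every derived seed below 2^31.
#' @keywords internal
#' @noRd
sub_seed <- function(seed, label, index = 0L) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  h <- (h * 31 + as.numeric(index) + 1) %% m
  as.integer(h)
}

# split "a;b;c" fields (used by graph attribute round-trips)
split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

join_field <- function(x) paste(sort(unique(x)), collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a
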