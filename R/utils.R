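#' Natural (alphanumeric) sort of chromosome or group names
#'
#' Sorts names such as `Pv1, Pv2, Pv10` in numeric rather than lexicographic
#' order, so concatenated genome axes come out in the conventional
#' `Pv01...Pv11` order.
#'
#' @param x character vector of names.
#' @return `x` sorted naturally.
#' @keywords internal
natural_sort <- function(x) {
  if (length(x) == 0L) return(x)
  prefix <- sub("([0-9]+)$", "", x)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", x)))
  num[is.na(num)] <- Inf
  x[order(prefix, num, x)]
}

# Derive an independent substream seed from a master seed and a stream label.
# Keeps every generator reproducible from one user-facing seed while letting
# the simulators draw from distinct streams. Result stays below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
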