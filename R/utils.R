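## Internal helpers: seeded RNG streams, assertions, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

scStop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Derive a reproducible sub-seed (< 2^31) from a master seed and a stream
## tag, so that independent generator stages draw from independent streams.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807 + 12345) %% 2147483629)
}

## Evaluate expr with a locally-set RNG seed, restoring the caller's RNG
## state afterwards (pure functions stay pure from the caller's viewpoint).
withSeed <- function(seed, expr) {
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

## Next power-of-two >= n (FFT-friendly length).
nextPow2 <- function(n) 2^ceiling(log2(max(n, 1)))

## Linear convolution of a real signal with a (possibly complex) kernel via
## FFT, returning the 'same'-sized central part.
fftConvSame <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  L <- nextPow2(n + m - 1)
  X <- fft(c(x, rep(0, L - n)))
  K <- fft(c(kernel, rep(0, L - m)))
  full <- fft(X * K, inverse = TRUE) / L
  start <- floor(m / 2) + 1
  full[start:(start + n - 1)]
}

## Event table constructor/validator: the package-wide tabular event format.

#' Construct a typed event table
#'
#' Events are stored as a plain data.frame with columns `onset` (seconds
#' from recording start), `type` (`ball_appear`, `participant_hit`, `serve`,
#' `rally`), `condition` (`machine`, `human`), `subcondition` (`rally`,
#' `serve` or NA) and `source` (`imu`, `reference`, `synthetic`).  Rows are
#' sorted by onset.
#'
#' @param onset numeric vector of onsets in seconds.
#' @param type,condition,subcondition,source character vectors (recycled).
#' @return a data.frame of class `c("eventTable", "data.frame")`.
#' @export
eventTable <- function(onset = numeric(0), type = character(0),
                       condition = NA_character_,
                       subcondition = NA_character_,
                       source = "synthetic") {
  n <- length(onset)
  tab <- data.frame(onset = as.numeric(onset),
                    type = rep_len(as.character(type), n),
                    condition = rep_len(as.character(condition), n),
                    subcondition = rep_len(as.character(subcondition), n),
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  okType <- c("ball_appear", "participant_hit", "serve", "rally")
  if (n && !all(tab$type %in% okType))
    scStop("event type must be one of: %s", paste(okType, collapse = ", "))
  tab <- tab[order(tab$onset), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("eventTable", "data.frame")
  tab
}

## Hann window (periodic) used for overlap-add stitching.
hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

## Robust per-channel amplitude statistic used for channel hygiene.
logRms <- function(x) {
  r <- sqrt(rowMeans(x^2))
  log10(pmax(r, .Machine$double.xmin))
}
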