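#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even (banker's rounding), which does
#' not reproduce the rounding seen in course reports (e.g. 73.75 -> 73.8,
#' 46.88 -> 47). This helper rounds ties away from zero at a fixed number of
#' decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfAway(c(73.75, 46.88, -0.5), digits = c(1, 0, 0)[1])
#' @export
roundHalfAway <- function(x, digits = 0) {
  f <- 10^digits
  # nudge by a relative epsilon so representation error (e.g. 73.75 stored
  # as 73.74999...) does not flip a tie downward
  sign(x) * floor(abs(x) * f + 0.5 + .Machine$double.eps * abs(x) * f) / f
}

#' Format seconds as mm:ss
#'
#' @param seconds numeric vector of durations in seconds.
#' @return character vector like \code{"9:08"} (minutes not zero-padded).
#' @examples
#' formatMMSS(548)
#' @export
formatMMSS <- function(seconds) {
  s <- roundHalfAway(seconds)
  sprintf("%d:%02d", s %/% 60, s %% 60)
}

# Parse "HH:MM" to minutes past midnight.
parseHM <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L)
    stop("time must be given as HH:MM, got ", sQuote(x), call. = FALSE)
  h <- as.integer(m[2]); mn <- as.integer(m[3])
  if (h > 24L || mn > 59L || (h == 24L && mn > 0L))
    stop("invalid time of day ", sQuote(x), call. = FALSE)
  h * 60L + mn
}

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopInvalid <- function(...) stop(..., call. = FALSE)
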