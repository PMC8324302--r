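#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils read.csv write.csv head tail
NULL

# Run `code` under a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed and a stream index to a derived seed, so that every
#' simulated animal, ROI and replicate draws from its own deterministic
#' stream. Values stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param k stream index.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + k) %% 2147483647L)
}

#' Standard error of the mean
#'
#' @param x numeric vector; `NA` values are dropped.
#' @return `sd(x)/sqrt(n)`, or `NA` for fewer than two observations.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Rolling quantile of `x` evaluated on a coarse grid and interpolated back.
# Used for slow-baseline estimation where an exact per-sample rolling
# quantile would add nothing but cost.
rolling_quantile <- function(x, width, prob, stride = NULL) {
  n <- length(x)
  if (is.null(stride)) stride <- max(1L, floor(width / 20))
  centers <- unique(c(seq(1L, n, by = stride), n))
  half <- floor(width / 2)
  q <- vapply(centers, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::quantile(x[lo:hi], prob, names = FALSE, type = 7)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}
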