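#' @keywords internal
"_PACKAGE"

# Shared small helpers: argument checks, seed streams, peak finding.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stopf("'%s' must be a finite numeric scalar", name)
  invisible(x)
}

#' Derive a reproducible child seed from a master seed and a stream tag
#'
#' Every stochastic operation in the package draws from its own stream so
#' that adding noise to one stage never perturbs another. The child seed is
#' a deterministic 31-bit hash of the master seed and a character tag.
#'
#' @param master integer master seed.
#' @param tag character stream label (e.g. `"motion"`, `"shot"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(master, tag) {
  assert_scalar_num(master, "master")
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(master) * 48271 + h * 69621 + 7) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Locate local maxima of a trace
#'
#' Simple peak counter used e.g. to count heartbeat-artifact fluctuations:
#' a sample is a peak when it exceeds both neighbours and `min_height`, and
#' peaks closer than `min_sep` samples are merged keeping the larger one.
#'
#' @param y numeric vector.
#' @param min_height minimum peak value (same units as `y`).
#' @param min_sep minimum separation between peaks, in samples.
#' @return Integer vector of peak indices (1-based).
#' @export
find_peaks <- function(y, min_height = -Inf, min_sep = 1L) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  cand <- cand[y[cand] >= min_height]
  if (min_sep > 1L && length(cand) > 1L) {
    keep <- integer(0)
    cand <- cand[order(-y[cand])]
    for (i in cand) if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
    cand <- sort(keep)
  }
  cand
}

# box-average downsample of a 1-D signal by integer factor; tail samples
# short of a full box are averaged over what remains
box_downsample <- function(y, factor) {
  n <- length(y)
  idx <- ceiling(seq_len(n) / factor)
  as.numeric(tapply(y, idx, mean))
}

# robust SD estimate (MAD, consistent for a Gaussian); falls back to sd()
# when the MAD degenerates to zero on sparse/quantized data
robust_sd <- function(y) {
  s <- stats::mad(y, constant = 1.4826)
  if (s == 0) s <- stats::sd(y)
  s
}
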