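## Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are deterministic given
#' their own seed without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage child seed from a global seed
#'
#' Deterministic expansion of one run seed into independent stage seeds
#' (multiplicative congruential step, kept below 2^31).
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 1) or stage name from the pipeline
#'   stage table.
#' @return integer seed.
#' @export
childSeed <- function(seed, stage) {
  stages <- c(synth = 1L, dic = 2L, modes = 3L, encode = 4L, infomap = 5L)
  k <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else as.integer(stage)
  as.integer((as.numeric(seed) * 2654435761 + 97 * k) %% 2147483647) + 1L
}

## Periodic Hann taper (Welch segments).
hannWindow <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
}

#' Locate local maxima of a sampled oscillation
#'
#' Peaks are strict local maxima separated by at least `minDistance` samples
#' with prominence above `minProminence`.  Peak positions are refined to
#' sub-sample resolution by a three-point quadratic fit, so phases derived
#' from peak times are not quantized to the frame clock.
#'
#' @param x numeric series.
#' @param minProminence minimum peak prominence (same units as `x`).
#'   Default: 10% of `sd(x)`.
#' @param minDistance minimum separation between retained peaks, in samples.
#'   Default: half the dominant period estimated from the periodogram.
#' @return data.frame with columns `index` (integer sample), `position`
#'   (fractional sample, quadratic-refined), `value` (refined peak height).
#' @export
findOscillationPeaks <- function(x, minProminence = NULL, minDistance = NULL) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), position = numeric(),
                                value = numeric()))
  if (is.null(minProminence)) minProminence <- 0.1 * stats::sd(x)
  if (is.null(minDistance)) {
    xc <- x - mean(x)
    sp <- Mod(stats::fft(xc))[seq_len(floor(n / 2))]
    sp[1] <- 0
    kdom <- which.max(sp)
    minDistance <- if (sp[kdom] > 0) max(2, floor(n / kdom / 2)) else 2
  }
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) return(data.frame(index = integer(), position = numeric(),
                                      value = numeric()))
  ## prominence: drop to the higher of the two flanking minima between
  ## neighbouring higher points (simple scan bounded by series ends)
  keepProm <- vapply(idx, function(i) {
    h <- x[i]
    l <- i; while (l > 1 && x[l] <= h) l <- l - 1L
    r <- i; while (r < n && x[r] <= h) r <- r + 1L
    leftMin <- min(x[l:i]); rightMin <- min(x[i:r])
    (h - max(leftMin, rightMin)) >= minProminence
  }, logical(1))
  idx <- idx[keepProm]
  if (!length(idx)) return(data.frame(index = integer(), position = numeric(),
                                      value = numeric()))
  ## enforce minimum separation, keeping the taller peak
  ord <- order(x[idx], decreasing = TRUE)
  keep <- logical(length(idx))
  taken <- rep(FALSE, n)
  for (j in ord) {
    i <- idx[j]
    lo <- max(1, i - ceiling(minDistance) + 1)
    hi <- min(n, i + ceiling(minDistance) - 1)
    if (!any(taken[lo:hi])) { keep[j] <- TRUE; taken[i] <- TRUE }
  }
  idx <- sort(idx[keep])
  ## quadratic refinement
  pos <- numeric(length(idx)); val <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (i > 1 && i < n) {
      ym <- x[i - 1]; y0 <- x[i]; yp <- x[i + 1]
      den <- ym - 2 * y0 + yp
      d <- if (den < 0) 0.5 * (ym - yp) / den else 0
      d <- max(-0.5, min(0.5, d))
      pos[j] <- i + d
      val[j] <- y0 - 0.25 * (ym - yp) * d
    } else { pos[j] <- i; val[j] <- x[i] }
  }
  data.frame(index = idx, position = pos, value = val)
}

## Circular mean of phases given in cycles, result in [0, 1).
circularMeanCycles <- function(theta) {
  ang <- atan2(mean(sin(2 * pi * theta)), mean(cos(2 * pi * theta)))
  (ang / (2 * pi)) %% 1
}

## Signed circular distance between phases in cycles, in (-0.5, 0.5].
circularDiffCycles <- function(a, b) {
  d <- (a - b) %% 1
  ifelse(d > 0.5, d - 1, d)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler.  `kappa = 0` reduces to the uniform
#' circular distribution; very large `kappa` approaches a wrapped normal with
#' SD `1/sqrt(kappa)`.
#'
#' @param n number of draws.
#' @param mu mean direction(s), radians (recycled to length `n`).
#' @param kappa concentration parameter, >= 0.
#' @return numeric vector of angles in radians (unwrapped around `mu`).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, is.finite(kappa))
  mu <- rep_len(mu, n)
  if (n == 0L) return(numeric())
  if (kappa < 1e-9) return(mu + stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  mu + out
}

## Trapezoidal integration on an (ordered) frequency grid; y may be a matrix
## with one spectrum per row.
trapzIntegrate <- function(x, y) {
  dx <- diff(x)
  if (is.matrix(y)) {
    nc <- ncol(y)
    as.numeric((y[, -nc, drop = FALSE] + y[, -1, drop = FALSE]) %*% dx) / 2
  } else {
    sum((y[-length(y)] + y[-1]) * dx) / 2
  }
}

## Odd-rounding helper (nearest odd integer >= 3).
oddRound <- function(x) {
  k <- max(3, round(x))
  if (k %% 2 == 0) k <- k + 1
  as.integer(k)
}
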