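# Explicit duration distributions for GHMM states: smoothed empirical pmf
# with a geometric tail.  Complete-CDS durations live on a mod-3 lattice
# (step = 3) so that frame consistency holds by construction.

#' Construct a duration model
#'
#' @param minLen,maxLen body support bounds (inclusive).
#' @param logPmf log masses at `seq(minLen, maxLen, by = step)`.
#' @param tailLogMass log of the total mass beyond `maxLen` (`-Inf` = none).
#' @param tailLogP log per-step geometric continuation ratio of the tail.
#' @param step body lattice step (1, or 3 for codon-quantized durations).
#' @return a [DurationModel-class].
#' @export
durationModel <- function(minLen, maxLen, logPmf, tailLogMass = -Inf,
                          tailLogP = -Inf, step = 1L) {
  new("DurationModel", minLen = as.integer(minLen),
      maxLen = as.integer(maxLen), step = as.integer(step),
      logPmf = as.numeric(logPmf), tailLogP = as.numeric(tailLogP),
      tailLogMass = as.numeric(tailLogMass))
}

#' Log probability of a segment length
#'
#' Body pmf inside `[minLen, maxLen]` (off-lattice lengths score `-Inf`),
#' geometric extrapolation beyond `maxLen`, `-Inf` below `minLen`.
#'
#' @param model a [DurationModel-class].
#' @param len positive integer length (vectorized).
#' @return log-probability vector.
#' @export
durationLogP <- function(model, len) {
  stopifnot(all(len >= 1))
  out <- rep(-Inf, length(len))
  body <- len >= model@minLen & len <= model@maxLen &
    (len - model@minLen) %% model@step == 0L
  out[body] <- model@logPmf[(len[body] - model@minLen) %/% model@step + 1L]
  tl <- len > model@maxLen & (len - model@maxLen) %% model@step == 0L
  if (any(tl) && is.finite(model@tailLogMass)) {
    j <- (len[tl] - model@maxLen) %/% model@step
    out[tl] <- model@tailLogMass + log1mexp(model@tailLogP) +
      (j - 1) * model@tailLogP
  }
  out
}

# log(1 - exp(x)) for x <= 0, stable
log1mexp <- function(x) {
  if (!is.finite(x)) return(0)
  if (x > -0.693) log(-expm1(x)) else log1p(-exp(x))
}

#' Log survival of a segment length
#'
#' `log P(D >= len)`.  Used to score right-censored final segments, whose
#' true duration extends past the end of the observed sequence.
#'
#' @param model a [DurationModel-class].
#' @param len positive integer length (vectorized).
#' @return log-probability vector.
#' @export
durationLogSurvival <- function(model, len) {
  stopifnot(all(len >= 1))
  pmf <- exp(model@logPmf)
  tailMass <- exp(model@tailLogMass)
  revc <- rev(cumsum(rev(pmf))) + tailMass   # P(D >= lattice point i)
  out <- numeric(length(len))
  below <- len <= model@minLen
  out[below] <- 0
  mid <- len > model@minLen & len <= model@maxLen
  if (any(mid)) {
    i <- ceiling((len[mid] - model@minLen) / model@step) + 1L
    out[mid] <- log(revc[i])
  }
  above <- len > model@maxLen
  if (any(above)) {
    j <- ceiling((len[above] - model@maxLen) / model@step)
    out[above] <- model@tailLogMass + (j - 1) * model@tailLogP
  }
  out
}

#' Mean of a duration model
#'
#' @param model a [DurationModel-class].
#' @return expected segment length (body plus geometric tail).
#' @export
durationMean <- function(model) {
  lens <- seq(model@minLen, model@maxLen, by = model@step)
  m <- sum(lens * exp(model@logPmf))
  if (is.finite(model@tailLogMass)) {
    r <- exp(model@tailLogP)
    m <- m + exp(model@tailLogMass) * (model@maxLen + model@step / (1 - r))
  }
  m
}

#' Fit a duration model from observed lengths
#'
#' Gaussian-kernel-smoothed, renormalized pmf over the observed range, with
#' a geometric tail whose mass is `1/(n+1)` and whose decay matches the mean
#' excess of the upper decile of the data.  With `step = 3` the body lives
#' on the mod-3 lattice anchored at the minimum observed length.
#'
#' @param lengths positive integer lengths (>= 2 observations).
#' @param bandwidth kernel bandwidth in bases; default `bw.nrd0` of the data
#'   (floored at `step / 2`).
#' @param step lattice step (1, or 3 for codon-quantized durations).
#' @return a [DurationModel-class].
#' @export
fitDuration <- function(lengths, bandwidth = NULL, step = 1L) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L) stop("at least 2 duration observations required")
  if (any(lengths < 1)) stop("durations must be positive")
  step <- as.integer(step)
  if (step == 3L && any(lengths %% 3 != 0))
    stop("step-3 duration fitting requires lengths that are multiples of 3")
  n <- length(lengths)
  mn <- min(lengths); mx <- max(lengths)
  mx <- mn + ((mx - mn) %/% step) * step
  grid <- seq(mn, mx, by = step)
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(stats::bw.nrd0(lengths), error = function(e) 0)
  }
  bandwidth <- max(bandwidth, step / 2)
  dens <- rowSums(outer(grid, lengths, dnorm, sd = bandwidth))
  if (sum(dens) <= 0) dens <- rep(1, length(grid))
  bodyMass <- n / (n + 1)
  pmf <- dens / sum(dens) * bodyMass
  q90 <- as.numeric(quantile(lengths, 0.9, type = 1))
  excess <- mean(lengths[lengths >= q90]) - q90 + step
  r <- min(max(1 - step / excess, 1e-6), 0.999)
  durationModel(mn, mx, log(pmf), tailLogMass = log(1 / (n + 1)),
                tailLogP = log(r), step = step)
}
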