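# internal helpers shared across modules

# Fan a master seed out into n reproducible child seeds without disturbing
# the caller's RNG stream more than once. Children stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  if (n == 0L) return(integer(0))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Normal draws clipped to an instrument's legal range, with the location
# shifted (via uniroot) so that the *clipped* mean equals `mean`. Plain
# clipping would bias scores whose population mean sits close to a bound
# (e.g. a floor-hugging autism-scale distribution in typically developing
# children).
rnorm_clipped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  clipped_mean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    # E[ clip(X) ] for X ~ N(mu, sd)
    mu * (pnorm(b) - pnorm(a)) +
      sd * (stats::dnorm(a) - stats::dnorm(b)) +
      lo * pnorm(a) + hi * (1 - pnorm(b))
  }
  mu <- tryCatch(
    uniroot(function(m) clipped_mean(m) - mean,
            lower = mean - 6 * sd, upper = mean + 6 * sd)$root,
    error = function(e) mean
  )
  pmin(pmax(rnorm(n, mu, sd), lo), hi)
}

# jitter a probability on the logit scale (between-participant heterogeneity)
jitter_prob <- function(p, logit_sd) {
  if (p <= 0 || p >= 1 || logit_sd <= 0) return(p)
  plogis(rnorm(1, qlogis(p), logit_sd))
}

quadrant_of <- function(x, y) {
  dplyr::case_when(
    x < 0.5 & y < 0.5 ~ "TL",
    x >= 0.5 & y < 0.5 ~ "TR",
    x < 0.5 & y >= 0.5 ~ "BL",
    TRUE ~ "BR"
  )
}

quadrant_center <- function(quadrant, offset = 0.2) {
  dx <- ifelse(quadrant %in% c("TL", "BL"), -offset, offset)
  dy <- ifelse(quadrant %in% c("TL", "TR"), -offset, offset)
  cbind(x = 0.5 + dx, y = 0.5 + dy)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
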