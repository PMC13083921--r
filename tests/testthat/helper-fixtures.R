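## Shared fixtures: configurations, random Stokes states, angle utilities.

default_cfg <- function() polarimeter_config()

## random physical Stokes states, a mix of fully and partially polarised
random_states <- function(n, seed = 1) {
  set.seed(seed)
  t(replicate(n, {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    p <- if (stats::runif(1) < 0.5) 1 else stats::runif(1, 0.2, 0.99)
    c(1, p * u)
  }))
}

## smallest difference between two axis angles defined modulo pi
ang_diff_mod_pi <- function(a, b) {
  d <- abs((a - b) %% pi)
  pmin(d, pi - d)
}

sig_vec <- function(s) c(s$S_DC, s$S_QU1, s$S_QU2, s$S_v)

## exhaustive two-sided Mann-Whitney p-value by enumerating all group splits
mwu_exact_perm <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
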