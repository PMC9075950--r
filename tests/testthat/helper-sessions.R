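# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A mid-sized all-rewarded session with exploratory bouts only: the
# workhorse for alignment and recovery checks.
std_session <- function() {
  cached("std", function() {
    cfg <- sim_config(n_trials = 80, p_unrewarded = 0, p_pre_water_bout = 1,
                      seed = 7L)
    tr <- generate_trials(cfg)
    lk <- generate_licks(tr, cfg)
    structure(list(trials = tr, licks = lk$licks,
                   ground_truth = list(bouts = lk$bouts), config = cfg),
              class = "lick_session")
  })
}

session_t_end <- function(session) {
  max(session$trials$start_s) + session$config$interval_s + 5
}

# Von Mises sampler (Best & Fisher rejection scheme); independent of the
# package's circular statistics.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.5)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    out <- c(out, (mu + sign(u3[ok] - 0.5) * acos(f[ok])) %% (2 * pi))
  }
  out[seq_len(n)]
}

# Homogeneous Poisson train on [0, t_end].
rpois_train <- function(rate, t_end) {
  sort(runif(rpois(1, rate * t_end), 0, t_end))
}
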