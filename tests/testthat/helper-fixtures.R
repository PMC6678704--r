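# Shared fixtures, built in code at test time.

# Small, fast cohort configuration for pipeline-level tests. The planted
# protective effect is stronger than the package default so that an 80-
# patient fixture carries unambiguous signal; overrides win over the
# fixture defaults.
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_patients = 80, n_genes = 40, n_panel_genes = 15,
         beta_per_alteration = -0.2, n_signature_genes = 12,
         n_immunogenic_patients = 4, protein_length_range = c(40, 80),
         seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# Deterministic right-censored survival fixture with a planted binary
# effect; beta is the log hazard ratio of group 1 vs group 0.
surv_fixture <- function(n = 80, beta = 0, seed = 1, base = 0.3, cens = 0.1) {
  set.seed(seed)
  grp <- rep_len(c(0, 1), n)
  t_ev <- rexp(n, rate = base * exp(beta * grp))
  t_ce <- rexp(n, rate = cens)
  list(time = pmin(t_ev, t_ce), event = as.integer(t_ev <= t_ce), group = grp)
}

# Random sparse design + survival outcome for solver tests.
encox_problem <- function(n = 30, p = 50, seed = 1, beta = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", seq_len(p))))
  if (is.null(beta)) beta <- rep(0, p)
  eta <- drop(x %*% beta)
  t_ev <- rexp(n, rate = 0.25 * exp(eta))
  t_ce <- rexp(n, rate = 0.1)
  list(x = x, time = pmin(t_ev, t_ce), event = as.integer(t_ev <= t_ce))
}

# Independent Breslow partial log-likelihood, written as a plain double
# loop so solver internals can be checked against it.
breslow_loglik <- function(time, event, eta) {
  ll <- 0
  for (tk in sort(unique(time[event == 1]))) {
    risk <- time >= tk
    dk <- sum(event == 1 & time == tk)
    ll <- ll + sum(eta[event == 1 & time == tk]) - dk * log(sum(exp(eta[risk])))
  }
  ll
}

# Brute-force window enumeration oracle: all substrings of the given
# lengths that fit in a length-P protein and cover position p.
brute_force_windows <- function(P, p, lengths = 8:11) {
  count <- 0L
  for (L in lengths) {
    for (s in seq_len(max(P - L + 1L, 0L))) {
      if (s <= p && p <= s + L - 1L) count <- count + 1L
    }
  }
  count
}
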