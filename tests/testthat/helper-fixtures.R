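# random valid raw states used by property-style tests
random_raw_states <- function(n, seed) {
  set.seed(seed)
  data.frame(
    s0 = runif(n, 0.05, 0.6),
    m0 = runif(n, 5, 40),
    s_tau = runif(n, 0.05, 0.95),
    m_tau = runif(n, 4, 40)
  )
}

# a small two-factor dataset: solute means set exactly, additive time
# effect, and a fixed non-additive perturbation giving nonzero error MS
two_factor_data <- function(solute_means, time_effects = c(0, 0.5),
                            wiggle = 0.01) {
  g <- expand.grid(solute = names(solute_means),
                   time = paste0("t", seq_along(time_effects)),
                   stringsAsFactors = FALSE)
  g$value <- solute_means[g$solute] + time_effects[as.integer(sub("t", "", g$time))]
  # deterministic alternating perturbation breaks perfect additivity
  g$value <- g$value + wiggle * rep_len(c(1, -1), nrow(g))
  g
}
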