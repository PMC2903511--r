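# Shared fixtures: minimal bodies, oracle comparison helpers, and a cached
# mixture run (the long joint simulation is reused by several tests).

tiny_body <- function() {
  body_physiology(
    list(compartment("blood", 5, 0, tags = "blood"),
         compartment("liver", 2, 90, tags = "liver"),
         compartment("rest", 55, 222, tags = "muscle")),
    cardiac_output = 312, body_mass = 70)
}

# engine vs matrix-exponential closed form on one fixture
fixture_max_rel_err <- function(fix, t_end = 20, n_grid = 21, ...) {
  sys <- fixture_to_system(fix)
  res <- simulate_system(sys, t_end, report_grid = seq(0, t_end, length.out = n_grid), ...)
  worst <- 0
  for (j in seq_along(res$time)) {
    ref <- fix$solution(res$time[j])
    num <- res$amounts[j, seq_len(fix$n_states)]
    worst <- max(worst, max(abs(num - ref) / pmax(abs(ref), 1e-8)))
  }
  worst
}

# one shared mixture run (base + unit-weight variant), computed on demand
.mixture_cache <- new.env(parent = emptyenv())
mixture_cached <- function() {
  if (is.null(.mixture_cache$mx))
    .mixture_cache$mx <- run_mixture_scenario(variant_multipliers = 1)
  .mixture_cache$mx
}

# max relative deviation between two simulations of the same states,
# normalized per chemical by its peak amount
max_rel_deviation <- function(res_a, res_b, chemicals = NULL) {
  keys <- intersect(colnames(res_a$amounts), colnames(res_b$amounts))
  if (!is.null(chemicals)) {
    chem <- sub("\\|.*$", "", keys)
    keys <- keys[chem %in% chemicals]
  }
  worst <- 0
  for (ch in unique(sub("\\|.*$", "", keys))) {
    kk <- keys[startsWith(keys, paste0(ch, "|"))]
    scale <- max(abs(res_b$amounts[, kk]), 1e-300)
    worst <- max(worst, max(abs(res_a$amounts[, kk] - res_b$amounts[, kk])) / scale)
  }
  worst
}
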