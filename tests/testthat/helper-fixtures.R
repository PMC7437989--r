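# Shared fixtures built in code: a reference target set, its exact band
# areas, and shortcut renderers used across the suite.

ref_targets <- function() phase_targets(0.59, 0.25, 0.70)

ref_areas <- function(a_ref = 20000) invert_composition(ref_targets(), a_ref)

render_ref <- function(noise = noise_spec(scale = 0), seed = NULL,
                       baseline = c(50, -10), areas = ref_areas(), ...) {
  render_spectrum(areas, baseline = baseline, noise = noise, seed = seed, ...)
}

# Independent brute-force Kruskal-Wallis permutation oracle: enumerates
# every labelled assignment of the pooled values into groups of the given
# sizes and computes H with stats::kruskal.test each time. Deliberately
# shares no code with the package's rank-sum enumeration.
kw_brute_force <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  g_obs <- rep(seq_along(groups), sizes)
  H_obs <- unname(stats::kruskal.test(x, factor(g_obs))$statistic)
  assignments <- function(idx, sizes) {
    if (length(sizes) == 1L) return(list(list(idx)))
    first <- utils::combn(idx, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      for (rest in assignments(setdiff(idx, f), sizes[-1])) {
        out[[length(out) + 1L]] <- c(list(f), rest)
      }
    }
    out
  }
  Hs <- vapply(assignments(seq_along(x), sizes), function(a) {
    g <- integer(length(x))
    for (k in seq_along(a)) g[a[[k]]] <- k
    unname(stats::kruskal.test(x, factor(g))$statistic)
  }, 1.0)
  list(H = H_obs, p = mean(Hs >= H_obs - 1e-9), n = length(Hs))
}
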