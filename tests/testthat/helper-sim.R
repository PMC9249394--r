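# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 600 s mixed-population session with processed traces
small_session <- function() cached("small_session", {
  spec <- sim_session_spec(n_cells = 40, frac_place = 0.4,
                           frac_speed = 0.15, frac_conjunctive = 0.05,
                           duration_s = 600, seed = 42)
  ses <- simulate_session(spec)
  pr <- lapply(seq_len(spec$n_cells), function(j)
    process_trace(ses$f_soma[j, ], ses$f_neuropil[j, ],
                  spec$frame_rate_hz))
  ses$dff <- do.call(rbind, lapply(pr, `[[`, "dff"))
  ses$rates <- do.call(rbind, lapply(pr, `[[`, "rates"))
  ses$alpha <- vapply(pr, `[[`, numeric(1), "alpha")
  ses$spec <- spec
  ses
})

classified_small <- function() cached("classified_small", {
  ses <- small_session()
  classify_cells(ses$dff, ses$rates, ses$frames, ses$track, seed = 42)
})

# noiseless single-dendrite analysis at a permissive area threshold
# (the published length thresholds put thin/filopodium spines below
# the published 1 um^2 inclusion area; see vignette)
dendrite_roundtrip <- function() cached("dendrite_roundtrip", {
  spec <- sim_dendrite_spec(seed = 5)
  sim <- simulate_dendrite(spec)
  ses <- analyze_dendrite(sim$mask, min_area_um2 = 0.05)
  list(spec = spec, sim = sim, ses = ses)
})

circ_dist_cm <- function(a, b, circumference = 61.26) {
  d <- abs(a - b)
  pmin(d, circumference - d)
}
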