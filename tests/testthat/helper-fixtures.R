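# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small 3-spine phantom (one canonical spine per class) and its analysis
small_phantom <- function() fixture("small_phantom", function() {
  spec <- phantom_spec(
    field_of_view = c(15, 9, 9), seed = 42,
    spines = list(spine_spec(5, 0, 1.5, 0.6, 0.2),       # canonical mushroom
                  spine_spec(8, pi, 3.0, 0.3, 0.25),      # thin
                  spine_spec(11, pi / 2, 0.8, 0.45, 0.4)))  # stubby
  ph <- rasterize(spec)
  fit <- analyze_spines(ph$volume, start = c(0.1, 4.5, 4.5))
  list(spec = spec, ph = ph, fit = fit)
})

# 50 um benchmark: 20 mixed spines, noiseless and foreground-SNR-10 versions
benchmark_noiseless <- function() fixture("benchmark_noiseless", function() {
  spec <- standard_phantom(n_spines = 20, dendrite_length = 50, seed = 3)
  ph <- rasterize(spec)
  start <- c(0.1, spec$field_of_view[2] / 2, spec$field_of_view[3] / 2)
  fit <- analyze_spines(ph$volume, start)
  list(spec = spec, ph = ph, fit = fit,
       score = score_detection(fit$spines, ph$truth))
})

benchmark_noisy <- function() fixture("benchmark_noisy", function() {
  spec <- standard_phantom(n_spines = 20, dendrite_length = 50, seed = 3,
                           noise = list(type = "gaussian", sd = 10))
  ph <- rasterize(spec)
  start <- c(0.1, spec$field_of_view[2] / 2, spec$field_of_view[3] / 2)
  fit <- analyze_spines(ph$volume, start)
  list(spec = spec, ph = ph, fit = fit,
       score = score_detection(fit$spines, ph$truth))
})

# 13-time-point tracked series with scripted morphs and prunes:
# 10 thin protrusions at t0; 4 morph to mushroom at t = 6, 3 are pruned
tracking_series <- function() fixture("tracking_series", function() {
  n <- 10
  spines <- lapply(1:n, function(i)
    spine_spec(2 + (i - 1) * 2.6, (i - 1) * 2.39996, 2.8, 0.28, 0.25))
  spec <- phantom_spec(field_of_view = c(27.5, 10, 10), spines = spines,
                       seed = 11)
  events <- c(lapply(1:4, function(i) ev_morph(i, 6, 2.0, 0.6, 0.25)),
              list(ev_prune(5, 6), ev_prune(6, 4), ev_prune(7, 9)))
  script <- remodel_script(n_time = 13, events = events,
                           jitter_amplitude = 0.1)
  ser <- rasterize_series(spec, script)
  fits <- lapply(ser$volumes, analyze_spines, start = c(0.1, 5, 5))
  list(spec = spec, script = script, ser = ser, fits = fits,
       tracks = track_spines(fits))
})

# independent truth-table classifier used as the classification oracle
oracle_classify <- function(length, ratio, max_len = 5) {
  if (length > max_len) return("excluded")
  if (ratio >= 1.5) return("mushroom")
  if (length <= 1) return("stubby")
  "thin"
}

# brute-force gated matching: minimize sum of matched costs plus gate/2 per
# unmatched object, over all one-to-one partial matchings
oracle_gated_match <- function(cost, gate) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  best <- list(total = Inf, pairs = NULL)
  recurse <- function(i, used2, pairs, total) {
    if (total >= best$total) return()
    if (i > n1) {
      total2 <- total + (gate / 2) * (n1 - nrow(pairs)) +
        (gate / 2) * (n2 - nrow(pairs))
      if (total2 < best$total) best <<- list(total = total2, pairs = pairs)
      return()
    }
    recurse(i + 1, used2, pairs, total)          # leave i unmatched
    for (j in seq_len(n2)) {
      if (!used2[j] && cost[i, j] <= gate) {
        u <- used2; u[j] <- TRUE
        recurse(i + 1, u, rbind(pairs, c(i, j)), total + cost[i, j])
      }
    }
  }
  recurse(1, rep(FALSE, n2), matrix(integer(0), ncol = 2), 0)
  best$total <- best$total + 0  # force evaluation
  best
}

match_cost_total <- function(mt, cost, gate) {
  matched <- if (nrow(mt$pairs)) sum(cost[mt$pairs]) else 0
  matched + (gate / 2) * (length(mt$unmatched1) + length(mt$unmatched2))
}
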