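# Brute-force reference agglomerator: recomputes the complete-link
# (max cross-pair) dissimilarity from scratch over the current partition at
# every step, with the same deterministic earliest-member-time tie-break as
# the production path. O(n^3) per run; only usable at toy sizes.
oracle_complete_link <- function(fv, params) {
  D <- bedvitals:::dissimilarity_matrix(fv, params)
  clusters <- as.list(seq_len(nrow(fv)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_h <- Inf; best_key <- c(Inf, Inf)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(D[clusters[[a]], clusters[[b]]])
      e <- sort(c(min(fv$t_start[clusters[[a]]]),
                  min(fv$t_start[clusters[[b]]])))
      if (h < best_h - 1e-12 ||
          (abs(h - best_h) <= 1e-12 &&
           (e[1] < best_key[1] - 1e-12 ||
            (abs(e[1] - best_key[1]) <= 1e-12 && e[2] < best_key[2] - 1e-12)))) {
        best <- c(a, b); best_h <- h; best_key <- e
      }
    }
    heights <- c(heights, best_h)
    merges[[length(merges) + 1L]] <-
      c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Theta-cut partition of the oracle agglomeration.
oracle_cut <- function(fv, params) {
  oc <- oracle_complete_link(fv, params)
  memb <- seq_len(nrow(fv))
  for (s in seq_along(oc$heights)) {
    if (oc$heights[s] >= params$theta) break
    ids <- oc$merges[[s]]
    memb[memb %in% memb[ids]] <- min(memb[ids])
  }
  match(memb, unique(memb))
}

# Random admissible feature-vector table (small n, low-dim features).
random_feature_vectors <- function(n, seed, dim = 6) {
  set.seed(seed)
  fv <- tibble::tibble(
    idx = seq_len(n),
    t_start = sort(stats::runif(n, 0, 10)),
    features = lapply(seq_len(n),
                      function(i) stats::rnorm(dim) * exp(stats::rnorm(1, 0, 0.8)))
  )
  fv$magnitude <- vapply(fv$features, function(f) sqrt(sum(f^2)), numeric(1))
  fv[, c("idx", "t_start", "magnitude", "features")]
}

normalize_partition <- function(p) match(p, unique(p))

# Hand-made feature vector row for dissimilarity tests.
make_fv_row <- function(features, t_start, idx) {
  list(features = features, t_start = t_start, idx = idx)
}

# Steady-state amplitude of a filtered unit sine, by least squares on the
# middle of the signal (exact for a noiseless sinusoid).
steady_state_amplitude <- function(out, f, from_s, to_s) {
  t <- signal_time(out)
  sel <- t >= from_s & t <= to_s
  X <- cbind(sin(2 * pi * f * t[sel]), cos(2 * pi * f * t[sel]))
  co <- stats::lsfit(X, out$values[sel], intercept = FALSE)$coefficients
  sqrt(sum(co^2))
}

# Recall/precision of detected event times against truth.
match_events <- function(detected, truth, tol = 0.05) {
  tp <- sum(vapply(truth, function(b) any(abs(detected - b) < tol), logical(1)))
  list(recall = tp / length(truth),
       precision = if (length(detected))
         sum(vapply(detected, function(d) any(abs(truth - d) < tol),
                    logical(1))) / length(detected) else NA_real_)
}

# Shared end-to-end scoring shortcut for synthetic scenarios.
score_scenario <- function(spec, qrs_mode = "clean") {
  gen <- generate_bcg(spec)
  card <- cardiac_component(gen$recording$force)
  beats <- detect_beats(card)
  rp <- detect_qrs(gen$recording$ecg, mode = qrs_mode)
  rep <- score_recording(beats, rp, t_max = signal_duration(card) - 0.66)
  list(gen = gen, cardiac = card, beats = beats, rpeaks = rp, report = rep)
}
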