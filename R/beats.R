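#' Segmentation plan
#'
#' The BCG stream is processed in segments of `seg_len_s` seconds that
#' start every `seg_len_s - overlap_s` seconds. The default 10.66 s window
#' with 0.66 s overlap gives an effective step of 10 s; the overlap equals
#' the feature-vector window so that a candidate wave too close to a
#' segment's end to host a full feature window reappears, complete, at the
#' start of the next segment.
#'
#' @param seg_len_s Segment length in seconds.
#' @param overlap_s Overlap between consecutive segments in seconds.
#' @return An object of class `segment_plan`.
#' @export
segment_plan <- function(seg_len_s = 10.66, overlap_s = 0.66) {
  if (!(overlap_s >= 0 && overlap_s < seg_len_s)) {
    abort("need 0 <= overlap_s < seg_len_s.")
  }
  structure(list(seg_len_s = seg_len_s, overlap_s = overlap_s,
                 step_s = seg_len_s - overlap_s),
            class = "segment_plan")
}

#' Split a signal into overlapping segments
#'
#' Segments start every `plan$step_s` seconds from the start of the
#' signal; each spans `plan$seg_len_s` except possibly the last, which is
#' truncated at the end of the signal. A 5-minute recording yields 30
#' segments under the default plan.
#'
#' @param sig A [sampled_signal()].
#' @param plan A [segment_plan()].
#' @return A list of [sampled_signal()] segments; each carries its
#'   1-based id in attribute `segment_id`.
#' @export
segment_stream <- function(sig, plan = segment_plan()) {
  stopifnot(inherits(sig, "sampled_signal"))
  n <- length(sig)
  if (!n) return(list())
  dur <- signal_duration(sig)
  # a further segment is opened only when it reaches past the previous
  # segment's end (by at least half a sample), i.e. contributes more than
  # the shared overlap
  n_starts <- max(1L, ceiling(
    (dur - plan$overlap_s - 0.5 / sig$fs) / plan$step_s))
  starts <- seq(0, by = plan$step_s, length.out = n_starts)
  len <- round(plan$seg_len_s * sig$fs)
  lapply(seq_along(starts), function(k) {
    i0 <- round(starts[k] * sig$fs) + 1L
    i1 <- min(n, i0 + len - 1L)
    seg <- sampled_signal(sig$values[i0:i1], sig$fs,
                          t0 = sig$t0 + (i0 - 1) / sig$fs, units = sig$units)
    attr(seg, "segment_id") <- k
    seg
  })
}

#' Local maxima of a signal
#'
#' A sample is a local maximum when the first difference changes sign from
#' positive to non-positive, i.e. the point ends a strict rise. Plateaus
#' are attributed to their first sample; endpoints are never maxima.
#'
#' @param sig A [sampled_signal()].
#' @return A tibble with columns `index`, `time_s` and `value`.
#' @export
local_maxima <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  v <- sig$values
  n <- length(v)
  if (n < 3L) {
    return(tibble::tibble(index = integer(), time_s = numeric(),
                          value = numeric()))
  }
  d <- diff(v)
  idx <- which(d[-(n - 1L)] > 0 & d[-1L] <= 0) + 1L
  tibble::tibble(index = idx,
                 time_s = sig$t0 + (idx - 1) / sig$fs,
                 value = v[idx])
}

#' Build candidate-heartbeat feature vectors
#'
#' Each feature vector starts at a local maximum (a presumed upward BCG
#' wave tip, e.g. H, J or L) and holds every `downsample`-th sample of the
#' `window_s` seconds of signal that follow — 28 features at 84.8 Hz with
#' the 0.66 s window, the span of a 90-bpm cardiac cycle. Maxima whose
#' full window would overrun the segment are dropped; the segment overlap
#' guarantees they reappear in the next segment.
#'
#' @param segment A [sampled_signal()], normally one element of
#'   [segment_stream()] applied to the cardiac component.
#' @param maxima Tibble from [local_maxima()] on the same segment.
#' @param window_s Feature window length in seconds.
#' @param downsample Decimation factor within the window (phase 0: samples
#'   at offsets 0, `downsample`, 2\eqn{\times}`downsample`, ...).
#' @return A tibble with columns `idx` (chronological order), `t_start`,
#'   `magnitude` (Euclidean norm) and list-column `features`.
#' @export
build_feature_vectors <- function(segment, maxima, window_s = 0.66,
                                  downsample = 2) {
  stopifnot(inherits(segment, "sampled_signal"))
  n_feat <- round(window_s * segment$fs / downsample)
  offs <- seq(0L, by = as.integer(downsample), length.out = n_feat)
  n <- length(segment)
  keep <- maxima$index + offs[n_feat] <= n
  m <- maxima[keep, , drop = FALSE]
  if (!nrow(m)) {
    return(tibble::tibble(idx = integer(), t_start = numeric(),
                          magnitude = numeric(), features = list()))
  }
  feats <- lapply(m$index, function(i) segment$values[i + offs])
  tibble::tibble(
    idx = seq_len(nrow(m)),
    t_start = m$time_s,
    magnitude = vapply(feats, function(f) sqrt(sum(f^2)), numeric(1)),
    features = feats
  )
}

#' Clustering parameters
#'
#' Parameters of the gated inverse-cosine dissimilarity and of the
#' dendrogram cut. `alpha` bounds the admissible magnitude ratio between
#' two vectors; `t_min` is the minimum time between the anchoring maxima
#' (0.33 s, which caps the usable heart rate just above 180 bpm); `i_min`
#' is the minimum difference in chronological order, reflecting that a
#' cardiac cycle normally presents at least three upward waves (H, J, L) —
#' the detector runs with `i_min = 3` and falls back to 2 when wave
#' superimposition at high rates leaves only two maxima per cycle.
#' `theta` is the dissimilarity threshold (radians) at which the
#' dendrogram is cut. `i_min <= 1` disables the order gate entirely,
#' which is useful to demonstrate why it exists.
#'
#' @param alpha Magnitude-ratio bound (> 1).
#' @param t_min Minimum inter-vector time in seconds.
#' @param i_min Minimum chronological index difference.
#' @param theta Dendrogram cut height in radians, in (0, pi).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(alpha = 3, t_min = 0.33, i_min = 3, theta = 1.2) {
  if (alpha <= 1) abort("`alpha` must be > 1.")
  if (t_min <= 0) abort("`t_min` must be positive.")
  if (!(theta > 0 && theta < pi)) abort("`theta` must lie in (0, pi).")
  if (i_min < 0) abort("`i_min` must be >= 0.")
  structure(list(alpha = alpha, t_min = t_min, i_min = as.integer(i_min),
                 theta = theta),
            class = "cluster_params")
}

# Full conditional dissimilarity matrix over a feature-vector table.
# d(x, y) = acos(x'y / (|x||y|)) when the magnitude-ratio, minimum-time and
# minimum-index conditions all hold, else pi exactly.
dissimilarity_matrix <- function(fv, params = cluster_params()) {
  m <- nrow(fv)
  X <- do.call(rbind, fv$features)
  nrm <- fv$magnitude
  if (any(nrm == 0)) {
    abort("zero-magnitude feature vector.", class = "bedvitals_domain_error")
  }
  C <- tcrossprod(X / nrm)
  C[C > 1] <- 1; C[C < -1] <- -1
  D <- acos(C)
  ratio <- outer(nrm, nrm, "/")
  ok <- ratio <= params$alpha + 1e-12 & ratio >= 1 / params$alpha - 1e-12
  ok <- ok & (abs(outer(fv$t_start, fv$t_start, "-")) >= params$t_min - 1e-9)
  if (params$i_min > 1L) {
    ok <- ok & (abs(outer(fv$idx, fv$idx, "-")) >= params$i_min)
  }
  D[!ok] <- pi
  diag(D) <- 0
  D
}

#' Gated inverse-cosine dissimilarity between two feature vectors
#'
#' Returns the angle between the two shape vectors when all three
#' admissibility conditions hold — magnitude ratio within
#' `[1/alpha, alpha]`, anchoring maxima at least `t_min` apart, and
#' chronological orders at least `i_min` apart — and exactly `pi`
#' otherwise. Symmetric in its arguments and invariant to positive
#' rescaling of either vector while the magnitude-ratio condition holds.
#'
#' @param x,y Single rows of a [build_feature_vectors()] tibble (or lists
#'   with elements `features`, `t_start`, `idx`).
#' @param params A [cluster_params()].
#' @return Dissimilarity in radians, in `[0, pi]`.
#' @export
beat_dissimilarity <- function(x, y, params = cluster_params()) {
  row1 <- function(z) {
    if (is.data.frame(z)) z <- as.list(z[1, ])
    if (is.list(z$features)) z$features <- z$features[[1]]
    z
  }
  x <- row1(x); y <- row1(y)
  fv <- tibble::tibble(
    idx = c(x$idx, y$idx), t_start = c(x$t_start, y$t_start),
    magnitude = c(sqrt(sum(x$features^2)), sqrt(sum(y$features^2))),
    features = list(x$features, y$features))
  dissimilarity_matrix(fv, params)[1, 2]
}

#' Complete-link agglomerative clustering of feature vectors
#'
#' Starts from singleton clusters and repeatedly merges the pair of
#' clusters with the smallest complete-link (maximum cross-pair)
#' dissimilarity until one cluster remains. Because the pairwise measure
#' is conditional, the max proximity function is essential: one gated
#' (`pi`) pair suffices to keep two clusters apart below the cut. Merge
#' heights are monotone non-decreasing (asserted). Ties in merge height
#' are resolved deterministically in lexicographic order of the clusters'
#' earliest member times.
#'
#' @param fv Tibble from [build_feature_vectors()].
#' @param params A [cluster_params()].
#' @return An object of class `beat_dendrogram`: a list with `merge`
#'   (hclust-style m-1 x 2 matrix), `height`, `times` (leaf anchor times),
#'   `diss` (the pairwise dissimilarity matrix) and `params`.
#' @export
complete_link <- function(fv, params = cluster_params()) {
  m <- nrow(fv)
  if (m < 1L) abort("need at least one feature vector.")
  D <- dissimilarity_matrix(fv, params)
  merge <- matrix(0L, max(m - 1L, 0L), 2L)
  height <- numeric(max(m - 1L, 0L))
  code <- -seq_len(m)           # hclust convention: negative = leaf
  earliest <- fv$t_start
  active <- seq_len(m)
  Dm <- D
  if (m >= 2L) {
    for (s in seq_len(m - 1L)) {
      na <- length(active)
      sub <- Dm[active, active, drop = FALSE]
      sub[lower.tri(sub, diag = TRUE)] <- Inf
      h <- min(sub)
      cand <- which(sub <= h + 1e-12, arr.ind = TRUE)
      e <- earliest[active]
      key1 <- pmin(e[cand[, 1]], e[cand[, 2]])
      key2 <- pmax(e[cand[, 1]], e[cand[, 2]])
      pick <- order(key1, key2)[1L]
      i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
      merge[s, ] <- sort(c(code[i], code[j]))
      height[s] <- max(h, if (s > 1L) height[s - 1L] else 0)
      if (h < (if (s > 1L) height[s - 1L] else 0) - 1e-9) {
        abort("complete-link merge heights decreased; internal error.")
      }
      # fold j into i: complete link = elementwise max of the two rows
      newrow <- pmax(Dm[i, ], Dm[j, ])
      Dm[i, ] <- newrow; Dm[, i] <- newrow
      Dm[i, i] <- 0
      earliest[i] <- min(earliest[i], earliest[j])
      code[i] <- s
      active <- setdiff(active, j)
    }
  }
  structure(list(merge = merge, height = height, times = fv$t_start,
                 diss = D, params = params, n_leaves = m),
            class = "beat_dendrogram")
}

#' @export
print.beat_dendrogram <- function(x, ...) {
  cat(sprintf("<beat_dendrogram> %d leaves, %d merges, heights [%.3f, %.3f] rad\n",
              x$n_leaves, nrow(x$merge),
              if (length(x$height)) min(x$height) else NA,
              if (length(x$height)) max(x$height) else NA))
  invisible(x)
}

#' Merge history as a tibble
#'
#' @param x A `beat_dendrogram`.
#' @param ... Unused.
#' @return A tibble with one row per merge: `merge1`, `merge2` (hclust
#'   codes: negative values are leaves) and `height` in radians.
#' @exportS3Method generics::tidy
tidy.beat_dendrogram <- function(x, ...) {
  tibble::tibble(merge1 = x$merge[, 1], merge2 = x$merge[, 2],
                 height = x$height)
}

#' Convert a beat dendrogram to an hclust object
#'
#' Allows standard dendrogram plotting and inspection tools to be used.
#'
#' @param x A `beat_dendrogram`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.beat_dendrogram <- function(x, ...) {
  n <- x$n_leaves
  ord <- if (n == 1L) 1L else {
    expand <- function(code) {
      if (code < 0L) -code
      else c(expand(x$merge[code, 1]), expand(x$merge[code, 2]))
    }
    expand(n - 1L)
  }
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = as.character(seq_len(n)), method = "complete",
                 call = match.call(), dist.method = "gated inverse cosine"),
            class = "hclust")
}

#' Cut a dendrogram at the dissimilarity threshold
#'
#' A cluster of the final partition is any group whose internal merges all
#' lie strictly below `theta`; merges at or above `theta` are discarded.
#'
#' @param dend A `beat_dendrogram`.
#' @param theta Cut height in radians (default: the value stored in the
#'   dendrogram's parameters).
#' @return Integer membership vector over the leaves (1-based cluster ids,
#'   numbered by first appearance in leaf order).
#' @export
cut_dendrogram <- function(dend, theta = dend$params$theta) {
  n <- dend$n_leaves
  if (n == 0L) return(integer())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  grp <- vector("list", max(n - 1L, 0L))   # members of each merge node
  memb <- lapply(seq_len(n), identity)
  for (s in seq_len(nrow(dend$merge))) {
    if (dend$height[s] >= theta) break
    pick <- function(code) if (code < 0L) -code else grp[[code]][1L]
    a <- find(pick(dend$merge[s, 1])); b <- find(pick(dend$merge[s, 2]))
    parent[b] <- a
    grp[[s]] <- c(a)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Select the cluster that best represents the cardiac cycles
#'
#' From the partition obtained by cutting at `theta`, the cluster with the
#' most members is chosen; ties are broken by the lowest mean pairwise
#' dissimilarity among members, then by earliest first member. The chosen
#' members are the presumed same-type heartbeat waves of the segment.
#'
#' @param dend A `beat_dendrogram` from [complete_link()].
#' @param fv The feature-vector tibble the dendrogram was built from.
#' @param params A [cluster_params()].
#' @return A list with `members` (rows of `fv`, sorted by time),
#'   `cluster_id` and `partition` (the full membership vector).
#' @export
cut_and_select <- function(dend, fv, params = dend$params) {
  memb <- cut_dendrogram(dend, params$theta)
  if (!length(memb)) {
    return(list(members = fv[0, ], cluster_id = NA_integer_,
                partition = memb))
  }
  D <- dend$diss
  ids <- unique(memb)
  stats_tbl <- lapply(ids, function(id) {
    mem <- which(memb == id)
    md <- if (length(mem) > 1) {
      sub <- D[mem, mem]
      mean(sub[upper.tri(sub)])
    } else 0
    list(id = id, size = length(mem), mean_d = md,
         first_t = min(fv$t_start[mem]))
  })
  size <- vapply(stats_tbl, `[[`, numeric(1), "size")
  mean_d <- vapply(stats_tbl, `[[`, numeric(1), "mean_d")
  first_t <- vapply(stats_tbl, `[[`, numeric(1), "first_t")
  best <- order(-size, mean_d, first_t)[1L]
  chosen <- ids[best]
  mem <- which(memb == chosen)
  members <- fv[mem, ][order(fv$t_start[mem]), ]
  list(members = members, cluster_id = chosen, partition = memb)
}

# One clustering pass over a segment with a given minimum index difference.
# Vectors below 1e-6 mN in magnitude are numerical residue (a physically
# flat signal filtered in floating point), not candidate waves.
run_clustering <- function(segment, params, window_s, downsample) {
  mx <- local_maxima(segment)
  fv <- build_feature_vectors(segment, mx, window_s, downsample)
  fv <- fv[fv$magnitude > 1e-6, ]
  if (nrow(fv)) fv$idx <- seq_len(nrow(fv))
  if (nrow(fv) == 0L) return(numeric())
  dend <- complete_link(fv, params)
  sel <- cut_and_select(dend, fv, params)
  sort(sel$members$t_start)
}

# Population standard deviation of beat-to-beat rates; Inf when there are
# too few beats to assess consistency.
rate_sigma <- function(beat_times) {
  if (length(beat_times) < 3L) return(Inf)
  r <- 60 / diff(beat_times)
  sqrt(mean((r - mean(r))^2))
}

#' Detect heartbeats in one cardiac-filtered segment
#'
#' Runs the full chain (local maxima, feature vectors, complete-link
#' clustering, threshold cut, cluster selection) twice — first with
#' `i_min = 3`, then `i_min = 2` — and keeps the `i_min = 2` result only
#' when the population standard deviation of its beat-to-beat rates is
#' strictly smaller; equal or larger consistency keeps the `i_min = 3`
#' run. This accommodates high heart rates at which wave superimposition
#' leaves only two upward waves per cycle.
#'
#' @param segment A [sampled_signal()] holding the cardiac component of
#'   one segment.
#' @param params A [cluster_params()]; its `i_min` is ignored in favour of
#'   the dual 3/2 run unless `dual_run = FALSE`.
#' @param window_s,downsample Feature-vector window parameters, see
#'   [build_feature_vectors()].
#' @param dual_run If `FALSE`, a single pass with `params$i_min` is used
#'   (e.g. to study the effect of the index condition).
#' @return A tibble with columns `beat_time_s` and `i_min_used`. Empty
#'   (with a warning) when neither run selects at least two beats.
#' @export
detect_beats_segment <- function(segment, params = cluster_params(),
                                 window_s = 0.66, downsample = 2,
                                 dual_run = TRUE) {
  if (!dual_run) {
    bt <- run_clustering(segment, params, window_s, downsample)
    return(tibble::tibble(beat_time_s = bt,
                          i_min_used = rep(params$i_min, length(bt))))
  }
  p3 <- params; p3$i_min <- 3L
  p2 <- params; p2$i_min <- 2L
  b3 <- run_clustering(segment, p3, window_s, downsample)
  b2 <- run_clustering(segment, p2, window_s, downsample)
  if (length(b3) < 2L && length(b2) < 2L) {
    warn("fewer than two beats selected in both clustering runs; empty segment result.",
         class = "bedvitals_empty_segment")
    return(tibble::tibble(beat_time_s = numeric(), i_min_used = integer()))
  }
  if (rate_sigma(b2) < rate_sigma(b3)) {
    tibble::tibble(beat_time_s = b2, i_min_used = rep(2L, length(b2)))
  } else {
    tibble::tibble(beat_time_s = b3, i_min_used = rep(3L, length(b3)))
  }
}

#' Detect heartbeats across a whole recording
#'
#' Segments the cardiac component with `plan`, detects beats per segment
#' with [detect_beats_segment()], concatenates the per-segment detections
#' and attaches beat-to-beat rates with [beats_to_rates()]. A maximum
#' lying in the overlap of two segments can be detected by both; such
#' near-identical duplicates (within 0.05 s) are dropped, keeping the
#' earlier segment's detection. Within a segment consecutive beats are
#' always at least `t_min` apart (the dissimilarity gate enforces it);
#' across a boundary the two clustering passes may track different wave
#' types, so closer pairs can occur there — those intervals are
#' boundary-flagged and carry no rate.
#'
#' @param cardiac A [sampled_signal()], the output of
#'   [cardiac_component()].
#' @param params A [cluster_params()].
#' @param plan A [segment_plan()].
#' @param window_s,downsample Feature-window parameters.
#' @param dual_run Passed to [detect_beats_segment()].
#' @return A tibble (one row per beat) with columns `segment`,
#'   `beat_time_s`, `i_min_used`, `rate_bpm` and `boundary_flag` — see
#'   [beats_to_rates()].
#' @export
detect_beats <- function(cardiac, params = cluster_params(),
                         plan = segment_plan(), window_s = 0.66,
                         downsample = 2, dual_run = TRUE) {
  segs <- segment_stream(cardiac, plan)
  parts <- lapply(segs, function(seg) {
    out <- withCallingHandlers(
      detect_beats_segment(seg, params, window_s, downsample, dual_run),
      bedvitals_empty_segment = function(w) {
        bv_log("beats", "segment %d: no beats", attr(seg, "segment_id"))
        invokeRestart("muffleWarning")
      })
    if (nrow(out)) out$segment <- attr(seg, "segment_id")
    out
  })
  beats <- dplyr::bind_rows(parts)
  if (!nrow(beats)) {
    return(tibble::tibble(segment = integer(), beat_time_s = numeric(),
                          i_min_used = integer(), rate_bpm = integer(),
                          boundary_flag = logical()))
  }
  beats <- beats[order(beats$beat_time_s, beats$segment), ]
  dup <- c(FALSE, diff(beats$beat_time_s) < 0.05)
  beats_to_rates(beats[!dup, c("segment", "beat_time_s", "i_min_used")])
}

#' Attach beat-to-beat rates to a beat sequence
#'
#' The rate of the interval starting at beat `k` is
#' `round(60 / (t[k+1] - t[k]))` bpm. Intervals that span a segment
#' boundary join waves selected by two independent clustering passes,
#' possibly of different types, so they are flagged and carry no rate; the
#' evaluation excludes them (29 such intermediate cycles in a 5-minute
#' recording).
#'
#' @param beats Tibble with columns `segment` and `beat_time_s` (and
#'   optionally others, preserved).
#' @return The input with columns `rate_bpm` (integer, `NA` on flagged or
#'   final intervals) and `boundary_flag` added.
#' @export
beats_to_rates <- function(beats) {
  n <- nrow(beats)
  if (!n) {
    beats$rate_bpm <- integer()
    beats$boundary_flag <- logical()
    return(beats)
  }
  dt <- c(diff(beats$beat_time_s), NA_real_)
  boundary <- c(beats$segment[-1] != beats$segment[-n], NA)
  rate <- as.integer(round(60 / dt))
  rate[is.na(boundary) | boundary] <- NA_integer_
  beats$rate_bpm <- rate
  beats$boundary_flag <- ifelse(is.na(boundary), NA, boundary)
  beats
}

#' Overlay detected beats on the cardiac signal
#'
#' @param cardiac A [sampled_signal()].
#' @param beats Tibble from [detect_beats()].
#' @return A ggplot object.
#' @export
plot_beats <- function(cardiac, beats) {
  autoplot(cardiac) +
    ggplot2::geom_vline(data = beats,
                        ggplot2::aes(xintercept = .data$beat_time_s),
                        colour = "red", alpha = 0.5, linetype = 2) +
    ggplot2::labs(title = "Detected heartbeats")
}
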