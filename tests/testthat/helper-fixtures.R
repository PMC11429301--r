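# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use a different algorithmic route (brute force,
# step-through) than the implementation they check.

# quick transcript: one word every `gap` seconds
make_tr <- function(words, t0 = 0, gap = 0.5, speaker = "doctor",
                    dur = 0.3) {
  n <- length(words)
  starts <- t0 + (seq_len(n) - 1) * gap
  transcript(words, starts, starts + dur, speaker)
}

# uniform gaze stream from a label vector
make_gaze <- function(labels, fps = 10, t0 = 0) {
  gaze_stream(t0 + (seq_along(labels) - 1) / fps, labels, fps = fps)
}

# pose stream realizing prescribed armpit angles: shoulders and hips fixed,
# elbows placed by rotating the shoulder->hip direction by the angle
# (geometry written from first principles, independent of the simulator)
make_pose_angles <- function(left_deg, right_deg = left_deg, fps = 10,
                             vis = 0.95, elbow_vis = NULL, nose_y = 0.45,
                             present = TRUE) {
  n <- max(length(left_deg), length(right_deg), length(nose_y))
  left_deg <- rep_len(left_deg, n)
  right_deg <- rep_len(right_deg, n)
  nose_y <- rep_len(nose_y, n)
  vis <- rep_len(vis, n)
  elbow_vis <- rep_len(elbow_vis %||% vis, n)
  present <- rep_len(present, n)
  place <- function(sx, sy, hx, hy, deg, sign) {
    u <- c(hx - sx, hy - sy)
    u <- u / sqrt(sum(u^2))
    th <- sign * deg * pi / 180
    list(x = sx + 0.18 * (cos(th) * u[1] - sin(th) * u[2]),
         y = sy + 0.18 * (sin(th) * u[1] + cos(th) * u[2]))
  }
  el <- place(0.42, 0.55, 0.44, 0.75, left_deg, -1)
  er <- place(0.58, 0.55, 0.56, 0.75, right_deg, 1)
  pose_stream(tibble::tibble(
    t_s = (seq_len(n) - 1) / fps, present = present,
    x_0 = 0.5, y_0 = nose_y, v_0 = vis,
    x_11 = 0.42, y_11 = 0.55, v_11 = vis,
    x_12 = 0.58, y_12 = 0.55, v_12 = vis,
    x_13 = el$x, y_13 = el$y, v_13 = elbow_vis,
    x_14 = er$x, y_14 = er$y, v_14 = elbow_vis,
    x_23 = 0.44, y_23 = 0.75, v_23 = vis,
    x_24 = 0.56, y_24 = 0.75, v_24 = vis
  ), fps = fps)
}

# --- oracles ---------------------------------------------------------------

# O(n * w) recount of the gaze-class density
oracle_density <- function(stream, label, window_s = 5) {
  vapply(stream$t_s, function(t0) {
    inwin <- stream$t_s >= t0 - window_s / 2 & stream$t_s <= t0 + window_s / 2
    sum(stream$label[inwin] == label) / sum(inwin)
  }, numeric(1))
}

# exhaustive scan over every above-threshold run of a density curve
oracle_longest_run <- function(curve, rel_threshold = 0.6) {
  d <- curve$density
  t <- curve$t_s
  mx <- max(d)
  if (mx <= 0) return(NULL)
  mask <- d > rel_threshold * mx
  dt <- if (length(t) >= 2) median(diff(t)) else 1
  best <- NULL
  i <- 1
  while (i <= length(d)) {
    if (!mask[i]) { i <- i + 1; next }
    j <- i
    while (j < length(d) && mask[j + 1]) j <- j + 1
    end <- if (j < length(t)) t[j + 1] else t[j] + dt
    dur <- end - t[i]
    if (is.null(best) || dur > best$duration_s) {
      best <- list(start_s = t[i], end_s = end, duration_s = dur)
    }
    i <- j + 1
  }
  best
}

# brute force over all split points of the sorted values
oracle_split_two <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- NULL
  for (k in 1:(n - 1)) {
    left <- xs[1:k]
    right <- xs[(k + 1):n]
    wss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (is.null(best) || wss < best$wss - 1e-12) {
      best <- list(wss = wss, means = c(mean(left), mean(right)))
    }
  }
  best
}

# fixpoint step-through of the sit-to-stand chain automaton
oracle_chain_window <- function(val_times, exp_times, word_times,
                                pair_window_s = 5, chain_s = 20,
                                extend_s = 10) {
  val_times <- sort(val_times)
  if (length(val_times) < 2) return(NULL)
  pair <- which(diff(val_times) <= pair_window_s)
  if (length(pair) == 0) return(NULL)
  start <- val_times[pair[1]]
  if (length(exp_times) == 0) exp_times <- start
  chains <- lapply(sort(exp_times), function(e) {
    end <- e + chain_s
    used <- numeric()
    last_ext <- -Inf
    repeat {
      nxt <- val_times[val_times > e & val_times <= end &
                         !val_times %in% used]
      if (length(nxt) == 0) break
      used <- c(used, nxt[1])
      end <- end + extend_s
      last_ext <- nxt[1]
    }
    list(start = e, end = end, last_ext = last_ext)
  })
  exts <- vapply(chains, function(ch) ch$last_ext, numeric(1))
  pick <- if (any(is.finite(exts))) which.max(exts) else {
    which.max(vapply(chains, function(ch) ch$end, numeric(1)))
  }
  ch <- chains[[pick]]
  inchain <- word_times[word_times >= ch$start & word_times <= ch$end]
  end <- if (length(inchain) > 0) max(inchain) else ch$end
  c(start, max(start, end))
}

# random density-like curve on a uniform grid
random_curve <- function(n = 120, dt = 0.5) {
  d <- pmax(0, stats::filter(runif(n), rep(1 / 5, 5), sides = 2))
  d[is.na(d)] <- 0
  tibble::tibble(t_s = (seq_len(n) - 1) * dt, density = as.numeric(d))
}
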