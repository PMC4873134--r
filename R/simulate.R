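#' Simulate an isothermal boiling series from a known Antoine law
#'
#' Emulates the DSC measurement design: boiling temperatures observed at
#' a set of controlled pressures, with Gaussian onset-reading noise. The
#' default noise SD of 1 K matches the boiling-onset uncertainty of the
#' measurement technique.
#'
#' @param params generating [antoine_params()].
#' @param pressures pressures in kPa; each must be reachable by the law.
#' @param noise_sd SD of the onset noise in kelvin (default 1).
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return data frame with columns `T` (kelvin) and `P_kPa`.
#' @export
simulate_boiling_series <- function(params, pressures, noise_sd = 1,
                                    seed = NULL) {
  stopifnot(inherits(params, "antoine_params"), noise_sd >= 0)
  T0 <- boiling_temperature(params, pressures)   # errors if unreachable
  eps <- maybe_seeded(seed, rnorm(length(pressures), 0, noise_sd))
  data.frame(T = T0 + eps, P_kPa = pressures)
}

maybe_seeded <- function(seed, expr) {
  expr <- substitute(expr)
  if (is.null(seed)) eval(expr, parent.frame())
  else withr::with_seed(seed, eval(expr, parent.frame()))
}

#' Simulate a DSC boiling endotherm
#'
#' Generates an idealised heat-flow trace: a (optionally sloped)
#' baseline, a linear endothermic descent beginning exactly at the
#' requested onset temperature, a linear recovery back to baseline, and
#' additive Gaussian noise proportional to the endotherm depth.
#'
#' @param onset boiling-onset temperature in kelvin.
#' @param pressure_kPa cell pressure recorded with the trace.
#' @param depth endotherm depth in trace units (default 1).
#' @param width temperature width of the descent in kelvin (default 5).
#' @param noise_frac noise SD as a fraction of `depth` (default 0).
#' @param baseline_slope baseline slope in trace units per kelvin
#'   (default 0).
#' @param span kelvin extents of the grid before the onset and after the
#'   endotherm, default `c(30, 8)`.
#' @param dT grid step in kelvin (default 0.1).
#' @param seed optional integer seed.
#' @return a [dsc_trace()].
#' @export
simulate_dsc_trace <- function(onset, pressure_kPa, depth = 1, width = 5,
                               noise_frac = 0, baseline_slope = 0,
                               span = c(30, 8), dT = 0.1, seed = NULL) {
  stopifnot(width > 0, depth > 0, noise_frac >= 0, dT > 0)
  recovery <- width / 2
  T <- seq(onset - span[1], onset + width + recovery + span[2], by = dT)
  base <- baseline_slope * (T - T[1])
  endo <- numeric(length(T))
  descending <- T >= onset & T < onset + width
  endo[descending] <- -depth * (T[descending] - onset) / width
  recovering <- T >= onset + width & T < onset + width + recovery
  endo[recovering] <- -depth * (1 - (T[recovering] - onset - width) / recovery)
  noise <- maybe_seeded(seed, rnorm(length(T), 0, noise_frac * depth))
  dsc_trace(T, base + endo + noise, pressure_kPa)
}

## rasterise one rotated ellipse into the frame; returns updated matrix
draw_ellipse <- function(m, cx, cy, a, b, theta, value) {
  r <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(cy - r)):min(nrow(m), ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(ncol(m), ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (x * ct + y * st) / a)
  v <- outer(dy, dx, function(y, x) (-x * st + y * ct) / b)
  inside <- u^2 + v^2 <= 1
  m[rows, cols][inside] <- value
  m
}

## axis-aligned square blob of exactly `side^2` pixels
draw_square <- function(m, cx, cy, side, value) {
  rows <- round(cy):(round(cy) + side - 1L)
  cols <- round(cx):(round(cx) + side - 1L)
  m[rows, cols] <- value
  m
}

#' Render synthetic cage-bioassay frames with known fly counts
#'
#' Draws dark fly blobs on a light background (the white mesh cage
#' ceiling seen from below), one frame per requested count, and stores
#' the generating count as ground truth. Blobs are ellipses of
#' approximately `fly_area_px` pixels with jittered aspect and
#' orientation; `shape = "square"` draws axis-aligned squares of exactly
#' `fly_area_px` pixels (requires a square number), useful for exact
#' area bookkeeping. Non-overlapping placement is rejection-sampled; by
#' default overlap is permitted above 40 flies to mimic crowding under
#' the lure.
#'
#' @param counts integer vector of fly counts, one frame per element.
#' @param width,height frame size in pixels (default 200 x 200).
#' @param fly_area_px nominal area of one fly in pixels (default 25).
#' @param shape `"ellipse"` (default) or `"square"`.
#' @param overlap_allowed allow blobs to overlap; default `NULL` means
#'   allowed only for frames with more than 40 flies.
#' @param bg,fg background and fly intensities (default 220 and 40).
#' @param noise_sd SD of Gaussian pixel noise added to the frame,
#'   clamped to \[0, 255\] (default 6).
#' @param seed optional integer seed.
#' @return list of [cage_image()]s with `ground_truth_count` set.
#' @examples
#' frames <- render_cage_frames(c(0, 10, 40), seed = 7)
#' vapply(frames, function(f) f$ground_truth_count, numeric(1))
#' @export
render_cage_frames <- function(counts, width = 200L, height = 200L,
                               fly_area_px = 25, shape = c("ellipse", "square"),
                               overlap_allowed = NULL,
                               bg = 220, fg = 40, noise_sd = 6,
                               seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(fly_area_px >= 1, all(counts >= 0), all(counts %% 1 == 0))
  if (shape == "square") {
    side <- sqrt(fly_area_px)
    if (side %% 1 != 0)
      lv_stop("square blobs need fly_area_px to be a perfect square",
              "lurevp_parameter_error")
    side <- as.integer(side)
  }
  maybe_seeded(seed, {
    lapply(counts, function(nfly) {
      m <- matrix(bg, nrow = height, ncol = width)
      allow <- if (is.null(overlap_allowed)) nfly > 40 else overlap_allowed
      margin <- if (shape == "square") side + 1 else ceiling(sqrt(fly_area_px)) + 3
      placed <- matrix(numeric(0), ncol = 2)
      sep <- 2 * sqrt(fly_area_px / pi) * 1.6 + 2   # centre distance ruling out overlap
      if (nfly > 0) {
        for (i in seq_len(nfly)) {
          for (attempt in seq_len(2000L)) {
            cx <- stats::runif(1, margin, width - margin)
            cy <- stats::runif(1, margin, height - margin)
            ok <- allow || nrow(placed) == 0 ||
              all((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 > sep^2)
            if (ok) break
            if (attempt == 2000L)
              lv_stop("cannot place non-overlapping flies: frame at capacity",
                      "lurevp_capacity_error")
          }
          placed <- rbind(placed, c(cx, cy))
          if (shape == "square") {
            m <- draw_square(m, cx, cy, side, fg)
          } else {
            aspect <- stats::runif(1, 1.1, 1.5)
            a <- sqrt(fly_area_px * aspect / pi)
            b <- sqrt(fly_area_px / (aspect * pi))
            m <- draw_ellipse(m, cx, cy, a, b, stats::runif(1, 0, pi), fg)
          }
        }
      }
      if (noise_sd > 0)
        m <- pmin(255, pmax(0, m + rnorm(length(m), 0, noise_sd)))
      cage_image(m, ground_truth_count = nfly)
    })
  })
}

#' Simulate a multi-replicate lure response-count series
#'
#' Generates per-frame treated/untreated counts under the constrained
#' exponential mean model: at frame time `t`,
#' `p(t) = p_max - (p_max - 0.5) exp(-t/k)` and
#' `n_treated ~ Binomial(n_flies, p(t))`, with
#' `n_untreated = n_flies - n_treated`. Frames and replicates are
#' independent — a deliberate simplification of real flies, which
#' persist between 5-second frames. Defaults follow the bioassay design:
#' frames every 5 s over 0--170 s, five replicate cages.
#'
#' @param true_pmax asymptotic response probability in \[0.5, 1\].
#' @param true_k time constant in seconds.
#' @param n_flies flies visible per frame (treated + untreated views).
#' @param n_replicates number of replicate cages (default 5).
#' @param frame_interval seconds between frames (default 5).
#' @param duration last frame time in seconds (default 170).
#' @param seed optional integer seed.
#' @return a [response_series()] covering all replicates.
#' @examples
#' s <- simulate_response_series(0.91, 15, n_flies = 30, seed = 1)
#' fit_response_series(s)
#' @export
simulate_response_series <- function(true_pmax, true_k, n_flies = 30L,
                                     n_replicates = 5L, frame_interval = 5,
                                     duration = 170, seed = NULL) {
  if (true_pmax < 0.5 || true_pmax > 1)
    lv_stop("true_pmax must lie in [0.5, 1]", "lurevp_parameter_error")
  if (true_k <= 0)
    lv_stop("true_k must be positive", "lurevp_parameter_error")
  stopifnot(n_flies >= 0, n_replicates >= 1)
  t <- seq(0, duration, by = frame_interval)
  p <- true_pmax - (true_pmax - 0.5) * exp(-t / true_k)
  maybe_seeded(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      n_tr <- rbinom(length(t), n_flies, p)
      data.frame(replicate_id = r, time_s = t,
                 n_treated = n_tr, n_untreated = n_flies - n_tr)
    })
    d <- do.call(rbind, reps)
    response_series(d$time_s, d$n_treated, d$n_untreated, d$replicate_id)
  })
}
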