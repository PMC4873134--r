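# independent oracles and hand-built fixtures used across test files

# Antoine evaluation written out directly, independent of the package path
oracle_antoine_p <- function(A, B, C, T) 10^(A - B / (T + C))

# d ln(P)/dT by central finite difference on the raw law
oracle_dlnp_dT <- function(A, B, C, T, h = 1e-3) {
  (log(oracle_antoine_p(A, B, C, T + h)) -
     log(oracle_antoine_p(A, B, C, T - h))) / (2 * h)
}

# Spearman rho by rank-then-Pearson, the brute-force route
oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# between-group sum of squares by explicit group means
oracle_group_ss <- function(y, g) {
  gb <- split(y, g)
  sum(vapply(gb, function(v) length(v) * (mean(v) - mean(y))^2, numeric(1)))
}

# one-way ANOVA F for two groups, closed form
oracle_anova_f <- function(y, g) {
  ssb <- oracle_group_ss(y, g)
  ssw <- sum(unlist(lapply(split(y, g), function(v) (v - mean(v))^2)))
  k <- length(unique(g)); n <- length(y)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# piecewise-linear DSC trace: flat (or sloped) baseline, linear drop at
# `onset`, no noise; built by hand rather than via the generator
make_piecewise_trace <- function(onset = 450, pressure = 5, slope_base = 0,
                                 drop_slope = -0.2, from = onset - 25,
                                 to = onset + 12, dT = 0.1) {
  T <- seq(from, to, by = dT)
  y <- slope_base * (T - T[1]) + pmin(0, (T - onset)) * 0 +
    ifelse(T >= onset, drop_slope * (T - onset), 0)
  dsc_trace(T, y, pressure)
}

# frame with `n` disjoint square blobs of exactly `area` dark pixels
make_blob_frame <- function(n, area = 25, size = 120, fg = 30, bg = 230) {
  side <- as.integer(sqrt(area))
  stopifnot(side^2 == area)
  m <- matrix(bg, size, size)
  per_row <- floor(size / (side + 4))
  stopifnot(n <= per_row^2)
  for (i in seq_len(n)) {
    r <- ((i - 1) %/% per_row) * (side + 4) + 2
    c <- ((i - 1) %% per_row) * (side + 4) + 2
    m[r:(r + side - 1), c:(c + side - 1)] <- fg
  }
  cage_image(m, ground_truth_count = n)
}

table2_cl <- function() antoine_params(9.32104, 4291.92, -0.998176,
                                       498.0, 587.4, "CL")
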