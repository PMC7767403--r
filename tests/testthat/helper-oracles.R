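# Independent oracles and small fixture builders used across the suite.

# Brute-force rotation search: coarse global axis-angle grid (Fibonacci-
# sphere axes x angle sweep) followed by grid refinement to below a 0.1
# degree step.  Independent of the SVD-based superposition it checks.
oracle_grid_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  eval_v <- function(v) {
    R <- bindshift:::rot_axis_angle(v)
    sqrt(mean(rowSums((X %*% R - Y)^2)))
  }
  # Fibonacci-sphere axes
  n_ax <- 120L
  i <- seq_len(n_ax) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  zc <- 1 - 2 * i / n_ax
  r <- sqrt(pmax(0, 1 - zc^2))
  axes <- cbind(r * cos(phi), r * sin(phi), zc)
  angles <- seq(10, 180, by = 10) * pi / 180
  best_v <- c(0, 0, 0); best <- eval_v(best_v)
  for (a in seq_len(n_ax)) for (th in angles) {
    v <- axes[a, ] * th
    val <- eval_v(v)
    if (val < best) { best <- val; best_v <- v }
  }
  # shrink a 3x3x3 axis-angle grid around the incumbent
  step <- 0.2
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  while (step > 0.0008) {          # 0.0008 rad = 0.046 degrees
    for (k in seq_len(nrow(offs))) {
      v <- best_v + offs[k, ] * step
      val <- eval_v(v)
      if (val < best) { best <- val; best_v <- v }
    }
    step <- step * 0.6
  }
  best
}

# Moving-block bootstrap standard error of the mean of an autocorrelated
# series: resample overlapping blocks with replacement and take the sd of
# the resampled means.
mbb_se <- function(x, block_len = 100L, n_boot = 1000L, seed = 1L) {
  n <- length(x)
  n_blocks <- ceiling(n / block_len)
  withr::with_seed(seed, {
    means <- replicate(n_boot, {
      starts <- sample.int(n - block_len + 1L, n_blocks, replace = TRUE)
      idx <- as.vector(outer(0:(block_len - 1L), starts, `+`))[seq_len(n)]
      mean(x[idx])
    })
    stats::sd(means)
  })
}

# Minimal water-pair structure: a donor water (with one hydrogen) and an
# acceptor water at distance `d` along x, the hydrogen at `angle_deg` off
# the donor-acceptor axis.
tiny_donor_acceptor <- function(d, angle_deg) {
  th <- angle_deg * pi / 180
  atoms <- data.frame(
    serial = 1:3,
    name = c("OW", "HW1", "OW"),
    element = c("O", "H", "O"),
    res_name = "HOH", res_seq = c(1L, 1L, 2L), chain_id = "W",
    x = c(0, cos(th), d), y = c(0, sin(th), 0), z = 0,
    record = "HETATM", stringsAsFactors = FALSE)
  pdb_structure(atoms)
}

# Four random mean-energy cells (one per variant x environment).
random_cells <- function() {
  cells <- list()
  for (v in c("AT", "GC")) for (e in c("Complex", "DNA"))
    cells[[paste(v, e)]] <- mean_energies(
      v, e, mean_vdw = stats::rnorm(1, -100, 10),
      mean_el = stats::rnorm(1, -200, 20),
      se_vdw = stats::runif(1, 0, 1), se_el = stats::runif(1, 0, 1),
      n_samples = 10L)
  cells
}

# Swap the AT/GC labels of a set of cells.
swap_variants <- function(cells) {
  lapply(cells, function(c) {
    c$variant <- if (c$variant == "AT") "GC" else "AT"
    c
  })
}
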