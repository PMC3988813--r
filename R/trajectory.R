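# Einstein/MSD self-diffusion estimation from particle trajectories,
# with a Brownian-motion fixture generator of known ground truth.
#
# Internal trajectory units: positions nm, frame time ps; estimated
# diffusivities are returned in m^2/s (1 nm^2/ps = 1e-6 m^2/s).

.NM2PS_PER_M2S <- 1e6  # m^2/s -> nm^2/ps

#' Construct a trajectory object
#'
#' @param positions numeric array frames x particles x 3 (nm)
#' @param dt time per frame (ps)
#' @param box optional periodic box lengths (nm)
#' @param wrapped are the coordinates wrapped into the box?
#' @return object of class `trajectory`
#' @export
trajectory <- function(positions, dt, box = NULL, wrapped = FALSE) {
  d <- dim(positions)
  if (length(d) != 3 || d[3] != 3)
    stop("positions must be a frames x particles x 3 array")
  if (d[1] < 2) stop("need at least 2 frames")
  if (dt <= 0) stop("dt must be positive")
  if (wrapped && is.null(box)) stop("wrapped trajectories need a box")
  structure(list(positions = positions, dt = dt, box = box,
                 wrapped = wrapped),
            class = "trajectory")
}

#' Generate a Brownian trajectory with known diffusivity
#'
#' Independent Gaussian displacements with per-axis step variance
#' 2 D dt. With a box, particles start uniformly inside it and the
#' coordinates are wrapped; otherwise all particles start at the
#' origin. Deterministic for a fixed seed.
#'
#' @param n_particles number of independent walkers
#' @param D_true ground-truth diffusivity (m^2/s)
#' @param dt frame time (ps)
#' @param n_frames number of frames (>= 2)
#' @param seed RNG seed
#' @param box optional periodic box (nm); output is wrapped when given
#' @return `trajectory`
#' @export
#' @examples
#' t <- generate_brownian(10, 2.6e-9, 1, 100, seed = 1)
#' dim(t$positions)
generate_brownian <- function(n_particles, D_true, dt, n_frames, seed,
                              box = NULL) {
  stopifnot(n_particles >= 1, D_true >= 0, dt > 0, n_frames >= 2)
  set.seed(seed)
  sd_step <- sqrt(2 * D_true * .NM2PS_PER_M2S * dt)
  pos <- array(0, dim = c(n_frames, n_particles, 3))
  start <- if (is.null(box)) matrix(0, n_particles, 3)
           else sapply(box, function(L) stats::runif(n_particles, 0, L))
  for (ax in 1:3) {
    steps <- matrix(stats::rnorm((n_frames - 1) * n_particles, sd = sd_step),
                    n_frames - 1, n_particles)
    walks <- matrix(apply(steps, 2, cumsum), n_frames - 1, n_particles)
    pos[, , ax] <- rbind(start[, ax], sweep(walks, 2, start[, ax], `+`))
  }
  if (!is.null(box)) {
    for (ax in 1:3) pos[, , ax] <- pos[, , ax] %% box[ax]
    trajectory(pos, dt, box = box, wrapped = TRUE)
  } else trajectory(pos, dt)
}

#' Unwrap periodic-boundary coordinates
#'
#' Accumulates minimum-image frame-to-frame displacements so
#' coordinates become continuous. Frame-to-frame motion larger than
#' half the box on any axis is aliased and cannot be recovered
#' (documented limitation of the minimum-image construction).
#'
#' @param t wrapped `trajectory` with a box
#' @return unwrapped `trajectory` (same box, `wrapped = FALSE`)
#' @export
unwrap <- function(t) {
  if (is.null(t$box)) stop("unwrap needs a periodic box")
  if (!t$wrapped) return(t)
  pos <- t$positions
  for (ax in 1:3) {
    x <- pos[, , ax, drop = FALSE]
    dim(x) <- dim(pos)[1:2]
    d <- diff(x)
    d <- d - t$box[ax] * round(d / t$box[ax])
    cum <- matrix(apply(d, 2, cumsum), nrow(d), ncol(d))
    pos[, , ax] <- rbind(x[1, , drop = FALSE],
                         cum + rep(x[1, ], each = nrow(d)))
  }
  trajectory(pos, t$dt, box = t$box, wrapped = FALSE)
}

# smallest highly-composite FFT length >= n
fft_length <- function(n) stats::nextn(n, c(2, 3, 5))

#' Time- and particle-averaged mean square displacement
#'
#' MSD(tau) averaged over all time origins and particles, computed
#' with the FFT autocorrelation algorithm (O(T log T) per particle;
#' equivalent to the naive double loop). Lags run from 0 up to
#' `max_lag_fraction` of the trajectory length.
#'
#' @param t unwrapped `trajectory`
#' @param max_lag_fraction largest lag as a fraction of the run
#'   (default 0.5)
#' @param per_particle keep the per-particle MSD matrix (needed for
#'   particle-resampled uncertainty in [estimate_D()])
#' @return data.frame of class `msd_curve` with columns `lag` (ps) and
#'   `msd` (nm^2); per-particle matrix in attribute "per_particle"
#' @export
msd <- function(t, max_lag_fraction = 0.5, per_particle = TRUE) {
  if (t$wrapped) stop("msd needs an unwrapped trajectory; call unwrap()")
  stopifnot(max_lag_fraction > 0, max_lag_fraction <= 1)
  nT <- dim(t$positions)[1]
  nP <- dim(t$positions)[2]
  L <- max(1, floor(max_lag_fraction * (nT - 1)))
  pad <- fft_length(2 * nT)
  msd_pp <- matrix(0, L + 1, nP)
  chunk <- 256
  for (ax in 1:3) {
    X <- t$positions[, , ax, drop = FALSE]
    dim(X) <- c(nT, nP)
    for (c0 in seq(1, nP, by = chunk)) {
      cols <- c0:min(nP, c0 + chunk - 1)
      Xc <- X[, cols, drop = FALSE]
      A <- stats::mvfft(rbind(Xc, matrix(0, pad - nT, length(cols))))
      S2 <- Re(stats::mvfft(A * Conj(A), inverse = TRUE)) / pad
      D2 <- Xc^2
      Q <- 2 * colSums(D2)
      for (tau in 0:L) {
        if (tau > 0) Q <- Q - D2[tau, ] - D2[nT - tau + 1, ]
        msd_pp[tau + 1, cols] <- msd_pp[tau + 1, cols] +
          (Q - 2 * S2[tau + 1, ]) / (nT - tau)
      }
    }
  }
  out <- data.frame(lag = (0:L) * t$dt, msd = rowMeans(msd_pp))
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "dt") <- t$dt
  if (per_particle) attr(out, "per_particle") <- msd_pp
  out
}

# naive O(T^2) reference used to validate the FFT algorithm on small
# cases
msd_naive <- function(t, max_lag_fraction = 0.5) {
  nT <- dim(t$positions)[1]
  L <- max(1, floor(max_lag_fraction * (nT - 1)))
  vals <- vapply(0:L, function(tau) {
    if (tau == 0) return(0)
    d <- t$positions[(1 + tau):nT, , , drop = FALSE] -
         t$positions[1:(nT - tau), , , drop = FALSE]
    mean(apply(d^2, c(1, 2), sum))
  }, numeric(1))
  data.frame(lag = (0:L) * t$dt, msd = vals)
}

#' Einstein-relation diffusivity from an MSD curve
#'
#' Least-squares slope of MSD versus lag over the fit window, divided
#' by 2 x dimensionality. The default window spans 10 to 50 percent of
#' the largest lag, excluding the shortest (ballistic/caging) lags.
#' When the curve carries per-particle MSDs, the standard error comes
#' from the spread of per-particle slopes (independent walkers);
#' otherwise from the OLS fit. A block diagnostic reports the running
#' slope over successive lag blocks and flags runs whose last two
#' blocks disagree by more than 10 percent.
#'
#' @param msd_curve `msd_curve` from [msd()]
#' @param fit_window c(lag_min, lag_max) in ps; default NULL uses
#'   the 10-50 percent window
#' @param dimensionality spatial dimensions of the walk (default 3)
#' @param block_ps lag-block width for the convergence diagnostic (ps)
#' @return list of class `diffusion_estimate`: `D`, `stderr` (m^2/s),
#'   `fit_window`, `msd_curve`, `convergence`, `converged`
#' @export
estimate_D <- function(msd_curve, fit_window = NULL, dimensionality = 3,
                       block_ps = 200) {
  lag <- msd_curve$lag
  if (is.null(fit_window))
    fit_window <- c(0.1, 0.5) * max(lag)
  sel <- which(lag >= fit_window[1] & lag <= fit_window[2] & lag > 0)
  if (length(sel) == 0) stop("empty fit window")
  if (length(sel) < 5) stop("need at least 5 MSD points in the fit window")
  fit <- stats::lm(msd_curve$msd[sel] ~ lag[sel])
  slope <- unname(stats::coef(fit)[2])      # nm^2/ps
  D <- max(0, slope / (2 * dimensionality)) / .NM2PS_PER_M2S
  pp <- attr(msd_curve, "per_particle")
  if (!is.null(pp) && ncol(pp) >= 2) {
    x <- lag[sel] - mean(lag[sel])
    slopes <- colSums(x * pp[sel, , drop = FALSE]) / sum(x^2)
    stderr <- stats::sd(slopes) / sqrt(ncol(pp)) /
      (2 * dimensionality) / .NM2PS_PER_M2S
  } else {
    sfit <- suppressWarnings(summary(fit))  # exact lines trip lm's warning
    stderr <- sfit$coefficients[2, 2] /
      (2 * dimensionality) / .NM2PS_PER_M2S
  }
  # running-slope diagnostic over successive lag blocks
  breaks <- seq(0, max(lag), by = block_ps)
  if (length(breaks) < 2) breaks <- range(lag)
  conv <- do.call(rbind, lapply(seq_len(length(breaks) - 1), function(b) {
    s <- which(lag > breaks[b] & lag <= breaks[b + 1])
    if (length(s) < 2) return(NULL)
    f <- stats::lm(msd_curve$msd[s] ~ lag[s])
    data.frame(block_end = breaks[b + 1],
               D = unname(stats::coef(f)[2]) / (2 * dimensionality) /
                 .NM2PS_PER_M2S)
  }))
  converged <- TRUE
  if (!is.null(conv) && nrow(conv) >= 2) {
    last <- conv$D[nrow(conv)]; prev <- conv$D[nrow(conv) - 1]
    if (prev > 0) converged <- abs(last - prev) / prev < 0.10
  }
  structure(list(D = D, stderr = stderr, fit_window = fit_window,
                 msd_curve = msd_curve[, c("lag", "msd")],
                 convergence = conv, converged = converged),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("diffusion_estimate: D = %.4g +/- %.2g m^2/s (window %g-%g ps)%s\n",
              x$D, x$stderr, x$fit_window[1], x$fit_window[2],
              if (x$converged) "" else " [non-asymptotic]"))
  invisible(x)
}

#' Trajectory text I/O
#'
#' Plain multi-frame format: a header line `frames particles dt
#' [box]`, then one line per atom per frame with x y z (nm), frames
#' concatenated.
#'
#' @param t `trajectory`
#' @param path file path
#' @return `write_trajectory`: path invisibly; `read_trajectory`: a
#'   `trajectory`
#' @export
write_trajectory <- function(t, path) {
  d <- dim(t$positions)
  hdr <- c(d[1], d[2], t$dt, if (!is.null(t$box)) t$box)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = " "), con)
  m <- matrix(aperm(t$positions, c(3, 2, 1)), ncol = 3, byrow = TRUE)
  utils::write.table(format(m, digits = 10), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- as.numeric(strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]])
  nT <- hdr[1]; nP <- hdr[2]; dt <- hdr[3]
  box <- if (length(hdr) >= 6) hdr[4:6] else NULL
  m <- as.matrix(utils::read.table(path, skip = 1))
  pos <- aperm(array(t(m), dim = c(3, nP, nT)), c(3, 2, 1))
  trajectory(pos, dt, box = box, wrapped = FALSE)
}
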