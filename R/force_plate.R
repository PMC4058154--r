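# Four-sensor force-plate model (balance-board class device, 45 x 26.5 cm).
# Vertical forces only: shear forces and moments are neglected, as they are
# on the real board. Coordinates: x = mediolateral (width, right positive),
# y = anteroposterior (depth, front positive), origin at the plate center.

#' Force-plate geometry
#'
#' @param width_cm plate width (mediolateral), default 45 cm
#' @param depth_cm plate depth (anteroposterior), default 26.5 cm
#' @return a `plate_geometry` object
#' @export
plate_geometry <- function(width_cm = 45, depth_cm = 26.5) {
  stopifnot(width_cm > 0, depth_cm > 0)
  structure(list(width_cm = width_cm, depth_cm = depth_cm),
            class = "plate_geometry")
}

#' Center of pressure from the four corner forces
#'
#' x = (W/2) * ((TR + BR) - (TL + BL)) / sum(F);
#' y = (D/2) * ((TL + TR) - (BL + BR)) / sum(F).
#' TL/TR are the front (top) corners, BL/BR the back corners.
#'
#' @param TL,TR,BL,BR vertical corner forces (N), >= 0, vectorized
#' @param geometry a [plate_geometry()]
#' @return data.frame with `cop_x`, `cop_y` (cm)
#' @export
#' @examples
#' compute_cop(100, 100, 0, 0) # front-edge midpoint: (0, 13.25)
compute_cop <- function(TL, TR, BL, BR, geometry = plate_geometry()) {
  assert_nonneg(c(TL, TR, BL, BR), "corner forces")
  tot <- TL + TR + BL + BR
  if (any(tot <= 0)) stop("no load on the plate: total force must be positive")
  data.frame(
    cop_x = (geometry$width_cm / 2) * ((TR + BR) - (TL + BL)) / tot,
    cop_y = (geometry$depth_cm / 2) * ((TL + TR) - (BL + BR)) / tot
  )
}

#' Corner forces realizing a given center of pressure
#'
#' Bilinear load split: with u, v the normalized CoP coordinates in \[0, 1\]
#' across width and depth, the corner loads are weight * \{u or 1-u\} *
#' \{v or 1-v\}, which reproduces the CoP exactly and sums to `weight`.
#'
#' @param cop_x,cop_y CoP (cm), within the plate bounds, vectorized
#' @param weight total vertical load (N)
#' @param geometry a [plate_geometry()]
#' @return data.frame with `TL`, `TR`, `BL`, `BR` (N)
#' @export
forces_from_cop <- function(cop_x, cop_y, weight, geometry = plate_geometry()) {
  hw <- geometry$width_cm / 2; hd <- geometry$depth_cm / 2
  if (any(abs(cop_x) > hw + 1e-12) || any(abs(cop_y) > hd + 1e-12)) {
    stop("CoP outside the plate bounds")
  }
  stopifnot(all(weight > 0))
  u <- (cop_x + hw) / geometry$width_cm # 0 = left edge, 1 = right edge
  v <- (cop_y + hd) / geometry$depth_cm # 0 = back edge, 1 = front edge
  data.frame(TL = weight * (1 - u) * v, TR = weight * u * v,
             BL = weight * (1 - u) * (1 - v), BR = weight * u * (1 - v))
}

#' Simulate a jittered force-plate sample stream
#'
#' Sample times start at 0 and advance by inter-sample intervals drawn from
#' `jitter` with mean `1 / mean_rate` (a Gamma model with shape 25 by default,
#' echoing the board's nonparametric spread around its nominal 100 Hz).
#' Corner forces realize the trajectory's CoP via [forces_from_cop()];
#' optional Gaussian sensor noise (default sigma 0.05 cm, the board's
#' approximate CoP resolution) perturbs the CoP before the force split.
#'
#' @param trajectory function of time returning the CoP x-coordinate (cm), or
#'   a two-column matrix/data.frame-returning function for (x, y)
#' @param duration stream duration (s)
#' @param mean_rate nominal sample rate (Hz), default 100
#' @param jitter a [jitter_model()]; default Gamma(shape 25)
#' @param seed integer seed (required: streams are reproducible by contract)
#' @param weight subject load (N), default 700
#' @param cop_noise_sd_cm CoP sensor noise sigma (cm); 0 disables
#' @param geometry a [plate_geometry()]
#' @return data.frame: timestamp, TL, TR, BL, BR, cop_x, cop_y
#' @export
#' @examples
#' ref <- sway_reference(10, 0.1)
#' s <- simulate_stream(function(t) reference_at(ref, t), duration = 2, seed = 1)
#' nrow(s)
simulate_stream <- function(trajectory, duration, mean_rate = 100,
                            jitter = jitter_model("gamma", shape = 25),
                            seed, weight = 700, cop_noise_sd_cm = 0.05,
                            geometry = plate_geometry()) {
  stopifnot(mean_rate > 0, duration > 0)
  mean_iv <- 1 / mean_rate
  times <- with_seed(seed, {
    n_guess <- ceiling(duration * mean_rate * 1.25) + 50L
    iv <- draw_intervals(jitter, n_guess, mean_iv)
    tt <- cumsum(c(0, iv))
    while (tt[length(tt)] < duration) {
      iv2 <- draw_intervals(jitter, n_guess, mean_iv)
      tt <- c(tt, tt[length(tt)] + cumsum(iv2))
    }
    tt <- tt[tt < duration]
    noise <- if (cop_noise_sd_cm > 0) {
      stats::rnorm(2 * length(tt), 0, cop_noise_sd_cm)
    } else rep(0, 2 * length(tt))
    list(t = tt, noise = noise)
  })
  tt <- times$t
  n <- length(tt)
  xy <- trajectory(tt)
  if (is.null(dim(xy))) xy <- cbind(xy, 0)
  xy <- as.matrix(xy)
  hw <- geometry$width_cm / 2; hd <- geometry$depth_cm / 2
  x <- pmin(pmax(xy[, 1] + times$noise[seq_len(n)], -hw), hw)
  y <- pmin(pmax(xy[, 2] + times$noise[n + seq_len(n)], -hd), hd)
  f <- forces_from_cop(x, y, weight, geometry)
  cop <- compute_cop(f$TL, f$TR, f$BL, f$BR, geometry)
  data.frame(timestamp = tt, f, cop)
}
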