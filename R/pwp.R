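#' Idealized initial profiles for the 1-D mixed-layer model
#'
#' Two piecewise-linear salinity profiles over a uniform vertical grid,
#' both with constant temperature 2 degC and zero initial momentum:
#' \describe{
#'   \item{P17}{meltwater-stratified: salinity 30.5 at the surface rising
#'     linearly to 35 at 50 m, then to 35.1 at 200 m, constant below.}
#'   \item{P18}{weakly stratified: same as P17 except the surface-to-50 m
#'     gradient runs from 34.8 to 35.}
#' }
#'
#' @param profile_id `"P17"` or `"P18"`.
#' @param dz grid spacing, m (default 1).
#' @param depth_max domain depth, m (default 250).
#' @return list of class `"pwp_state"` with `z` (cell centres), `T`, `S`,
#'   `U`, `V`, `dz`.
#' @export
pwp_profile <- function(profile_id = c("P17", "P18"), dz = 1, depth_max = 250) {
  profile_id <- match.arg(profile_id)
  z <- seq(dz / 2, depth_max - dz / 2, by = dz)
  s_surf <- if (profile_id == "P17") 30.5 else 34.8
  S <- ifelse(z <= 50, s_surf + (35 - s_surf) * z / 50,
              ifelse(z <= 200, 35 + 0.1 * (z - 50) / 150, 35.1))
  structure(list(z = z, T = rep(2, length(z)), S = S,
                 U = rep(0, length(z)), V = rep(0, length(z)), dz = dz),
            class = "pwp_state")
}

#' @export
print.pwp_state <- function(x, ...) {
  cat(sprintf("<pwp_state> %d cells, dz = %g m, MLD = %g m\n",
              length(x$z), x$dz, pwp_mld(x)))
  invisible(x)
}

#' Model parameters for the PWP simulator
#'
#' Canonical Price-Weller-Pinkel settings: bulk and gradient critical
#' Richardson numbers 0.65 and 0.25, a two-band shortwave absorption
#' profile (62 percent with 0.6 m e-folding, the rest with 20 m), a
#' quadratic wind-stress drag law over 10-m wind, and Coriolis frequency
#' for 79 degrees north.
#'
#' @param rb_crit bulk critical Richardson number (default 0.65).
#' @param rg_crit gradient critical Richardson number (default 0.25).
#' @param latitude degrees north, sets the inertial rotation (default 79).
#' @param cd_wind 10-m drag coefficient (default 1.2e-3).
#' @param rho_air air density, kg m-3 (default 1.22).
#' @param rho0 reference seawater density, kg m-3 (default 1026).
#' @param cp seawater heat capacity, J kg-1 K-1 (default 4000).
#' @param sw_frac fraction of shortwave in the short absorption band
#'   (default 0.62).
#' @param sw_scale1,sw_scale2 absorption e-folding scales, m (0.6, 20).
#' @return list of parameters.
#' @export
pwp_params <- function(rb_crit = 0.65, rg_crit = 0.25, latitude = 79,
                       cd_wind = 1.2e-3, rho_air = 1.22, rho0 = 1026,
                       cp = 4000, sw_frac = 0.62, sw_scale1 = 0.6,
                       sw_scale2 = 20) {
  list(rb_crit = rb_crit, rg_crit = rg_crit,
       f = 2 * 7.2921e-5 * sin(latitude * pi / 180),
       cd_wind = cd_wind, rho_air = rho_air, rho0 = rho0, cp = cp,
       sw_frac = sw_frac, sw_scale1 = sw_scale1, sw_scale2 = sw_scale2,
       g = 9.81)
}

# potential density of the model column (surface-referenced)
pwp_sigma <- function(state) potential_density(state$S, state$T, 0)

# model MLD: deepest contiguous cell whose density is within `thresh` of the
# surface cell
pwp_mld <- function(state, thresh = 0.05) {
  sig <- pwp_sigma(state)
  over <- which(sig - sig[1] >= thresh)
  if (!length(over)) return(max(state$z) + state$dz / 2)
  if (over[1] == 1) return(0)
  state$z[over[1] - 1] + state$dz / 2
}

# mix cells 1..k to their means (T, S, U, V)
mix_down <- function(state, k) {
  idx <- seq_len(k)
  state$T[idx] <- mean(state$T[idx])
  state$S[idx] <- mean(state$S[idx])
  state$U[idx] <- mean(state$U[idx])
  state$V[idx] <- mean(state$V[idx])
  state
}

# convective adjustment: mix from the surface until statically stable
convective_adjust <- function(state) {
  n <- length(state$z)
  k <- 1L
  repeat {
    sig <- pwp_sigma(state)
    unstable <- which(diff(sig) < -1e-10)
    if (!length(unstable)) break
    k <- unstable[1] + 1L
    state <- mix_down(state, k)
    if (k >= n) break
  }
  state
}

# index of the deepest cell belonging to the (homogeneous) surface mixed layer
ml_index <- function(state, tol = 1e-8) {
  sig <- pwp_sigma(state)
  below <- which(sig - sig[1] > tol)
  if (!length(below)) length(state$z) else max(1L, below[1] - 1L)
}

#' One time step of the Price-Weller-Pinkel model
#'
#' Sequential sub-steps: (1) deposit non-penetrating heat and the
#' freshwater (evaporation minus precipitation) flux in the surface cell
#' and distribute shortwave over the column with the two-band exponential
#' absorption profile; (2) convective adjustment (mix downward until
#' statically stable); (3) accelerate the mixed layer by the wind stress
#' (quadratic drag on the 10-m wind) and rotate the momentum by the
#' inertial increment f dt; (4) deepen the mixed layer while the bulk
#' Richardson number is below its critical value; (5) relieve gradient
#' Richardson numbers below critical by partial mixing of adjacent cells.
#'
#' @param state a [pwp_profile()] state.
#' @param forcing list/row with `u10`, `v10` (m/s), `q_nonpen` (W m-2,
#'   positive warms), `q_sw` (W m-2, >= 0), `emp` (m/s, evaporation minus
#'   precipitation).
#' @param dt time step, s (default 900).
#' @param params see [pwp_params()].
#' @return the advanced `pwp_state`.
#' @export
pwp_step <- function(state, forcing, dt = 900, params = pwp_params()) {
  fr <- forcing
  vals <- c(fr$u10, fr$v10, fr$q_nonpen, fr$q_sw, fr$emp)
  if (any(!is.finite(vals))) stop("non-finite forcing")
  n <- length(state$z)
  dz <- state$dz
  p <- params

  # -- 1. surface fluxes
  heat_per_cell <- dt / (p$rho0 * p$cp * dz)
  state$T[1] <- state$T[1] + fr$q_nonpen * heat_per_cell
  if (fr$q_sw != 0) {
    zf <- seq(0, n) * dz  # cell faces
    pen <- p$sw_frac * exp(-zf / p$sw_scale1) +
      (1 - p$sw_frac) * exp(-zf / p$sw_scale2)
    absorbed <- fr$q_sw * (pen[-(n + 1)] - pen[-1])
    state$T <- state$T + absorbed * heat_per_cell
  }
  # virtual salt flux for E-P
  state$S[1] <- state$S[1] + state$S[1] * fr$emp * dt / dz

  # -- 2. convective adjustment
  state <- convective_adjust(state)

  # -- 3. wind stress on the mixed layer + inertial rotation
  wind <- sqrt(fr$u10^2 + fr$v10^2)
  taux <- p$rho_air * p$cd_wind * wind * fr$u10
  tauy <- p$rho_air * p$cd_wind * wind * fr$v10
  k <- ml_index(state)
  h <- k * dz
  idx <- seq_len(k)
  state$U[idx] <- state$U[idx] + taux * dt / (p$rho0 * h)
  state$V[idx] <- state$V[idx] + tauy * dt / (p$rho0 * h)
  # rotate (U + iV) by exp(-i f dt): U' = U cos + V sin, V' = -U sin + V cos
  u_new <- state$U * cos(p$f * dt) + state$V * sin(p$f * dt)
  v_new <- -state$U * sin(p$f * dt) + state$V * cos(p$f * dt)
  state$U <- u_new
  state$V <- v_new

  # -- 4. bulk Richardson deepening
  repeat {
    k <- ml_index(state)
    if (k >= n) break
    sig <- pwp_sigma(state)
    h <- k * dz
    drho <- sig[k + 1] - sig[k]
    du2 <- (state$U[k] - state$U[k + 1])^2 + (state$V[k] - state$V[k + 1])^2
    if (du2 < 1e-12) break
    rb <- p$g * max(drho, 0) * h / (p$rho0 * du2)
    if (rb >= p$rb_crit) break
    state <- mix_down(state, k + 1L)
  }

  # -- 5. gradient Richardson adjustment (partial mixing of the worst pair)
  for (iter in seq_len(4 * n)) {
    sig <- pwp_sigma(state)
    drho <- diff(sig)
    du2 <- diff(state$U)^2 + diff(state$V)^2
    rg <- ifelse(du2 < 1e-12, Inf, p$g * pmax(drho, 0) * dz / (p$rho0 * du2))
    jm <- which.min(rg)
    if (rg[jm] >= p$rg_crit) break
    s <- 1 - rg[jm] / 0.3  # stir towards Rg ~ 0.3
    for (fld in c("T", "S", "U", "V")) {
      a <- state[[fld]][jm]; b <- state[[fld]][jm + 1]
      state[[fld]][jm] <- a + 0.5 * s * (b - a)
      state[[fld]][jm + 1] <- b - 0.5 * s * (b - a)
    }
    state <- convective_adjust(state)
  }

  state
}

#' Run the PWP model over a forcing series
#'
#' Advances [pwp_step()] with forcing linearly interpolated to the model
#' time step and collects diagnostics: model mixed-layer depth (density
#' threshold criterion against the surface cell), column heat and salt
#' content, and the time-integrated surface inputs for conservation
#' checking.
#'
#' @param state initial [pwp_profile()] state.
#' @param forcing data.frame with `time` (POSIXct or days) and columns
#'   `u10`, `v10`, `q_nonpen`, `q_sw`, `emp`.
#' @param days length of the run (default: forcing span).
#' @param dt time step, s (default 900).
#' @param out_every_hours diagnostic output interval (default 6).
#' @param params see [pwp_params()].
#' @return list with `time_days`, `mld` (m), `heat` (J m-2), `salt`
#'   (psu m), `heat_in`, `salt_in` (integrated surface inputs) and
#'   `final` state.
#' @export
pwp_run <- function(state, forcing, days = NULL, dt = 900,
                    out_every_hours = 6, params = pwp_params()) {
  p <- params
  tf <- if (inherits(forcing$time, "POSIXct")) {
    num_days(forcing$time)
  } else {
    as.numeric(forcing$time) - as.numeric(forcing$time)[1]
  }
  days <- days %||% max(tf)
  nstep <- ceiling(days * 86400 / dt)
  interp <- function(col) {
    stats::approx(tf, forcing[[col]], xout = (seq_len(nstep) - 0.5) * dt / 86400,
                  rule = 2)$y
  }
  u10 <- interp("u10"); v10 <- interp("v10")
  qnp <- interp("q_nonpen"); qsw <- interp("q_sw"); emp <- interp("emp")

  n <- length(state$z); dz <- state$dz
  zf_bot <- n * dz
  sw_through <- p$sw_frac * exp(-zf_bot / p$sw_scale1) +
    (1 - p$sw_frac) * exp(-zf_bot / p$sw_scale2)

  every <- max(1L, round(out_every_hours * 3600 / dt))
  nout <- floor(nstep / every)
  out_t <- numeric(nout); out_mld <- numeric(nout)
  out_heat <- numeric(nout); out_salt <- numeric(nout)
  out_heat_in <- numeric(nout); out_salt_in <- numeric(nout)
  heat_in <- 0; salt_in <- 0
  io <- 0L
  for (i in seq_len(nstep)) {
    fr <- list(u10 = u10[i], v10 = v10[i], q_nonpen = qnp[i],
               q_sw = qsw[i], emp = emp[i])
    s_surf_before <- state$S[1]
    state <- pwp_step(state, fr, dt = dt, params = p)
    heat_in <- heat_in + (qnp[i] + qsw[i] * (1 - sw_through)) * dt
    salt_in <- salt_in + s_surf_before * emp[i] * dt
    if (i %% every == 0L) {
      io <- io + 1L
      out_t[io] <- i * dt / 86400
      out_mld[io] <- pwp_mld(state)
      out_heat[io] <- sum(p$rho0 * p$cp * state$T * dz)
      out_salt[io] <- sum(state$S * dz)
      out_heat_in[io] <- heat_in
      out_salt_in[io] <- salt_in
    }
  }
  list(time_days = out_t[seq_len(io)], mld = out_mld[seq_len(io)],
       heat = out_heat[seq_len(io)], salt = out_salt[seq_len(io)],
       heat_in = out_heat_in[seq_len(io)], salt_in = out_salt_in[seq_len(io)],
       final = state)
}
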