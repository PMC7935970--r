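# Seeded synthetic-data generators. Every instrument input the analysis
# pipeline consumes (HPLC peak-area time courses, CD kinetic traces and
# melts, SLB confocal z-stack series) can be produced from the forward
# models with explicit noise, so parameter-recovery round trips are testable
# without laboratory data. Ground truth travels with each output as the
# `ground_truth` attribute.

apply_noise <- function(y, noise) {
  if (is.null(noise) || identical(noise$type, "none")) return(y)
  if (noise$type == "gaussian") {
    rng <- diff(range(y))
    y + stats::rnorm(length(y), 0, (noise$sd_frac %||% 0.02) * max(rng, 1e-12))
  } else if (noise$type == "multiplicative") {
    pmax(y * (1 + stats::rnorm(length(y), 0, noise$cv %||% 0.05)), 0)
  } else {
    stop(sprintf("unknown noise type '%s'", noise$type))
  }
}

with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Generate an HPLC substrate/product peak-area time course
#'
#' Runs the solution kinetics, maps to baseline-integrated peak areas
#' (substrate = B + AB because the complex dissociates under the acidic
#' reversed-phase conditions; product = Bp) and applies multiplicative area
#' noise (default 5% CV). At zero noise the substrate + product sum is
#' conserved.
#'
#' @param params A [kinetic_params()].
#' @param init Named state (see [simulate_solution()]).
#' @param times Sampling times, min.
#' @param noise `list(type = "multiplicative", cv = )`, `list(type =
#'   "gaussian", sd_frac = )`, or `NULL` for none.
#' @param seed Integer seed (fixed seed => identical output).
#' @param scale Area units per uM.
#' @return `time_course` with `substrate_area`, `product_area` and a
#'   `ground_truth` attribute.
#' @export
gen_hplc <- function(params, init = c(B = 50), times = seq(0, 30, by = 0.5),
                     noise = list(type = "multiplicative", cv = 0.05),
                     seed = NULL, scale = 1) {
  tc <- simulate_solution(params, init, times)
  obs <- observables(tc, list(mode = "hplc", scale = scale))
  out <- with_seed_maybe(seed, {
    obs$substrate_area <- apply_noise(obs$substrate_area, noise)
    obs$product_area <- apply_noise(obs$product_area, noise)
    obs
  })
  attr(out, "ground_truth") <- list(params = params, init = init,
                                    nominal_k = attr(params, "nominal_k"),
                                    seed = seed)
  out
}

#' Generate a CD phosphorylation kinetic trace (MRE222 vs time)
#'
#' Helicity tracks the dimer concentration; with `kdp = 0` the zero-noise
#' trace rises monotonically towards the unfolded value as phosphorylation
#' depletes the dimer.
#'
#' @inheritParams gen_hplc
#' @param noise Default additive Gaussian at 2% of the trace range.
#' @return `time_course` with `mre222` and a `ground_truth` attribute.
#' @export
gen_cd_kinetic <- function(params, init = c(A = 50, B = 50),
                           times = seq(0, 480, by = 2),
                           noise = list(type = "gaussian", sd_frac = 0.02),
                           seed = NULL) {
  A0 <- if ("A" %in% names(init)) init[["A"]] else 0
  B0 <- if ("B" %in% names(init)) init[["B"]] else 0
  d0 <- dimer_equilibrium(A0, B0, params$koff / max(params$kon, 1e-12))
  y0 <- c(A = A0 - d0, B = B0 - d0, AB = d0, Bp = 0)
  tc <- simulate_solution(params, y0, times)
  obs <- observables(tc, list(mode = "cd", ab_ref = d0))
  out <- with_seed_maybe(seed, {
    obs$mre222 <- apply_noise(obs$mre222, noise)
    obs
  })
  attr(out, "ground_truth") <- list(params = params, init = init,
                                    nominal_k = attr(params, "nominal_k"),
                                    seed = seed)
  out
}

#' Generate a CD melt curve
#'
#' [melt_curve()] plus additive Gaussian noise, on a 1 degC grid over
#' 5-90 degC by default.
#'
#' @param params A [melt_params()].
#' @param temperatures Ascending grid, deg C.
#' @param noise As in [gen_cd_kinetic()].
#' @param seed Integer seed.
#' @return `melt_curve` data frame carrying `total_conc_uM` and
#'   `ground_truth` attributes.
#' @export
gen_cd_melt <- function(params, temperatures = seq(5, 90, by = 1),
                        noise = list(type = "gaussian", sd_frac = 0.02),
                        seed = NULL) {
  mc <- melt_curve(params, temperatures)
  out <- with_seed_maybe(seed, {
    mc$mre222 <- apply_noise(mc$mre222, noise)
    mc
  })
  attr(out, "total_conc_uM") <- params$total_conc_uM
  attr(out, "ground_truth") <- list(params = params, seed = seed)
  out
}

default_slb_channels <- function(mode, release_k) {
  if (mode == "tether") {
    list(
      cargo = list(d0 = 200, d_inf = 40, k = release_k, bulk0 = 10, bulk_inf = 30),
      anchor = list(d0 = 150, d_inf = 150, k = 0, bulk0 = 5, bulk_inf = 5),
      lipid = list(d0 = 250, d_inf = 250, k = 0, bulk0 = 0, bulk_inf = 0)
    )
  } else {
    list(
      switchA = list(d0 = 200, d_inf = 40, k = release_k, bulk0 = 15, bulk_inf = 35),
      switchB = list(d0 = 180, d_inf = 35, k = release_k, bulk0 = 15, bulk_inf = 35),
      lipid = list(d0 = 250, d_inf = 250, k = 0, bulk0 = 0, bulk_inf = 0)
    )
  }
}

#' Generate a supported-lipid-bilayer confocal z-stack series
#'
#' Per channel and time point the z-profile is a Gaussian membrane peak on a
#' uniform bulk background,
#' `I(z, t) = density(t) * exp(-(z - z_mem)^2 / (2 sigma_z^2)) + bulk(t)`,
#' expanded to (y, x) pixels with Poisson-like noise (Gaussian, sd =
#' `noise_gain * sqrt(I)`). Membrane peaks are coincident across channels;
#' the lipid channel is constant. Default channel dynamics follow a
#' single-exponential release at `release_k` after a kinase addition at
#' t = 0 (tether mode: decaying cargo over constant anchor and lipid;
#' avidity mode: both switch channels decay). Supplying `density_tc`
#' (columns `time`, one per channel, optional `bulk_<channel>`) instead
#' drives the stack from arbitrary simulated dynamics, e.g. a
#' [simulate_tether()] output.
#'
#' @param mode `"tether"` or `"avidity"`.
#' @param release_k Release rate constant (min^-1) of the default dynamics.
#' @param times Sampling times, min.
#' @param n_z,dz_um,z_mem_um,sigma_z_um z geometry: slice count, spacing,
#'   membrane position, axial peak width.
#' @param n_px Lateral pixels per side.
#' @param noise_gain Poisson-approximation gain; 0 disables pixel noise.
#' @param density_tc Optional data frame of channel dynamics (see Details).
#' @param seed Integer seed.
#' @return A [zstack_series()] with a `ground_truth` attribute (release
#'   rate and per-channel density/bulk tables).
#' @export
gen_slb_series <- function(mode = c("tether", "avidity"), release_k = 0.07,
                           times = seq(0, 70, by = 2),
                           n_z = 41, dz_um = 0.25, z_mem_um = 4,
                           sigma_z_um = 0.5, n_px = 16, noise_gain = 1,
                           density_tc = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (sigma_z_um < dz_um) {
    warning("sigma_z_um < dz_um: membrane peak under-resolved in z")
  }
  if (is.null(density_tc)) {
    chans <- default_slb_channels(mode, release_k)
    density_tc <- data.frame(time = times)
    for (nm in names(chans)) {
      ch <- chans[[nm]]
      density_tc[[nm]] <- ch$d_inf + (ch$d0 - ch$d_inf) * exp(-ch$k * times)
      density_tc[[paste0("bulk_", nm)]] <- ch$bulk_inf +
        (ch$bulk0 - ch$bulk_inf) * exp(-ch$k * times)
    }
  } else {
    stopifnot("time" %in% names(density_tc))
    if (!isTRUE(all.equal(density_tc$time, times))) {
      stop("density_tc$time must match times")
    }
  }
  channels <- setdiff(names(density_tc),
                      c("time", grep("^bulk_", names(density_tc), value = TRUE)))
  z <- (seq_len(n_z) - 1) * dz_um
  shape <- exp(-(z - z_mem_um)^2 / (2 * sigma_z_um^2))
  nt <- length(times)
  arr <- array(0, dim = c(nt, length(channels), n_z, n_px, n_px))
  arr <- with_seed_maybe(seed, {
    for (it in seq_len(nt)) for (ic in seq_along(channels)) {
      nm <- channels[ic]
      bulk_col <- paste0("bulk_", nm)
      bulk <- if (bulk_col %in% names(density_tc)) density_tc[[bulk_col]][it] else 0
      prof <- density_tc[[nm]][it] * shape + bulk
      for (iz in seq_len(n_z)) {
        px <- prof[iz]
        if (noise_gain > 0) {
          px <- px + stats::rnorm(n_px * n_px, 0, noise_gain * sqrt(max(prof[iz], 0)))
        }
        arr[it, ic, iz, , ] <- pmax(px, 0)
      }
    }
    arr
  })
  out <- zstack_series(arr, dz_um = dz_um, times = times, channels = channels)
  attr(out, "ground_truth") <- list(mode = mode, release_k = release_k,
                                    density = density_tc, z_mem_um = z_mem_um,
                                    sigma_z_um = sigma_z_um, seed = seed)
  out
}
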