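#' Sample an equilibrium Zc profile at equal Eh7 intervals
#'
#' Reads the step function produced by [zc_vs_eh_profile()] at `n_points`
#' equally spaced Eh values spanning the profile domain (endpoints
#' included).
#'
#' @param profile data.frame from [zc_vs_eh_profile()].
#' @param n_points Number of sample points (>= 3).
#' @return data.frame with `eh7_V` (Eh in volts; at pH 7 the profile's Eh
#'   axis is Eh7) and `zc_eq`.
#' @export
sample_equilibrium_profile <- function(profile, n_points) {
  if (is.null(profile) || nrow(profile) == 0) stop("empty profile")
  if (n_points < 3) stop("need at least 3 sample points")
  eh <- seq(min(profile$Eh_from_mV), max(profile$Eh_to_mV),
            length.out = n_points)
  zc <- step_lookup(profile, eh)
  data.frame(eh7_V = eh / 1000, zc_eq = zc)
}

# Step-function lookup: value of the segment containing each Eh (internal).
step_lookup <- function(profile, eh_mV) {
  idx <- findInterval(eh_mV, profile$Eh_from_mV)
  idx[idx < 1] <- 1L
  profile$zc[idx]
}

#' Draw a random taxon assignment with near-zero Zc-Eh7 slope
#'
#' Repeatedly assigns a random sample (without replacement) of pool Zc
#' values to the Eh7 points until the OLS slope magnitude falls below
#' `tolerance`, emulating random biological variation with no redox trend.
#' Deterministic under `seed`.
#'
#' @param taxa_zc Pool of taxon Zc values (length >= number of points).
#' @param eh7_V Eh7 points (volts).
#' @param tolerance Slope acceptance bound in 1/V (default 0.005, an order
#'   of magnitude below the smallest global slope of interest).
#' @param seed Integer seed.
#' @param max_draws Give up after this many draws.
#' @return List with `zc_rand` (accepted assignment), `slope`, `draws`.
#' @export
select_near_zero_pool <- function(taxa_zc, eh7_V, tolerance = 0.005,
                                  seed = 1L, max_draws = 10000L) {
  n <- length(eh7_V)
  if (length(taxa_zc) < n) stop("pool smaller than the number of points")
  set.seed(seed)
  for (d in seq_len(max_draws)) {
    zc <- sample(taxa_zc, n)
    if (stats::sd(zc) == 0) {
      return(list(zc_rand = zc, slope = 0, draws = d))
    }
    m <- ols_fit(eh7_V, zc)$m
    if (abs(m) < tolerance)
      return(list(zc_rand = zc, slope = m, draws = d))
  }
  stop("no assignment with |slope| < ", tolerance, " in ", max_draws,
       " draws; increase the tolerance")
}

#' Mix equilibrium and random Zc series and fit the result
#'
#' The mixture zc_mix = w_eq * zc_eq + (1 - w_eq) * zc_rand models
#' incomplete metastable equilibrium: a community whose composition is
#' partly set by energy minimization and partly by random biological
#' variation. By OLS linearity the mixture slope equals
#' w_eq * slope(zc_eq) + (1 - w_eq) * slope(zc_rand) exactly.
#'
#' @param eh7_V Eh7 points (volts).
#' @param zc_eq Equilibrium Zc series.
#' @param zc_rand Random-taxon Zc series.
#' @param w_eq Equilibrium weight in [0, 1] (default 0.20).
#' @return List with `zc_mix`, `fit` (the mixture [ols_fit()]), `fit_eq`,
#'   `fit_rand`, `w_eq`.
#' @export
mix_and_fit <- function(eh7_V, zc_eq, zc_rand, w_eq = 0.20) {
  stopifnot(length(eh7_V) == length(zc_eq),
            length(zc_eq) == length(zc_rand))
  if (w_eq < 0 || w_eq > 1) stop("w_eq must lie in [0, 1]")
  zc_mix <- w_eq * zc_eq + (1 - w_eq) * zc_rand
  fit_rand <- if (stats::sd(zc_rand) == 0) NULL else ols_fit(eh7_V, zc_rand)
  list(zc_mix = zc_mix,
       fit = ols_fit(eh7_V, zc_mix),
       fit_eq = ols_fit(eh7_V, zc_eq),
       fit_rand = fit_rand,
       w_eq = w_eq)
}

#' Run the incomplete-equilibrium simulation end to end
#'
#' Samples an equilibrium profile at equal Eh7 intervals, rescales it to a
#' requested equilibrium slope if asked, selects a near-zero-slope random
#' taxon assignment from a Zc pool, mixes the two series, and reports all
#' three fits.
#'
#' @param profile Step profile from [zc_vs_eh_profile()] (taken at pH 7 so
#'   the Eh axis is Eh7).
#' @param taxa_zc Pool of taxon Zc values for the random component.
#' @param n_points Number of Eh7 points.
#' @param w_eq Equilibrium weight (default 0.20).
#' @param tolerance Near-zero slope bound for the random pool.
#' @param seed Integer seed.
#' @param target_eq_slope Optional: rescale the equilibrium series about
#'   its mean so its OLS slope equals this value (1/V) exactly.
#' @return data.frame of the three series plus attributes `fit`, `fit_eq`,
#'   `fit_rand`, `w_eq`, `draws`.
#' @export
run_equilibrium_sim <- function(profile, taxa_zc, n_points = 25,
                                w_eq = 0.20, tolerance = 0.005, seed = 1L,
                                target_eq_slope = NULL) {
  eq <- sample_equilibrium_profile(profile, n_points)
  zc_eq <- eq$zc_eq
  if (!is.null(target_eq_slope)) {
    m0 <- ols_fit(eq$eh7_V, zc_eq)$m
    if (m0 == 0) stop("cannot rescale a flat equilibrium profile")
    zc_eq <- mean(zc_eq) + (zc_eq - mean(zc_eq)) * (target_eq_slope / m0)
  }
  sel <- select_near_zero_pool(taxa_zc, eq$eh7_V, tolerance, seed)
  mix <- mix_and_fit(eq$eh7_V, zc_eq, sel$zc_rand, w_eq)
  out <- data.frame(eh7_V = eq$eh7_V, zc_eq = zc_eq,
                    zc_rand = sel$zc_rand, zc_mix = mix$zc_mix)
  attr(out, "fit") <- mix$fit
  attr(out, "fit_eq") <- mix$fit_eq
  attr(out, "fit_rand") <- mix$fit_rand
  attr(out, "w_eq") <- w_eq
  attr(out, "draws") <- sel$draws
  out
}
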