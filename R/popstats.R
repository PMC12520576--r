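#' Density-normalised radius histogram
#'
#' @param radii_um droplet/capsule radii in um (or a tibble with an `r_um`
#'   column)
#' @param bin_width_um histogram bin width in um (default 5)
#' @return tibble: `mid_um`, `density` (1/um; integrates to 1), `count`
#' @export
radius_pdf <- function(radii_um, bin_width_um = 5) {
  r <- radii_vector(radii_um)
  if (length(r) == 0) abort("empty sample", class = "capsulejet_domain_error")
  breaks <- seq(floor(min(r) / bin_width_um) * bin_width_um,
                ceiling(max(r) / bin_width_um) * bin_width_um + bin_width_um,
                by = bin_width_um)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  out <- tibble(mid_um = h$mids, density = h$density, count = h$counts)
  class(out) <- c("radius_pdf", class(out))
  out
}

radii_vector <- function(x) {
  r <- if (is.data.frame(x)) x$r_um else as.numeric(x)
  if (any(r <= 0)) abort("radii must be > 0", class = "capsulejet_domain_error")
  r
}

#' Gaussian-mixture fit of a radius sample
#'
#' Maximum-likelihood fit of a 1-3 component Gaussian mixture with
#' unequal variances (EM with deterministic model-based initialisation, via
#' mclust). `components = "auto"` selects the component count in 1:3 by the
#' Bayesian information criterion. Components are reported sorted by mean.
#'
#' @param radii_um radii in um (vector or tibble with `r_um`)
#' @param components integer in 1:3, or "auto"
#' @return an object of class `mixture_fit`; see [tidy.mixture_fit()] and
#'   [glance.mixture_fit()]
#' @examples
#' set.seed(1)
#' r <- c(rnorm(800, 196, 9), rnorm(800, 241, 20))
#' fit_mixture(r, 2)
#' @export
fit_mixture <- function(radii_um, components = "auto") {
  r <- radii_vector(radii_um)
  g <- if (identical(components, "auto")) 1:3 else as.integer(components)
  if (length(r) < 10 * max(g))
    abort(sprintf("need at least %d observations for %d component(s)",
                  10 * max(g), max(g)),
          class = "capsulejet_domain_error")
  if (sd(r) == 0)
    abort("degenerate sample with zero variance", class = "capsulejet_singular_fit")
  # Mclust evaluates helper calls in the caller's frame, so mclustBIC must be
  # visible here (hence the importFrom rather than :: access).
  fit <- Mclust(r, G = g, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    abort("mixture fit failed", class = "capsulejet_singular_fit")
  ord <- order(fit$parameters$mean)
  structure(
    list(
      n_components = as.integer(fit$G),
      means = unname(fit$parameters$mean[ord]),
      sds = unname(sqrt(fit$parameters$variance$sigmasq))[
        if (length(fit$parameters$variance$sigmasq) == 1) rep(1, fit$G) else ord],
      weights = unname(fit$parameters$pro[ord]),
      loglik = fit$loglik,
      bic = fit$bic,
      n = length(r),
      data = r
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: %d component(s), n = %d, BIC = %.1f>\n",
              x$n_components, x$n, x$bic))
  for (i in seq_len(x$n_components))
    cat(sprintf("  %d: mean %.1f um, sd %.1f um, weight %.2f\n",
                i, x$means[i], x$sds[i], x$weights[i]))
  invisible(x)
}

#' Tidiers for mixture fits
#'
#' @param x a [fit_mixture()] result
#' @param ... unused
#' @return `tidy()`: one row per component (`component`, `mean_um`, `sd_um`,
#'   `weight`); `glance()`: one row with `n_components`, `loglik`, `bic`, `n`
#' @exportS3Method generics::tidy
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = seq_len(x$n_components),
         mean_um = x$means, sd_um = x$sds, weight = x$weights)
}

#' @rdname tidy.mixture_fit
#' @exportS3Method generics::glance
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(n_components = x$n_components, loglik = x$loglik, bic = x$bic, n = x$n)
}

#' Selectivity of a droplet population
#'
#' The fraction of droplets whose radius lies within `tolerance` (default
#' +/-10%, inclusive at both ends) of the targeted radius R_th:
#' S = #\{r : |r - R_th| <= tolerance R_th\} / N.
#'
#' @param radii_um radii in um (vector or tibble with `r_um`)
#' @param r_th_um targeted radius in um (> 0), from [targeted_radius()]
#' @param tolerance band half-width as a fraction of R_th (default 0.10)
#' @return one-row tibble: `s`, `n_in`, `n_total`, `r_th_um`, `band_lo_um`,
#'   `band_hi_um`
#' @export
selectivity <- function(radii_um, r_th_um, tolerance = 0.10) {
  r <- radii_vector(radii_um)
  if (length(r) == 0) abort("empty sample", class = "capsulejet_domain_error")
  if (r_th_um <= 0) abort("`r_th_um` must be > 0", class = "capsulejet_domain_error")
  lo <- r_th_um * (1 - tolerance); hi <- r_th_um * (1 + tolerance)
  n_in <- sum(r >= lo & r <= hi)
  tibble(s = n_in / length(r), n_in = n_in, n_total = length(r),
         r_th_um = r_th_um, band_lo_um = lo, band_hi_um = hi)
}

#' Label droplets as satellite / primary / doublet / triplet
#'
#' Radii below `satellite_cutoff` (default 0.7) times the primary radius R0
#' are satellites; the rest are assigned to the nearest of
#' \{R0, 2^(1/3) R0, 3^(1/3) R0\} (volume-conserving coalescence radii) with
#' midpoint boundaries. Every radius receives exactly one label.
#'
#' @param radii_um radii in um
#' @param r0_um primary droplet radius in um (> 0)
#' @param satellite_cutoff satellite threshold as a fraction of `r0_um`
#' @return tibble: `r_um`, `label` (factor with levels satellite, primary,
#'   doublet, triplet)
#' @export
label_modes <- function(radii_um, r0_um, satellite_cutoff = 0.7) {
  r <- radii_vector(radii_um)
  if (r0_um <= 0) abort("`r0_um` must be > 0", class = "capsulejet_domain_error")
  anchors <- r0_um * c(1, 2^(1 / 3), 3^(1 / 3))
  nearest <- apply(abs(outer(r, anchors, `-`)), 1, which.min)
  lab <- c("primary", "doublet", "triplet")[nearest]
  lab[r < satellite_cutoff * r0_um] <- "satellite"
  tibble(r_um = r,
         label = factor(lab, levels = c("satellite", "primary", "doublet",
                                        "triplet")))
}

#' Assemble a frequency/potential sweep table
#'
#' Combines per-(f, U) analysis results into a tidy table: spatial growth
#' rate from the fragmentation length, selectivity at each run's targeted
#' radius, and the modal radius from a mixture fit. Also reports the best
#' (f, U) pair (maximum selectivity).
#'
#' @param runs a list; each element needs `f_hz`, `u_v`, `l_frag_m` and
#'   `radii_um` (droplet radii), plus optionally `r_th_um` (defaults to the
#'   targeted radius of a [jet_run()] forced at `f_hz`)
#' @param run a [jet_run()] template used to compute targeted radii
#' @param gain spatial-growth log-amplification (default 7)
#' @param tolerance selectivity band (default 0.10)
#' @return a tibble of class `sweep_table`: `f_hz`, `u_v`, `l_frag_um`,
#'   `growth_per_m`, `s`, `modal_radius_um`, `r_th_um`, `n_drops`; the best
#'   row index is attached as attribute `best`
#' @export
assemble_sweep <- function(runs, run = jet_run(), gain = 7, tolerance = 0.10) {
  if (length(runs) == 0)
    return(structure(tibble(f_hz = numeric(0), u_v = numeric(0),
                            l_frag_um = numeric(0), growth_per_m = numeric(0),
                            s = numeric(0), modal_radius_um = numeric(0),
                            r_th_um = numeric(0), n_drops = integer(0)),
                     class = c("sweep_table", class(tibble()))))
  rows <- purrr::map(runs, function(x) {
    for (field in c("f_hz", "u_v", "l_frag_m", "radii_um"))
      if (is.null(x[[field]]))
        abort(sprintf("sweep run missing field `%s`", field),
              class = "capsulejet_schema_error")
    r_th <- x$r_th_um %||% targeted_radius(x$f_hz, run)
    sel <- selectivity(x$radii_um, r_th, tolerance)
    modal <- if (length(x$radii_um) >= 30) {
      fit <- fit_mixture(x$radii_um, "auto")
      fit$means[which.max(fit$weights)]
    } else median(x$radii_um)
    tibble(f_hz = x$f_hz, u_v = x$u_v,
           l_frag_um = m_to_um(x$l_frag_m),
           growth_per_m = spatial_growth_rate(x$l_frag_m, gain),
           s = sel$s, modal_radius_um = modal, r_th_um = r_th,
           n_drops = length(x$radii_um))
  })
  out <- bind_rows(rows)
  attr(out, "best") <- which.max(out$s)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Gelation shrinkage between drops in air and capsules in the bath
#'
#' 1 - mean(capsule radii) / mean(drop radii), with a seeded bootstrap
#' confidence interval.
#'
#' @param drop_radii_um droplet radii in air (um)
#' @param capsule_radii_um capsule radii after gelation (um)
#' @param n_boot bootstrap resamples (default 1000)
#' @param conf confidence level (default 0.95)
#' @param seed integer seed
#' @return one-row tibble: `shrinkage`, `ci_lo`, `ci_hi`, `n_drops`,
#'   `n_capsules`
#' @export
shrinkage_ratio <- function(drop_radii_um, capsule_radii_um, n_boot = 1000,
                            conf = 0.95, seed = 1) {
  d <- radii_vector(drop_radii_um); k <- radii_vector(capsule_radii_um)
  if (length(d) == 0 || length(k) == 0)
    abort("both samples must be nonempty", class = "capsulejet_domain_error")
  est <- 1 - mean(k) / mean(d)
  set.seed(sub_seed(seed, "bootstrap"))
  boot <- replicate(n_boot, {
    1 - mean(sample(k, replace = TRUE)) / mean(sample(d, replace = TRUE))
  })
  a <- (1 - conf) / 2
  tibble(shrinkage = est,
         ci_lo = unname(quantile(boot, a)), ci_hi = unname(quantile(boot, 1 - a)),
         n_drops = length(d), n_capsules = length(k))
}
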