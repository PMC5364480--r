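#' Conformer ensemble
#'
#' A set of conformer potential energies (kcal/mol) at a temperature, used as
#' a conformational-flexibility descriptor: Boltzmann probabilities, the
#' conformational entropy `S = -R * sum(P_i * log(P_i))`, and the count of
#' low-energy local minima.
#'
#' @param energies Numeric vector of potential energies in kcal/mol
#'   (non-empty, finite).
#' @param temperature Temperature in Kelvin (> 0). Default 298.15 K.
#' @param label Optional ensemble label.
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(energies, temperature = 298.15,
                               label = "ensemble") {
  stop_if_not(length(energies) >= 1, "ensemble must contain >= 1 conformer")
  stop_if_not(all(is.finite(energies)), "energies must be finite")
  stop_if_not(temperature > 0, "temperature must be > 0 K")
  structure(list(energies = as.double(energies),
                 temperature = as.double(temperature),
                 label = as.character(label)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> '%s': %d conformers at %g K, E in [%.3f, %.3f] kcal/mol\n",
              x$label, length(x$energies), x$temperature,
              min(x$energies), max(x$energies)))
  invisible(x)
}

# RT in kcal/mol at temperature T
rt_kcal <- function(temperature) GAS_CONSTANT_CAL * 1e-3 * temperature

#' Boltzmann probabilities of a conformer ensemble
#'
#' `P_i` is proportional to `exp(-(E_i - E_min) / RT)`; the minimum-energy
#' shift makes the computation numerically stable and leaves the result
#' invariant to adding any constant to all energies.
#'
#' @param ensemble A [conformer_ensemble()].
#' @return Numeric vector of probabilities summing to 1.
#' @export
boltzmann_probabilities <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  e <- ensemble$energies
  w <- exp(-(e - min(e)) / rt_kcal(ensemble$temperature))
  w / sum(w)
}

#' Conformational entropy from conformer probabilities
#'
#' `S = -R * sum(P_i * log(P_i))` with `R = 1.98720 cal mol^-1 K^-1`; terms
#' with `P_i = 0` contribute nothing. Entropies are molar
#' (cal K^-1 mol^-1). The maximum for `N` conformers is `R * log(N)`,
#' attained by the uniform distribution.
#'
#' @param probabilities Numeric probabilities summing to 1 (tolerance 1e-6).
#' @return Entropy in cal K^-1 mol^-1.
#' @export
conformational_entropy <- function(probabilities) {
  stop_if_not(all(probabilities >= 0), "probabilities must be non-negative")
  stop_if_not(abs(sum(probabilities) - 1) < 1e-6,
              "probabilities must sum to 1 (got %.8f)", sum(probabilities))
  p <- probabilities[probabilities > 0]
  -GAS_CONSTANT_CAL * sum(p * log(p))
}

#' Count low-energy local minima in an ensemble
#'
#' Number of conformers within `window` kcal/mol of the global minimum, the
#' conformational-space size descriptor.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param window Energy window above the global minimum (kcal/mol, >= 0;
#'   `Inf` counts all conformers). Default 5.
#' @return Integer count.
#' @export
count_low_energy_minima <- function(ensemble, window = 5) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  stop_if_not(window >= 0, "window must be >= 0")
  e <- ensemble$energies
  sum(e - min(e) <= window)
}

#' Full flexibility report for one ensemble
#'
#' @param ensemble A [conformer_ensemble()].
#' @param window Minima window in kcal/mol (see
#'   [count_low_energy_minima()]).
#' @return An object of class `flexibility_report` with `probabilities`,
#'   `entropy` (cal K^-1 mol^-1), `n_minima`, and the `max_entropy`
#'   reference `R * log(N)`.
#' @export
flexibility_report <- function(ensemble, window = 5) {
  p <- boltzmann_probabilities(ensemble)
  structure(
    list(
      label = ensemble$label,
      temperature = ensemble$temperature,
      probabilities = p,
      entropy = conformational_entropy(p),
      n_minima = count_low_energy_minima(ensemble, window),
      max_entropy = GAS_CONSTANT_CAL * log(length(p)),
      window = window
    ),
    class = "flexibility_report"
  )
}

#' @export
print.flexibility_report <- function(x, ...) {
  cat(sprintf("<flexibility_report> '%s' at %g K: S = %.3f cal/(K mol) (max %.3f), %d low-energy minima (window %g kcal/mol)\n",
              x$label, x$temperature, x$entropy, x$max_entropy, x$n_minima,
              x$window))
  invisible(x)
}

#' @export
glance.flexibility_report <- function(x, ...) {
  tibble(label = x$label, temperature = x$temperature, entropy = x$entropy,
         max_entropy = x$max_entropy, n_minima = x$n_minima,
         n_conformers = length(x$probabilities), window = x$window)
}

#' @export
tidy.flexibility_report <- function(x, ...) {
  tibble(conformer = seq_along(x$probabilities),
         probability = x$probabilities)
}

#' Compare the flexibility of two conformer ensembles
#'
#' Reports the fold-change in low-energy minima counts, the entropy
#' difference, and which ensemble is the more flexible (higher entropy).
#' Both ensembles must be at the same temperature; re-evaluate one of them
#' explicitly otherwise.
#'
#' @param a,b [conformer_ensemble()] objects at the same temperature.
#' @param window Minima window in kcal/mol.
#' @return A one-row tibble (class `flexibility_comparison`).
#' @export
compare_flexibility <- function(a, b, window = 5) {
  stop_if_not(isTRUE(all.equal(a$temperature, b$temperature)),
              "ensembles are at different temperatures (%g vs %g K); re-evaluate one explicitly",
              a$temperature, b$temperature)
  ra <- flexibility_report(a, window)
  rb <- flexibility_report(b, window)
  out <- tibble(
    label_a = a$label, label_b = b$label,
    n_minima_a = ra$n_minima, n_minima_b = rb$n_minima,
    fold_minima = rb$n_minima / ra$n_minima,
    entropy_a = ra$entropy, entropy_b = rb$entropy,
    delta_entropy = rb$entropy - ra$entropy,
    more_flexible = dplyr::case_when(
      rb$entropy > ra$entropy ~ b$label,
      rb$entropy < ra$entropy ~ a$label,
      TRUE ~ "tie"
    )
  )
  class(out) <- c("flexibility_comparison", class(out))
  out
}

#' Simulate a conformer-energy ensemble
#'
#' Generates `n` conformer energies from a chosen distribution and attaches
#' the directly evaluated reference entropy as ground truth.
#'
#' @param n Conformer count (>= 1).
#' @param energy_scale Spread of the energies in kcal/mol (>= 0; 0 makes all
#'   energies equal).
#' @param distribution `"uniform-window"` (uniform on `[0, energy_scale]`),
#'   `"exponential"` (rate `1/energy_scale`), or `"gaussian"` (sd
#'   `energy_scale`).
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @return A [conformer_ensemble()]; `attr(, "reference_entropy")` holds the
#'   directly computed entropy in cal K^-1 mol^-1.
#' @export
simulate_conformer_ensemble <- function(n, energy_scale = 2,
                                        distribution = c("uniform-window",
                                                         "exponential",
                                                         "gaussian"),
                                        temperature = 298.15, seed = 1L) {
  stop_if_not(n >= 1, "n must be >= 1")
  stop_if_not(energy_scale >= 0, "energy_scale must be >= 0")
  distribution <- match.arg(distribution)
  seed_rng(seed)
  e <- if (energy_scale == 0) rep(0, n) else switch(
    distribution,
    "uniform-window" = runif(n, 0, energy_scale),
    "exponential" = stats::rexp(n, rate = 1 / energy_scale),
    "gaussian" = rnorm(n, 0, energy_scale)
  )
  ens <- conformer_ensemble(e, temperature = temperature,
                            label = sprintf("sim-%s-n%d", distribution, n))
  # direct evaluation of the reference entropy (ground truth for tests)
  w <- exp(-(e - min(e)) / rt_kcal(temperature))
  p <- w / sum(w)
  attr(ens, "reference_entropy") <- -GAS_CONSTANT_CAL *
    sum(p[p > 0] * log(p[p > 0]))
  attr(ens, "params") <- list(n = n, energy_scale = energy_scale,
                              distribution = distribution,
                              temperature = temperature, seed = seed)
  ens
}

#' Read conformer energies from a one-column CSV or a JSON list
#' @param source File path (`.csv`/`.tsv` one column, or `.json` array).
#' @param temperature,label Passed to [conformer_ensemble()].
#' @export
read_conformer_energies <- function(source, temperature = 298.15,
                                    label = basename(source)) {
  e <- if (grepl("\\.json$", source)) {
    as.numeric(jsonlite::read_json(source, simplifyVector = TRUE))
  } else {
    df <- readr::read_csv(source, show_col_types = FALSE, comment = "#")
    as.numeric(df[[1]])
  }
  conformer_ensemble(e, temperature = temperature, label = label)
}
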