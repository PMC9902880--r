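#' Assay configuration for the two-probe displacement chemistry
#'
#' Describes one sample of the surface assay: a Cy5-labelled capture probe
#' (probe 1) immobilized on the coverslip, pre-hybridized with a shorter
#' quencher-labelled competitor (probe 2), and a solution-phase target miRNA
#' that displaces probe 2 and switches the dye on. Concentrations are molar;
#' surface densities are molecules per square micrometre.
#'
#' The dissociation constants are not measurable from spot counts alone, so the
#' defaults encode the qualitative design of the assay: the target binds the
#' capture probe much more tightly (`kd_target` = 10 pM) than the quencher
#' probe does (`kd_probe2` = 10 nM), and the pseudo-first-order displacement
#' rate is such that the reaction is >95% complete after the standard 60 min
#' incubation at 10 pM target.
#'
#' @param probe1_surface_density Surface density of capture-probe sites,
#'   molecules per um^2.
#' @param probe2_conc Quencher-probe solution concentration, molar.
#' @param target_conc Target miRNA solution concentration, molar.
#' @param kd_target Dissociation constant of the target/probe-1 duplex, molar.
#' @param kd_probe2 Dissociation constant of the probe-2/probe-1 duplex, molar.
#' @param k_obs_per_conc Pseudo-first-order rate coefficient, 1/(molar * min).
#' @param kinetic_baseline_conc Background concentration added to the target
#'   concentration in the pseudo-first-order rate, molar.
#' @param reaction_time Incubation time, minutes.
#' @param relative_capture_efficiency Capture efficiency of this species
#'   relative to the perfect-match target, in [0, 1]. Mismatched species are
#'   modelled phenomenologically through this factor.
#' @param unquenched_baseline_fraction Fraction of free capture-probe sites
#'   that fluoresce anyway (sites never paired with probe 2), in [0, 1].
#' @param nonspecific_density False-positive emitters per um^2 from
#'   non-specific adsorption.
#' @param species Label for the target species.
#' @return An object of class `smi_assay`.
#' @seealso [solve_competitive_occupancy()], [occupancy_time_course()]
#' @export
assay_config <- function(probe1_surface_density = 0.15,
                         probe2_conc = 10e-9,
                         target_conc = 10e-12,
                         kd_target = 10e-12,
                         kd_probe2 = 10e-9,
                         k_obs_per_conc = 5e9,
                         kinetic_baseline_conc = 1e-12,
                         reaction_time = 60,
                         relative_capture_efficiency = 1,
                         unquenched_baseline_fraction = 0.02,
                         nonspecific_density = 0.002,
                         species = "miR-126") {
  check_num(probe1_surface_density, "probe1_surface_density", min = 0)
  check_num(probe2_conc, "probe2_conc", min = 0)
  check_num(target_conc, "target_conc", min = 0)
  check_num(kd_target, "kd_target", min = 0)
  check_num(kd_probe2, "kd_probe2", min = 0)
  check_num(k_obs_per_conc, "k_obs_per_conc", min = 0)
  check_num(kinetic_baseline_conc, "kinetic_baseline_conc", min = 0)
  check_num(reaction_time, "reaction_time", min = 0)
  check_num(relative_capture_efficiency, "relative_capture_efficiency",
            min = 0, max = 1)
  check_num(unquenched_baseline_fraction, "unquenched_baseline_fraction",
            min = 0, max = 1)
  check_num(nonspecific_density, "nonspecific_density", min = 0)
  structure(list(probe1_surface_density = probe1_surface_density,
                 probe2_conc = probe2_conc,
                 target_conc = target_conc,
                 kd_target = kd_target,
                 kd_probe2 = kd_probe2,
                 k_obs_per_conc = k_obs_per_conc,
                 kinetic_baseline_conc = kinetic_baseline_conc,
                 reaction_time = reaction_time,
                 relative_capture_efficiency = relative_capture_efficiency,
                 unquenched_baseline_fraction = unquenched_baseline_fraction,
                 nonspecific_density = nonspecific_density,
                 species = as.character(species)),
            class = "smi_assay")
}

#' @export
print.smi_assay <- function(x, ...) {
  cat("Displacement assay configuration (", x$species, ")\n", sep = "")
  cat(sprintf("  probe 1: %.3g sites/um^2 (Kd target %.3g M, Kd probe2 %.3g M)\n",
              x$probe1_surface_density, x$kd_target, x$kd_probe2))
  cat(sprintf("  probe 2: %.3g M, target: %.3g M (capture efficiency %.3g)\n",
              x$probe2_conc, x$target_conc, x$relative_capture_efficiency))
  cat(sprintf("  reaction: %.3g min; baseline unquenched %.3g; nonspecific %.3g/um^2\n",
              x$reaction_time, x$unquenched_baseline_fraction,
              x$nonspecific_density))
  invisible(x)
}

#' Equilibrium occupancy of the capture probe under competitive hybridization
#'
#' Solves the competitive-binding equilibrium between the target miRNA and the
#' quencher probe for the surface capture-probe sites, assuming solution
#' species are in large excess over surface sites (no ligand depletion). With
#' \eqn{a = c_T e / K_T} and \eqn{b = c_2 / K_2},
#' \deqn{\theta_T = a / (1 + a + b), \quad \theta_2 = b / (1 + a + b),}
#' and the free fraction is the remainder. The fluorescent emitter density is
#' `probe1_surface_density * (theta_target + unquenched_baseline_fraction *
#' theta_free) + nonspecific_density`: target-bound sites are unquenched, a
#' small fraction of never-paired free sites fluoresce, and non-specific
#' adsorption adds a constant floor.
#'
#' @param cfg An [assay_config()] object.
#' @return An object of class `smi_occupancy` with fields `theta_target`,
#'   `theta_probe2`, `theta_free` (fractions summing to 1) and
#'   `fluorescent_density` (emitters per um^2).
#' @examples
#' solve_competitive_occupancy(assay_config(target_conc = 10e-12))
#' @export
solve_competitive_occupancy <- function(cfg) {
  if (!inherits(cfg, "smi_assay")) abort_config("'cfg' must be an smi_assay")
  if (cfg$target_conc > 0 && cfg$kd_target <= 0)
    abort_config("kd_target must be > 0 when target_conc > 0")
  if (cfg$probe2_conc > 0 && cfg$kd_probe2 <= 0)
    abort_config("kd_probe2 must be > 0 when probe2_conc > 0")
  a <- if (cfg$target_conc > 0)
    cfg$target_conc * cfg$relative_capture_efficiency / cfg$kd_target else 0
  b <- if (cfg$probe2_conc > 0) cfg$probe2_conc / cfg$kd_probe2 else 0
  denom <- 1 + a + b
  theta_target <- a / denom
  theta_probe2 <- b / denom
  theta_free <- 1 / denom
  dens <- cfg$probe1_surface_density *
    (theta_target + cfg$unquenched_baseline_fraction * theta_free) +
    cfg$nonspecific_density
  structure(list(theta_target = theta_target,
                 theta_probe2 = theta_probe2,
                 theta_free = theta_free,
                 fluorescent_density = dens,
                 species = cfg$species),
            class = "smi_occupancy")
}

#' @export
print.smi_occupancy <- function(x, ...) {
  cat(sprintf("Occupancy (%s): target %.4f, probe2 %.4f, free %.4f\n",
              x$species, x$theta_target, x$theta_probe2, x$theta_free))
  cat(sprintf("  fluorescent density: %.4g emitters/um^2\n",
              x$fluorescent_density))
  invisible(x)
}

#' Displacement time course of the target occupancy
#'
#' Pseudo-first-order approach to the competitive equilibrium:
#' \deqn{\theta_T(t) = \theta_T^{eq} (1 - e^{-k_{obs} t}),}
#' with \eqn{k_{obs} = k_{obs/c} (c_T + c_0)} where \eqn{c_0} is a small
#' kinetic baseline concentration. The probe-2 and free fractions relax from
#' their target-free equilibrium to the competitive equilibrium with the same
#' rate, so the three fractions sum to one at every time point.
#'
#' @param cfg An [assay_config()] object.
#' @param times Sorted vector of times in minutes, all >= 0.
#' @return A data frame (class `smi_occupancy_course`) with one row per time:
#'   `time`, `theta_target`, `theta_probe2`, `theta_free`,
#'   `fluorescent_density`.
#' @export
occupancy_time_course <- function(cfg, times) {
  if (!inherits(cfg, "smi_assay")) abort_config("'cfg' must be an smi_assay")
  if (!is.numeric(times) || length(times) < 1 || anyNA(times))
    abort_config("'times' must be a numeric vector")
  if (any(times < 0)) abort_config("negative times are not allowed")
  if (is.unsorted(times)) abort_config("'times' must be sorted increasing")
  eq <- solve_competitive_occupancy(cfg)
  cfg0 <- cfg
  cfg0$target_conc <- 0
  init <- solve_competitive_occupancy(cfg0)
  k_obs <- cfg$k_obs_per_conc * (cfg$target_conc + cfg$kinetic_baseline_conc)
  s <- 1 - exp(-k_obs * times)
  th_t <- eq$theta_target * s
  th_2 <- init$theta_probe2 + (eq$theta_probe2 - init$theta_probe2) * s
  th_f <- init$theta_free + (eq$theta_free - init$theta_free) * s
  dens <- cfg$probe1_surface_density *
    (th_t + cfg$unquenched_baseline_fraction * th_f) + cfg$nonspecific_density
  structure(data.frame(time = times, theta_target = th_t, theta_probe2 = th_2,
                       theta_free = th_f, fluorescent_density = dens),
            class = c("smi_occupancy_course", "data.frame"))
}
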