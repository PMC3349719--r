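#' Cross-bridge energetics and strain-dependent rate parameters
#'
#' Parameterises the three-state cross-bridge cycle XB1 (unbound) -> XB2
#' (bound, pre-power-stroke, low force) -> XB3 (bound, post-power-stroke,
#' high force) -> XB1 on free-energy wells over the distortion coordinate
#' `x`, the axial offset between the myosin node and its actin partner
#' (positive = myosin toward the Z-line; `x = 0` is the zero-strain binding
#' register of XB2). The unbound level is flat (`G1 = 0` reference); the
#' bound wells are parabolas of curvature `k_xb / (2 kT)`:
#' `G2(x) = -w2 + k_xb x^2 / (2 kT)` and
#' `G3(x) = -w3 + k_xb (x - x_ps)^2 / (2 kT)` (thermal units).
#'
#' The power-stroke distance `x_ps` is derived from a stiffness-independent
#' stroke free energy: `x_ps = sqrt(2 kT stroke_energy / k_xb)`, so the
#' stroke thermodynamics at the zero-strain register are preserved when
#' `k_xb` is varied while the force borne per post-stroke bridge scales as
#' `sqrt(k_xb)`. Pass `x_ps` explicitly to override. Each model myosin
#' coarse-grains a crown of heads, so the well depths and stroke energy are
#' effective values calibrated against whole-half-sarcomere steady-state
#' observables (maximal force, bound fraction and its split between XB2 and
#' XB3, rate of force development), not single-molecule constants.
#'
#' @param k_xb Cross-bridge spring constant (pN/nm).
#' @param kT Thermal energy (pN nm).
#' @param w2,w3 Depths of the XB2 and XB3 wells below the unbound level
#'   (thermal units). `w3` defaults to `w2 + stroke_energy + b_stroke` so
#'   the power stroke at `x = 0` drops the free energy by `b_stroke`.
#' @param stroke_energy Elastic energy `k_xb x_ps^2 / (2 kT)` stored by a
#'   full stroke at fixed `x = 0` (thermal units); sets `x_ps`.
#' @param b_stroke Free-energy drop of the stroke at the zero-strain
#'   register (thermal units).
#' @param x_ps Power-stroke distance (nm); overrides `stroke_energy`.
#' @param attach_rate Peak attachment rate (1/s) at the reference
#'   cross-bridge stiffness `k_xb_ref`.
#' @param attach_exp_lo,attach_exp_hi Exponents of the attachment-rate
#'   prefactor `(k_xb/k_xb_ref)^e` below and above the reference
#'   stiffness. Below the reference the peak follows the head's thermal
#'   positional density (`e = 1/2`, the window-limited regime); above it
#'   the spring's attempt frequency dominates (`e > 1`), an empirical
#'   rate-shape calibrated against the stiffness dependence of turnover
#'   and force development.
#' @param k_xb_ref Reference stiffness (pN/nm) at which `attach_rate` and
#'   the stroke energy are quoted.
#' @param f1 Peak attachment rate at perfect register (1/s); computed from
#'   `attach_rate` unless given explicitly.
#' @param h23 Power-stroke attempt rate ceiling (1/s).
#' @param d31,d31_strain Post-stroke detachment: base rate (1/s) and
#'   dimensionless strain acceleration, `r31(x) = d31 (1 + d31_strain
#'   ((x - x_ps)/x_ps)^2)`.
#' @param rate_cap Rate (1/s) above which a transition probability reaches
#'   1 in a 1-ms step; faster kinetics are handled by sub-stepping.
#' @export
xb_energetics <- function(k_xb = 3, kT = 4.14,
                          w2 = 0.55, stroke_energy = 70, b_stroke = 2.5,
                          w3 = NULL, x_ps = NULL,
                          attach_rate = 90, attach_exp_lo = 0.5,
                          attach_exp_hi = 1.3, k_xb_ref = 3, f1 = NULL,
                          h23 = 170, d31 = 50, d31_strain = 2,
                          rate_cap = 1000) {
  stopifnot(k_xb > 0, kT > 0, attach_rate > 0, k_xb_ref > 0, h23 > 0,
            d31 > 0, d31_strain >= 0, rate_cap > 0)
  if (is.null(x_ps)) x_ps <- sqrt(2 * kT * stroke_energy / k_xb)
  phi <- k_xb / (2 * kT)
  if (is.null(f1)) {
    e_att <- if (k_xb >= k_xb_ref) attach_exp_hi else attach_exp_lo
    f1 <- attach_rate * (k_xb / k_xb_ref)^e_att
  }
  stopifnot(f1 > 0)
  if (is.null(w3)) w3 <- w2 + phi * x_ps^2 + b_stroke
  stopifnot(w3 > w2)
  structure(list(k_xb = k_xb, kT = kT, phi = phi, w2 = w2, w3 = w3,
                 x_ps = x_ps, stroke_energy = phi * x_ps^2,
                 attach_rate = attach_rate, attach_exp_lo = attach_exp_lo,
                 attach_exp_hi = attach_exp_hi, k_xb_ref = k_xb_ref,
                 f1 = f1, h23 = h23, d31 = d31,
                 d31_strain = d31_strain, rate_cap = rate_cap),
            class = "xb_energetics")
}

#' @export
print.xb_energetics <- function(x, ...) {
  cat("<xb_energetics>\n")
  cat(sprintf("  k_xb = %g pN/nm, kT = %g pN nm, x_ps = %.2f nm\n",
              x$k_xb, x$kT, x$x_ps))
  cat(sprintf("  wells: w2 = %g kT, w3 = %g kT (stroke energy %.1f kT)\n",
              x$w2, x$w3, x$stroke_energy))
  cat(sprintf("  f1 = %g /s, h23 = %g /s, d31 = %g /s (strain accel %g), cap = %g /s\n",
              x$f1, x$h23, x$d31, x$d31_strain, x$rate_cap))
  invisible(x)
}

#' Cross-bridge free energy
#'
#' Free energy (thermal units) of a cross-bridge state at distortion `x`:
#' the flat unbound level `G1 = 0`, or the parabolic bound wells `G2`, `G3`
#' with curvature `k_xb / (2 kT)` and minima at 0 and the power-stroke
#' distance.
#'
#' @param state Integer 1, 2 or 3 (XB1/XB2/XB3); vectorised.
#' @param x Distortion (nm); vectorised.
#' @param energetics An [xb_energetics()] object.
#' @export
xb_free_energy <- function(state, x, energetics) {
  e <- energetics
  out <- numeric(length(x) * 0 + max(length(x), length(state)))
  state <- rep_len(state, length(out)); x <- rep_len(x, length(out))
  out[state == 1L] <- 0
  out[state == 2L] <- -e$w2 + e$phi * x[state == 2L]^2
  out[state == 3L] <- -e$w3 + e$phi * (x[state == 3L] - e$x_ps)^2
  out
}

#' Strain-dependent cross-bridge transition rates
#'
#' The five rates of the cycle at distortion `x` (vectorised):
#' * `r12(x) = f1 exp(-k_xb x^2 / 2kT)` - Gaussian attachment window, the
#'   Boltzmann weight of the head diffusing a distance `x` against its own
#'   spring, maximal at perfect register;
#' * `r21(x) = r12(x) exp(G2 - G1)` - detailed balance (a constant,
#'   `f1 exp(-w2)`);
#' * `r23(x) = h23 / (1 + exp(G3 - G2))`, `r32(x) = h23 / (1 + exp(G2 -
#'   G3))` - Glauber-gated power stroke, bounded by `h23`, favoured exactly
#'   when it lowers the free energy, and satisfying detailed balance
#'   `r23/r32 = exp(-(G3 - G2))` at every `x`;
#' * `r31(x) = d31 (1 + d31_strain ((x - x_ps)/x_ps)^2)` - irreversible
#'   ATP-coupled detachment, accelerated by post-stroke strain; there is no
#'   reverse `r13`.
#'
#' @param x Distortion (nm).
#' @param energetics An [xb_energetics()] object.
#' @return Tibble with columns `x, r12, r21, r23, r32, r31` (1/s).
#' @export
xb_rates <- function(x, energetics) {
  e <- energetics
  g2 <- -e$w2 + e$phi * x^2
  g3 <- -e$w3 + e$phi * (x - e$x_ps)^2
  dg <- g3 - g2
  tibble::tibble(
    x = x,
    r12 = e$f1 * exp(-e$phi * x^2),
    r21 = e$f1 * exp(g2 - e$phi * x^2),
    r23 = e$h23 / (1 + exp(dg)),
    r32 = e$h23 / (1 + exp(-dg)),
    r31 = e$d31 * (1 + e$d31_strain * ((x - e$x_ps) / e$x_ps)^2)
  )
}

#' Monte Carlo update of cross-bridge states (reference stepper)
#'
#' Advances a population of cross-bridges one time step at fixed distortions
#' (mechanics frozen), mirroring the engine's kinetic logic on a small,
#' inspectable state: unbound bridges attempt attachment to their candidate
#' actin node only if it is available and unoccupied, with probability
#' `r12(x) dt`; bound bridges take one of their two exits by partitioning a
#' single uniform draw (probabilities renormalised and a transition forced
#' when their sum reaches 1); every completed XB3 -> XB1 detachment counts
#' one ATP. If any applicable rate exceeds `rate_cap` the update of that
#' bridge runs as `n_substeps` equal sub-steps at fixed `x`, permitting
#' multiple transitions within the step.
#'
#' @param states Integer vector of cross-bridge states (1, 2, 3).
#' @param partner Integer vector of bound actin node ids (`NA` if unbound).
#' @param candidate Integer vector: the actin node each unbound bridge
#'   would attach to.
#' @param x Numeric vector of current distortions (nm) to the bound
#'   partner, or to the candidate node for unbound bridges.
#' @param available Logical vector (parallel to `states`): is the
#'   candidate/partner node myosin-available.
#' @param energetics An [xb_energetics()] object.
#' @param dt Time step (s).
#' @param n_substeps Sub-steps used when a rate exceeds `rate_cap`.
#' @return List with updated `states`, `partner`, `atp_events` and
#'   `occupied` (node ids claimed this step).
#' @export
step_xb <- function(states, partner, candidate, x, available, energetics,
                    dt, n_substeps = 10L) {
  stopifnot(dt > 0, length(partner) == length(states),
            length(x) == length(states), length(available) == length(states))
  e <- energetics
  occupied <- partner[!is.na(partner)]
  atp <- 0L
  scalar_rates <- function(xi) {
    g2 <- -e$w2 + e$phi * xi^2
    g3 <- -e$w3 + e$phi * (xi - e$x_ps)^2
    dg <- g3 - g2
    r12 <- e$f1 * exp(-e$phi * xi^2)
    c(r12 = r12, r21 = e$f1 * exp(g2 - e$phi * xi^2),
      r23 = e$h23 / (1 + exp(dg)), r32 = e$h23 / (1 + exp(-dg)),
      r31 = e$d31 * (1 + e$d31_strain * ((xi - e$x_ps) / e$x_ps)^2))
  }
  for (i in seq_along(states)) {
    rs <- scalar_rates(x[i])
    steps <- 1L
    step_dt <- dt
    applicable <- switch(states[i],
                         rs[["r12"]], rs[c("r21", "r23")], rs[c("r32", "r31")])
    if (max(applicable) > e$rate_cap) {
      steps <- n_substeps
      step_dt <- dt / n_substeps
    }
    for (s in seq_len(steps)) {
      if (states[i] == 1L) {
        node <- candidate[i]
        if (is.na(node) || !available[i] || node %in% occupied) next
        if (stats::runif(1) < min(1, rs[["r12"]] * step_dt)) {
          states[i] <- 2L; partner[i] <- node
          occupied <- c(occupied, node)
        }
      } else {
        if (states[i] == 2L) {
          pa <- rs[["r23"]] * step_dt; ta <- 3L
          pb <- rs[["r21"]] * step_dt; tb <- 1L
        } else {
          pa <- rs[["r32"]] * step_dt; ta <- 2L
          pb <- rs[["r31"]] * step_dt; tb <- 1L
        }
        tot <- pa + pb
        if (tot >= 1) { pa <- pa / tot; pb <- pb / tot }
        u <- stats::runif(1)
        from <- states[i]
        if (u < pa) states[i] <- ta
        else if (u < pa + pb) states[i] <- tb
        if (states[i] == 1L && from > 1L) {
          if (from == 3L) atp <- atp + 1L
          occupied <- setdiff(occupied, partner[i])
          partner[i] <- NA_integer_
          break  # a bridge that detached mid-step does not reattach
        }
      }
    }
  }
  list(states = states, partner = partner, atp_events = atp,
       occupied = occupied)
}
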