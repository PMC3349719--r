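#' Default pCa grid for force-pCa protocols
#'
#' Nine points from 4.0 to 8.0 concentrated around the activation
#' transition (0.25-unit spacing between pCa 5.5 and 6.5), dense enough to
#' resolve the Hill slope at desk-scale cost.
#'
#' @export
default_pca_grid <- function() c(4.0, 5.0, 5.5, 5.75, 6.0, 6.25, 6.5, 7.0, 8.0)

protocol_result <- function(name, spec, tables, fits = NULL) {
  structure(list(name = name, spec = spec, tables = tables, fits = fits),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s\n", x$name))
  for (nm in names(x$tables)) {
    cat("$", nm, ":\n", sep = "")
    print(x$tables[[nm]], n = 6)
  }
  invisible(x)
}

#' Force-pCa protocol with Hill fits
#'
#' Runs replicate simulations over a pCa grid at one activation span and
#' fits the three-parameter Hill equation to the steady-state force and
#' fraction-available means.
#'
#' @param ru_span Activation span (actins).
#' @param pCa pCa grid.
#' @param n_reps Replicates per grid point.
#' @param base_seed Base seed; all cell seeds derive from it.
#' @param duration Simulated seconds per run.
#' @param ... Passed to [run_simulation()] (stiffness scalers, cooperative
#'   configuration, ...).
#' @return A `protocol_result` with tables `summary` and `results`, and
#'   Hill fits for `force` and `frac_avail`.
#' @export
protocol_force_pca <- function(ru_span = 9, pCa = default_pca_grid(),
                               n_reps = 4, base_seed = 1, duration = 2, ...) {
  reps <- run_replicates(pCa = pCa, n_reps = n_reps, base_seed = base_seed,
                         duration = duration, ru_span = ru_span, ...)
  s <- reps$summary
  # inverse-variance weighting: the replicate SEs differ by orders of
  # magnitude between the plateau and the transition
  wfit <- function(y, se) {
    if (length(unique(s$pCa)) < 4) return(NULL)  # grid too small to fit
    if (all(is.finite(s[[se]])) && any(s[[se]] > 0)) {
      hill_fit(s, pca = "pCa", y = !!rlang::sym(y), weights = !!rlang::sym(se))
    } else {
      hill_fit(s, pca = "pCa", y = !!rlang::sym(y))
    }
  }
  fits <- list(
    force = wfit("force_mean", "force_se"),
    frac_avail = wfit("frac_avail_mean", "frac_avail_se")
  )
  protocol_result(
    "force_pca",
    spec = list(ru_span = ru_span, pCa = pCa, n_reps = n_reps,
                base_seed = base_seed, duration = duration),
    tables = list(summary = s, results = reps$results),
    fits = fits
  )
}

#' Activation-span by troponin-density protocol
#'
#' Co-varies the regulatory-unit activation span and the functional
#' troponin density at saturating calcium, reporting steady-state force per
#' cell. The force-versus-density relationship is close to linear when the
#' span equals one structural regulatory unit (7 actins) and becomes
#' increasingly convex as the span grows.
#'
#' @param ru_span Spans (actins) to sweep.
#' @param rho_tn Functional troponin densities to sweep.
#' @param pCa Calcium level (default saturating, 4.0).
#' @param n_reps,base_seed,duration As in [protocol_force_pca()].
#' @param ... Passed to [run_simulation()].
#' @export
protocol_ru_span_rho <- function(ru_span = c(7, 9, 11, 14),
                                 rho_tn = seq(0, 1, by = 0.25),
                                 pCa = 4, n_reps = 4, base_seed = 1,
                                 duration = 2, ...) {
  grid <- tidyr::expand_grid(ru_span = ru_span, rho_tn = rho_tn)
  cells <- purrr::pmap_dfr(grid, function(ru_span, rho_tn) {
    reps <- run_replicates(pCa = pCa, n_reps = n_reps,
                           base_seed = derive_seed(base_seed,
                                                   1000L * match(ru_span, c(7, 9, 11, 14)),
                                                   round(1e4 * rho_tn)),
                           duration = duration,
                           ru_span = ru_span, rho_tn = rho_tn, ...)
    dplyr::mutate(reps$summary, ru_span = ru_span, rho_tn = rho_tn,
                  .before = 1)
  })
  protocol_result(
    "ru_span_x_rhoTn",
    spec = list(ru_span = ru_span, rho_tn = rho_tn, pCa = pCa,
                n_reps = n_reps, base_seed = base_seed, duration = duration),
    tables = list(cells = cells)
  )
}

#' Cooperative pathway matrix protocol
#'
#' Runs the force-pCa protocol for combinations of cooperativity sources
#' (TF3, XB2, XB3) and targets (`rt12`, `rt23`), returning the fitted
#' `pCa50` and `n_H` per combination. The single-source hierarchy of
#' influence on `pCa50` is TF3 > XB2 > XB3, and joint targets exceed single
#' targets.
#'
#' @param sources List of character vectors of sources (empty vector =
#'   no cooperativity).
#' @param targets List of character vectors of targets.
#' @param pCa,n_reps,base_seed,duration As in [protocol_force_pca()].
#' @param ... Passed to [run_simulation()].
#' @export
protocol_coop_matrix <- function(sources = list("TF3", "XB2", "XB3",
                                                c("TF3", "XB2", "XB3")),
                                 targets = list(c("rt12", "rt23")),
                                 pCa = default_pca_grid(), n_reps = 4,
                                 base_seed = 1, duration = 2, ...) {
  grid <- tidyr::expand_grid(i_src = seq_along(sources),
                             i_tgt = seq_along(targets))
  rows <- purrr::pmap_dfr(grid, function(i_src, i_tgt) {
    src <- sources[[i_src]]; tgt <- targets[[i_tgt]]
    cc <- if (length(src) == 0) coop_config(enabled = FALSE)
      else coop_config(sources = src, targets = tgt)
    pr <- protocol_force_pca(pCa = pCa, n_reps = n_reps,
                             base_seed = derive_seed(base_seed, i_src, i_tgt),
                             duration = duration, coop = cc, ...)
    cf <- coef(pr$fits$force)
    tibble::tibble(
      sources = paste(src, collapse = "+"),
      targets = paste(tgt, collapse = "+"),
      x_max = cf["x_max"], pca50 = cf["pca50"], n_h = cf["n_h"],
      converged = pr$fits$force$converged
    )
  })
  protocol_result(
    "coop_pathway_matrix",
    spec = list(sources = sources, targets = targets, pCa = pCa,
                n_reps = n_reps, base_seed = base_seed, duration = duration),
    tables = list(fits = rows)
  )
}

#' Cross-bridge contribution protocol
#'
#' Compares thin-filament activation with and without cross-bridge binding,
#' each with and without cooperative kinetics, reporting steady-state
#' fraction available and the activation rate constant per condition.
#'
#' @param pCa pCa values.
#' @param n_reps,base_seed,duration As in [protocol_force_pca()].
#' @param ... Passed to [run_simulation()].
#' @export
protocol_xb_contribution <- function(pCa = default_pca_grid(), n_reps = 4,
                                     base_seed = 1, duration = 2, ...) {
  grid <- tidyr::expand_grid(xb_binding = c(TRUE, FALSE),
                             cooperative = c(TRUE, FALSE))
  cells <- purrr::pmap_dfr(grid, function(xb_binding, cooperative) {
    reps <- run_replicates(pCa = pCa, n_reps = n_reps,
                           base_seed = derive_seed(base_seed,
                                                   xb_binding * 2L + cooperative, 0L),
                           duration = duration, xb_binding = xb_binding,
                           coop = coop_config(enabled = cooperative), ...)
    dplyr::mutate(reps$summary, xb_binding = xb_binding,
                  cooperative = cooperative, .before = 1)
  })
  protocol_result(
    "xb_contribution",
    spec = list(pCa = pCa, n_reps = n_reps, base_seed = base_seed,
                duration = duration),
    tables = list(cells = cells)
  )
}

#' Stiffness sweep protocol
#'
#' Varies the cross-bridge spring constant and the thick/thin filament
#' stiffness scalers at saturating calcium, reporting steady-state force,
#' rate of force development and ATPase per condition.
#'
#' @param conditions Tibble with columns `k_xb`, `k_m_scale`, `k_a_scale`,
#'   `k_fil_scale` (one row per condition).
#' @param pCa Calcium level.
#' @param n_reps,base_seed,duration As in [protocol_force_pca()].
#' @param ... Passed to [run_simulation()].
#' @export
protocol_stiffness_sweep <- function(conditions = NULL, pCa = 4, n_reps = 4,
                                     base_seed = 1, duration = 2, ...) {
  if (is.null(conditions)) {
    conditions <- dplyr::bind_rows(
      tibble::tibble(k_xb = c(1, 3, 10), k_m_scale = 1, k_a_scale = 1,
                     k_fil_scale = 1),
      tibble::tibble(k_xb = 3, k_m_scale = c(0.1, 10), k_a_scale = 1,
                     k_fil_scale = 1),
      tibble::tibble(k_xb = 3, k_m_scale = 1, k_a_scale = c(0.1, 10),
                     k_fil_scale = 1),
      tibble::tibble(k_xb = 3, k_m_scale = 1, k_a_scale = 1,
                     k_fil_scale = c(0.1, 10))
    )
  }
  cells <- purrr::map_dfr(seq_len(nrow(conditions)),
    function(i) {
      cond <- conditions[i, ]
      sc <- stiffness_scalers(k_m_scale = cond$k_m_scale,
                              k_a_scale = cond$k_a_scale,
                              k_fil_scale = cond$k_fil_scale,
                              k_xb = cond$k_xb)
      reps <- run_replicates(pCa = pCa, n_reps = n_reps,
                             base_seed = derive_seed(base_seed, i, 0L),
                             duration = duration, scalers = sc, ...)
      dplyr::bind_cols(cond, reps$summary)
    })
  protocol_result(
    "stiffness_sweep",
    spec = list(conditions = conditions, pCa = pCa, n_reps = n_reps,
                base_seed = base_seed, duration = duration),
    tables = list(cells = cells)
  )
}

#' Cooperative-scale sweep protocol
#'
#' Sweeps the cooperative amplification factor psi, with the Ca-equilibrium
#' rescale xi either fixed or tied to psi, reporting force-pCa Hill
#' parameters per cell.
#'
#' @param psi Psi values.
#' @param xi Either a single value or `"psi"` to set xi = psi per cell.
#' @param pCa,n_reps,base_seed,duration As in [protocol_force_pca()].
#' @param ... Passed to [run_simulation()].
#' @export
protocol_psi_xi <- function(psi = c(1, 10, 100, 1000), xi = 100,
                            pCa = default_pca_grid(), n_reps = 4,
                            base_seed = 1, duration = 2, ...) {
  rows <- purrr::map_dfr(seq_along(psi), function(i) {
    xi_i <- if (identical(xi, "psi")) psi[i] else xi
    pr <- protocol_force_pca(pCa = pCa, n_reps = n_reps,
                             base_seed = derive_seed(base_seed, i, 0L),
                             duration = duration,
                             rates = thin_rate_table(psi = psi[i], xi = xi_i),
                             ...)
    cf <- coef(pr$fits$force)
    tibble::tibble(psi = psi[i], xi = xi_i, x_max = cf["x_max"],
                   pca50 = cf["pca50"], n_h = cf["n_h"])
  })
  protocol_result(
    "psi_xi_sweep",
    spec = list(psi = psi, xi = xi, pCa = pCa, n_reps = n_reps,
                base_seed = base_seed, duration = duration),
    tables = list(fits = rows)
  )
}

#' Stationary distribution of a continuous-time Markov generator
#'
#' Left null vector of the generator matrix, normalised to a probability
#' vector; the independent oracle used for frozen-kinetics checks.
#'
#' @param Q Square generator matrix (rows sum to zero).
#' @export
markov_stationary <- function(Q) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q),
            max(abs(rowSums(Q))) < 1e-8 * max(abs(Q)))
  ev <- eigen(t(Q))
  i <- which.min(abs(ev$values))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

#' Generator of the three-state regulatory-unit chain
#'
#' @param rates Named vector from [effective_rates()] (pseudo-first-order,
#'   1/s): `r12, r21, r23, r32, r31, r13`.
#' @return 3x3 generator matrix over states (TF1, TF2, TF3).
#' @export
ru_generator <- function(rates) {
  r <- rates
  Q <- matrix(0, 3, 3, dimnames = list(c("TF1", "TF2", "TF3"),
                                       c("TF1", "TF2", "TF3")))
  Q["TF1", "TF2"] <- r[["r12"]]; Q["TF1", "TF3"] <- r[["r13"]]
  Q["TF2", "TF1"] <- r[["r21"]]; Q["TF2", "TF3"] <- r[["r23"]]
  Q["TF3", "TF2"] <- r[["r32"]]; Q["TF3", "TF1"] <- r[["r31"]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Generate analytic test fixtures
#'
#' Emits small, fully specified inputs with analytically known answers:
#' * `"tiny_lattice"` - a 1-thick/2-thin lattice with short filaments;
#' * `"spring_chain"` - a two-element chain (anchors at both ends, one
#'   internal node) with its closed-form displacement under a point load;
#' * `"frozen_markov"` - the regulatory-unit generator at fixed calcium
#'   with its stationary eigen-distribution;
#' * `"hill_curves"` - noise-free and noisy Hill data with the true
#'   parameters recorded.
#'
#' @param kind Fixture kind.
#' @param seed Seed for any randomness in the fixture.
#' @export
generate_fixtures <- function(kind = c("tiny_lattice", "spring_chain",
                                       "frozen_markov", "hill_curves"),
                              seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    tiny_lattice = build_lattice(n_thick = 1, n_thin = 2,
                                 nodes_per_thick = 12, nodes_per_thin = 18,
                                 hs_length = 300),
    spring_chain = {
      k1 <- 100; k2 <- 300; f <- 12
      list(k = c(k1, k2), load = f,
           displacement = f / (k1 + k2),
           note = "two springs to fixed walls, point load f on the shared node")
    },
    frozen_markov = {
      rt <- thin_rate_table()
      Ca <- 1e-4
      r <- effective_rates(Ca, context = logical(0), table = rt,
                           coop = coop_config(enabled = FALSE))
      Q <- ru_generator(r)
      list(Ca = Ca, rates = r, Q = Q, stationary = markov_stationary(Q))
    },
    hill_curves = {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      pca <- seq(8, 4, by = -0.25)
      truth <- list(x_max = 1000, pca50 = 5.95, n_h = 3.2)
      clean <- hill_curve(pca, truth$x_max, truth$pca50, truth$n_h)
      list(truth = truth, pca = pca, clean = clean,
           noisy = clean + stats::rnorm(length(pca), sd = 15), sd = 15)
    })
}
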