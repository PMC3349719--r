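pack_geometry <- function(lattice, scalers) {
  nodes <- lattice$nodes
  el <- lattice$elements
  k_el <- element_stiffness(lattice, scalers)
  anchors <- el$role == "anchor"
  tr <- lattice$troponins
  stopifnot(!is.null(tr$functional), !is.null(tr$influence))
  infl_len <- lengths(tr$influence)
  cand <- lattice$myosins$candidates
  cand_len <- lengths(cand)
  list(
    fil_of = as.integer(nodes$filament - 1L),
    p0 = as.numeric(nodes$position),
    el_a = as.integer(el$node_a - 1L),   # wall (0) becomes -1
    el_b = as.integer(el$node_b - 1L),
    el_k = as.numeric(k_el),
    zanch_node = as.integer(el$node_b[anchors & el$kind == "thin"] - 1L),
    zanch_k = as.numeric(k_el[anchors & el$kind == "thin"]),
    manch_node = as.integer(el$node_b[anchors & el$kind == "thick"] - 1L),
    manch_k = as.numeric(k_el[anchors & el$kind == "thick"]),
    myo_node = as.integer(lattice$myosins$node - 1L),
    cand_ptr = as.integer(c(0L, cumsum(cand_len))),
    cand_node = as.integer(unlist(cand, use.names = FALSE) - 1L),
    trop_func = as.integer(tr$functional),
    trop_prev = as.integer(ifelse(is.na(tr$prev), 0L, tr$prev) - 1L),
    trop_next = as.integer(ifelse(is.na(tr$nxt), 0L, tr$nxt) - 1L),
    infl_ptr = as.integer(c(0L, cumsum(infl_len))),
    infl_node = as.integer(unlist(tr$influence, use.names = FALSE) - 1L),
    n_thin_nodes = sum(nodes$kind == "thin")
  )
}

#' Run one half-sarcomere simulation
#'
#' Simulates isometric activation of the half-sarcomere at a clamped
#' calcium level. The system starts fully relaxed (all regulatory units
#' Ca-free, all cross-bridges unbound, filaments at rest) and is stepped
#' with the Monte Carlo scheme: each step solves the instantaneous force
#' balance, evaluates thin-filament and strain-dependent cross-bridge
#' rates from the start-of-step state, applies synchronous stochastic
#' updates, and records the observables. Runs are bit-reproducible for a
#' fixed configuration and seed.
#'
#' @param pCa Clamped calcium level, `-log10([Ca2+]/M)`.
#' @param duration Simulated time (s); at least ~0.5 s is recommended to
#'   reach steady state.
#' @param dt Time step (s), default 1 ms.
#' @param seed Integer RNG seed.
#' @param lattice Optional prebuilt `lattice_geometry`; by default the
#'   standard 4 thick / 8 thin lattice is built.
#' @param rho_tn,ru_span Troponin functional density and activation span
#'   (actins), used when `lattice` lacks a layout. The knockout draw uses a
#'   seed derived from `seed`.
#' @param rates A [thin_rate_table()].
#' @param coop A [coop_config()].
#' @param energetics An [xb_energetics()]; defaults to
#'   `xb_energetics(k_xb = scalers$k_xb)`.
#' @param scalers A [stiffness_scalers()].
#' @param xb_binding Set `FALSE` to disable cross-bridge binding entirely
#'   (pure thin-filament activation model).
#' @param deactivation How regulatory-unit deactivation interacts with
#'   bound cross-bridges. `"release"` (default): units deactivate freely
#'   and any bridge whose node loses availability is forcibly released
#'   (interrupted cycle, no ATP counted), so attachments and availability
#'   stay consistent at every step. `"free"`: availability gates only new
#'   attachments - a bound bridge completes its cycle on the node where
#'   binding was granted. `"block"`: a unit cannot leave TF3 while any
#'   bridge is bound within its influence region (hard steric
#'   interpretation; produces slowly creeping quasi-steady states at
#'   intermediate calcium).
#' @param n_substeps Sub-steps used when a cross-bridge rate exceeds the
#'   probability-1 threshold within `dt`.
#' @return A `sim_trace`: tibble with one row per step (`t`, `force`,
#'   `force_m`, `frac_avail`, regulatory and cross-bridge state fractions,
#'   `n_bound`, cumulative `atp`) carrying the configuration, seed and
#'   final microstate as attributes.
#' @examples
#' \donttest{
#' tr <- run_simulation(pCa = 4, duration = 0.3, seed = 1)
#' dplyr::last(tr$force)
#' }
#' @export
run_simulation <- function(pCa, duration = 2, dt = 1e-3, seed = NULL,
                           lattice = NULL, rho_tn = 1, ru_span = 9,
                           rates = thin_rate_table(),
                           coop = coop_config(),
                           energetics = NULL,
                           scalers = stiffness_scalers(),
                           xb_binding = TRUE,
                           deactivation = c("release", "free", "block"),
                           n_substeps = 10L) {
  deactivation <- match.arg(deactivation)
  stopifnot(duration >= 0, dt > 0, pCa > 0)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  if (is.null(lattice)) lattice <- build_lattice()
  if (is.null(lattice$troponins[["functional"]])) {
    lattice <- assign_troponin(lattice, rho_tn = rho_tn,
                               seed = (seed + 777L) %% 2147483647L)
  }
  if (is.null(lattice$troponins[["influence"]])) {
    lattice <- influence_map(lattice, ru_span = ru_span)
  }
  if (is.null(energetics)) energetics <- xb_energetics(k_xb = scalers$k_xb)
  if (!isTRUE(all.equal(energetics$k_xb, scalers$k_xb))) {
    stop("energetics$k_xb and scalers$k_xb disagree", call. = FALSE)
  }
  Ca <- 10^(-pCa)
  geom <- pack_geometry(lattice, scalers)
  kin <- list(
    Ca = Ca, dt = dt,
    r_t12 = rates$r_t12, r_t21 = rates$r_t21, r_t23 = rates$r_t23,
    r_t32 = rates$r_t32, r_t31 = rates$r_t31, r_t13 = rates$r_t13,
    coop_r_t12 = rates$coop_r_t12, coop_r_t23 = rates$coop_r_t23,
    coop_enabled = coop$enabled,
    src_tf3 = "TF3" %in% coop$sources,
    src_xb2 = "XB2" %in% coop$sources,
    src_xb3 = "XB3" %in% coop$sources,
    tgt_rt12 = "rt12" %in% coop$targets,
    tgt_rt23 = "rt23" %in% coop$targets,
    deact_mode = match(deactivation, c("free", "block", "release")) - 1L,
    xb_binding = xb_binding,
    k_xb = energetics$k_xb, kT = energetics$kT, phi = energetics$phi,
    w2 = energetics$w2, w3 = energetics$w3, x_ps = energetics$x_ps,
    f1 = energetics$f1, h23 = energetics$h23, d31 = energetics$d31,
    d31_strain = energetics$d31_strain, rate_cap = energetics$rate_cap
  )
  n_steps <- as.integer(round(duration / dt))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- cpp_simulate(geom, kin, list(n_steps = n_steps,
                                      n_substeps = as.integer(n_substeps)))
  tr <- res$trace
  colnames(tr) <- c("t", "force", "force_m", "frac_avail",
                    "tf1", "tf2", "tf3", "xb1", "xb2", "xb3",
                    "n_bound", "atp", "forced_thin", "substeps")
  out <- tibble::as_tibble(as.data.frame(tr))
  structure(out,
            class = c("sim_trace", class(out)),
            config = list(pCa = pCa, duration = duration, dt = dt,
                          rho_tn = rho_tn,
                          ru_span = lattice$layout$ru_span,
                          rates = unclass(rates), coop = unclass(coop),
                          energetics = unclass(energetics),
                          scalers = unclass(scalers),
                          xb_binding = xb_binding,
                          deactivation = deactivation),
            seed = seed,
            n_myosins = lattice$params$n_myosins,
            lattice = lattice,
            final_state = res[c("ru_states", "xb_states", "xb_partner", "u",
                                "atp_total", "force_z", "force_m")])
}

#' @export
print.sim_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<sim_trace> pCa %.2f, %d steps of %g ms, seed %d\n",
              cfg$pCa, nrow(x) - 1L, cfg$dt * 1e3, attr(x, "seed")))
  ss <- steady_state(x)
  cat(sprintf("  steady state: force %.1f pN, fraction available %.3f, ATPase %.2f /myosin/s\n",
              ss$force, ss$frac_avail, atpase_rate(x)$atpase))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy sim_trace
#' @export
tidy.sim_trace <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @importFrom generics glance
#' @method glance sim_trace
#' @export
glance.sim_trace <- function(x, ...) {
  ss <- steady_state(x)
  rts <- rate_constants(x)
  tibble::tibble(
    pCa = attr(x, "config")$pCa,
    force = ss$force, frac_avail = ss$frac_avail,
    n_bound = ss$n_bound,
    atpase = atpase_rate(x)$atpase,
    k_dev = rts$rate[rts$quantity == "force"],
    k_tf_act = rts$rate[rts$quantity == "frac_avail"],
    stationary = ss$stationary
  )
}

#' @method autoplot sim_trace
#' @export
autoplot.sim_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tidy(object), "t", "force", "frac_avail"),
    -"t", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

derive_seed <- function(base_seed, i, r) {
  as.integer((as.numeric(base_seed) + 1000003 * i + 7919 * r) %% 2147483647)
}

#' Run replicate simulations over a pCa grid
#'
#' Runs `n_reps` independent simulations at each pCa value, with the seed
#' of each grid cell derived deterministically from `(base_seed, pCa index,
#' replicate index)`, and summarises steady-state force, fraction of
#' available actin nodes, ATPase, and the half-time rate constants of force
#' development (`k_dev`) and thin-filament activation (`k_tf_act`).
#'
#' @param pCa Numeric vector of pCa values.
#' @param n_reps Replicates per pCa (>= 1).
#' @param base_seed Integer base seed for the deterministic seed grid.
#' @param keep_traces Keep the individual `sim_trace` objects (memory).
#' @inheritParams run_simulation
#' @param ... Further arguments passed to [run_simulation()].
#' @return A `sim_replicates` list: `results` (one row per run), `summary`
#'   (per-pCa mean and standard error; SE is `NA` when `n_reps = 1`),
#'   `traces` (optional), and the call configuration.
#' @export
run_replicates <- function(pCa, n_reps = 4, base_seed = 1, duration = 2,
                           keep_traces = FALSE, ...) {
  stopifnot(n_reps >= 1)
  grid <- tidyr::expand_grid(i_pca = seq_along(pCa), rep = seq_len(n_reps))
  traces <- purrr::pmap(grid, function(i_pca, rep) {
    run_simulation(pCa = pCa[i_pca], duration = duration,
                   seed = derive_seed(base_seed, i_pca, rep), ...)
  })
  results <- purrr::map2_dfr(traces, seq_len(nrow(grid)), function(tr, k) {
    dplyr::bind_cols(tibble::tibble(pCa = pCa[grid$i_pca[k]],
                                    rep = grid$rep[k],
                                    seed = attr(tr, "seed")),
                     dplyr::select(glance(tr), -"pCa"))
  })
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  summary <- results |>
    dplyr::group_by(.data$pCa) |>
    dplyr::summarise(dplyr::across(c("force", "frac_avail", "atpase",
                                     "k_dev", "k_tf_act"),
                                   list(mean = ~ mean(.x, na.rm = TRUE),
                                        se = se)),
                     n = dplyr::n(), .groups = "drop")
  structure(list(results = results, summary = summary,
                 traces = if (keep_traces) traces else NULL,
                 pCa = pCa, n_reps = n_reps, base_seed = base_seed),
            class = "sim_replicates")
}

#' @export
print.sim_replicates <- function(x, ...) {
  cat(sprintf("<sim_replicates> %d pCa values x %d replicates (base seed %d)\n",
              length(x$pCa), x$n_reps, x$base_seed))
  print(x$summary)
  invisible(x)
}

#' @method tidy sim_replicates
#' @export
tidy.sim_replicates <- function(x, ...) x$results

#' @method glance sim_replicates
#' @export
glance.sim_replicates <- function(x, ...) x$summary

#' @method autoplot sim_replicates
#' @export
autoplot.sim_replicates <- function(object, quantity = "force", ...) {
  s <- object$summary
  m <- s[[paste0(quantity, "_mean")]]
  e <- s[[paste0(quantity, "_se")]]
  ggplot2::ggplot(s, ggplot2::aes(.data$pCa, m)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = m - e, ymax = m + e)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "pCa", y = quantity)
}
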