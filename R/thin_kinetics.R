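#' Thin-filament transition rate table
#'
#' Rates of the three-state regulatory-unit cycle TF1 (no Ca bound) <->
#' TF2 (Ca bound) <-> TF3 (tropomyosin moved, myosin-permissive), plus the
#' TF3 -> TF1 / TF1 -> TF3 loop closure. Second-order rates (`r_t12`,
#' `r_t13`, units 1/M/s) are multiplied by `[Ca2+]` at evaluation time.
#'
#' The cooperative forward rates are the basic rates scaled by `psi`
#' (`coop_r_t12 = psi * r_t12`, `coop_r_t23 = psi * r_t23`); reverse rates
#' are independent of `psi`. `xi` rescales the Ca-binding equilibrium
#' `K1' = r_t12 / r_t21` (by dividing the second-order on-rates) so that the
#' effective Ca affinity during a cooperative simulation, approximately
#' `K1' * psi`, stays near the physiological range. The defaults
#' (`psi = 100`, `xi = 100`) give `r_t12 = r_t13 = 5e4 /M/s`.
#'
#' The one-way equilibrium constants around the loop TF1->TF2->TF3->TF1 are
#' reported (`loop_product`); their product differs from 1 for the default
#' rates, which is flagged by [print()] but deliberately not "fixed": the
#' rate values are used verbatim.
#'
#' @param psi Cooperative rate amplification factor (dimensionless).
#' @param xi Rescale of the Ca-binding equilibrium (dimensionless).
#' @param r_t21,r_t23,r_t32,r_t31 First-order rates (1/s).
#' @param r_t12,r_t13 Second-order on-rates (1/M/s); defaults `5e6 / xi`.
#' @return A `thin_rate_table` object (list of rates and derived
#'   equilibrium constants).
#' @export
thin_rate_table <- function(psi = 100, xi = 100,
                            r_t12 = 5e6 / xi, r_t21 = 50,
                            r_t23 = 10, r_t32 = 10,
                            r_t31 = 5, r_t13 = 5e6 / xi) {
  stopifnot(psi > 0, xi > 0, r_t12 > 0, r_t21 > 0, r_t23 > 0, r_t32 > 0,
            r_t31 > 0, r_t13 > 0)
  out <- list(
    r_t12 = r_t12, r_t21 = r_t21, r_t23 = r_t23, r_t32 = r_t32,
    r_t31 = r_t31, r_t13 = r_t13,
    coop_r_t12 = psi * r_t12, coop_r_t23 = psi * r_t23,
    psi = psi, xi = xi,
    K1_prime = r_t12 / r_t21,
    K2 = r_t23 / r_t32,
    K3_prime = r_t31 / r_t13,
    effective_K1 = psi * r_t12 / r_t21
  )
  out$loop_product <- out$K1_prime * out$K2 * out$K3_prime
  class(out) <- "thin_rate_table"
  out
}

#' @export
print.thin_rate_table <- function(x, ...) {
  cat("<thin_rate_table>\n")
  cat(sprintf("  r_t12 = %g /M/s (coop %g), r_t21 = %g /s\n",
              x$r_t12, x$coop_r_t12, x$r_t21))
  cat(sprintf("  r_t23 = %g /s (coop %g), r_t32 = %g /s\n",
              x$r_t23, x$coop_r_t23, x$r_t32))
  cat(sprintf("  r_t31 = %g /s, r_t13 = %g /M/s\n", x$r_t31, x$r_t13))
  cat(sprintf("  psi = %g, xi = %g; K1' = %g /M, K2 = %g, K3' = %g M\n",
              x$psi, x$xi, x$K1_prime, x$K2, x$K3_prime))
  cat(sprintf("  effective cooperative Ca affinity K1'*psi = %g /M\n",
              x$effective_K1))
  if (abs(x$loop_product * 1 - 1) > 1e-9) {
    cat(sprintf("  note: loop product K1'*K2*K3' = %g M^0 (not unity; rates used verbatim)\n",
                x$loop_product))
  }
  invisible(x)
}

#' Cooperative pathway configuration
#'
#' Selects which neighbouring-state conditions act as sources of kinetic
#' cooperativity and which thin-filament forward rates they target. Sources:
#' `"TF3"` (an adjacent regulatory unit on the same helix is activated;
#' RU-RU cooperativity), `"XB2"`/`"XB3"` (a cross-bridge in the pre-/
#' post-power-stroke state is attached within an adjacent unit's influence
#' region; XB-RU cooperativity). Targets: `"rt12"` (Ca binding) and/or
#' `"rt23"` (tropomyosin movement). When any configured source condition
#' holds, the targeted rate takes its psi-scaled cooperative value; the
#' scaled value is identical however many source conditions hold at once.
#' Pathway strings of the form `"TF3-RU"`, `"XB2-RU"`, `"XB3-RU"` are also
#' accepted as sources.
#'
#' @param sources Character subset of `c("TF3", "XB2", "XB3")` (or
#'   `"*-RU"` pathway spellings). Empty means no cooperativity.
#' @param targets Character subset of `c("rt12", "rt23")`.
#' @param enabled Master switch; `FALSE` gives basic kinetics everywhere.
#' @export
coop_config <- function(sources = c("TF3", "XB2", "XB3"),
                        targets = c("rt12", "rt23"),
                        enabled = TRUE) {
  sources <- toupper(sub("-RU$", "", sources, ignore.case = TRUE))
  stopifnot(all(sources %in% c("TF3", "XB2", "XB3")),
            all(targets %in% c("rt12", "rt23")))
  structure(list(sources = unique(sources), targets = unique(targets),
                 enabled = isTRUE(enabled) && length(sources) > 0 && length(targets) > 0),
            class = "coop_config")
}

#' @export
print.coop_config <- function(x, ...) {
  if (!x$enabled) cat("<coop_config> disabled (basic kinetics)\n")
  else cat("<coop_config> sources:", paste(x$sources, collapse = ", "),
           "-> targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

#' Cooperative neighbour context of a regulatory unit
#'
#' Reports, for each configured cooperativity source, whether its condition
#' holds in either adjacent regulatory unit along the same helix: `TF3` - a
#' flanking troponin is in the activated state; `XB2`/`XB3` - a cross-bridge
#' in that state is attached to an actin node within a flanking troponin's
#' influence set. Knocked-out neighbours are frozen in TF1 (so never satisfy
#' the TF3 condition) but their influence region is still inspected for
#' bound cross-bridges.
#'
#' @param lattice A `lattice_geometry` with troponins assigned and the
#'   influence map built.
#' @param ru Troponin id (must be a functional site).
#' @param ru_states Integer vector of regulatory states (1, 2, 3) per
#'   troponin site.
#' @param xb_states Integer vector of cross-bridge states (1, 2, 3) per
#'   myosin.
#' @param xb_partner Integer vector: global actin node bound by each
#'   myosin (`NA` if unbound).
#' @param coop A [coop_config()].
#' @return Named logical vector over the configured sources.
#' @export
neighbor_context <- function(lattice, ru, ru_states, xb_states, xb_partner,
                             coop = coop_config()) {
  tr <- lattice$troponins
  stopifnot(isTRUE(tr$functional[ru]))
  if (!coop$enabled) return(stats::setNames(logical(0), character(0)))
  neigh <- c(tr$prev[ru], tr$nxt[ru])
  neigh <- neigh[!is.na(neigh)]
  out <- stats::setNames(rep(FALSE, length(coop$sources)), coop$sources)
  if ("TF3" %in% coop$sources) {
    out["TF3"] <- any(ru_states[neigh] == 3L & tr$functional[neigh])
  }
  if (any(c("XB2", "XB3") %in% coop$sources) && length(neigh) > 0) {
    infl <- unique(unlist(tr$influence[neigh]))
    bound <- !is.na(xb_partner) & xb_partner %in% infl
    if ("XB2" %in% coop$sources) out["XB2"] <- any(bound & xb_states == 2L)
    if ("XB3" %in% coop$sources) out["XB3"] <- any(bound & xb_states == 3L)
  }
  out
}

#' Effective thin-filament transition rates
#'
#' Returns the six pseudo-first-order rates out of the three regulatory
#' states at a given `[Ca2+]`, substituting the cooperative (psi-scaled)
#' value for a targeted rate when any configured source condition is true in
#' `context`. Non-targeted rates and all reverse rates always keep their
#' basic values; second-order rates are multiplied by `[Ca2+]`.
#'
#' @param Ca Free calcium concentration (M), `> 0`.
#' @param context Named logical vector from [neighbor_context()] (or any
#'   logical vector; `any(context)` triggers the substitution).
#' @param table A [thin_rate_table()].
#' @param coop A [coop_config()].
#' @return Named numeric vector `c(r12, r21, r23, r32, r31, r13)` in 1/s.
#' @export
effective_rates <- function(Ca, context, table, coop = coop_config()) {
  stopifnot(Ca > 0)
  hot <- coop$enabled && length(context) > 0 && any(context)
  r12 <- if (hot && "rt12" %in% coop$targets) table$coop_r_t12 else table$r_t12
  r23 <- if (hot && "rt23" %in% coop$targets) table$coop_r_t23 else table$r_t23
  c(r12 = r12 * Ca, r21 = table$r_t21, r23 = r23, r32 = table$r_t32,
    r31 = table$r_t31, r13 = table$r_t13 * Ca)
}

#' Monte Carlo update of regulatory-unit states
#'
#' Advances a vector of regulatory units one time step. For each unit a
#' single uniform draw on (0,1) is partitioned among the transitions
#' available from its current state (TF1 has two exits, to TF2 and TF3; TF2
#' to TF3 and TF1; TF3 to TF2 and TF1) with probabilities `rate * dt`
#' computed from the pre-step state; updates are synchronous. If the summed
#' exit probability of a unit reaches 1 the probabilities are renormalised
#' to their ratio and a transition is forced (the count of such forced
#' resolutions is returned as an attribute), preserving the "transition
#' occurs if p >= 1" semantics.
#'
#' @param states Integer vector of current states (1, 2, 3).
#' @param rates Matrix with one row per unit and columns
#'   `r12, r21, r23, r32, r31, r13` (pseudo-first-order, 1/s), e.g. built
#'   with [effective_rates()].
#' @param dt Time step (s).
#' @return Integer vector of updated states, with attribute `forced` (count
#'   of forced transitions).
#' @export
step_thin <- function(states, rates, dt) {
  stopifnot(dt > 0, is.matrix(rates), nrow(rates) == length(states),
            ncol(rates) == 6)
  n <- length(states)
  # exits (a, b) per current state
  pa <- numeric(n); pb <- numeric(n)
  ta <- integer(n); tb <- integer(n)
  s1 <- states == 1L; s2 <- states == 2L; s3 <- states == 3L
  pa[s1] <- rates[s1, 1] * dt; ta[s1] <- 2L   # TF1 -> TF2
  pb[s1] <- rates[s1, 6] * dt; tb[s1] <- 3L   # TF1 -> TF3
  pa[s2] <- rates[s2, 3] * dt; ta[s2] <- 3L   # TF2 -> TF3
  pb[s2] <- rates[s2, 2] * dt; tb[s2] <- 1L   # TF2 -> TF1
  pa[s3] <- rates[s3, 4] * dt; ta[s3] <- 2L   # TF3 -> TF2
  pb[s3] <- rates[s3, 5] * dt; tb[s3] <- 1L   # TF3 -> TF1
  tot <- pa + pb
  forced <- tot >= 1 & tot > 0
  scale <- ifelse(forced, 1 / tot, 1)
  pa <- pa * scale; pb <- pb * scale
  n_draw <- stats::runif(n)
  new <- states
  hit_a <- n_draw < pa
  hit_b <- !hit_a & n_draw < pa + pb
  new[hit_a] <- ta[hit_a]
  new[hit_b] <- tb[hit_b]
  attr(new, "forced") <- sum(forced)
  new
}

#' Myosin availability of actin nodes
#'
#' A thin-filament node is available for myosin binding if and only if the
#' most activated of its governing troponins (TF3 > TF2 > TF1) is in the
#' tropomyosin-moved state TF3. Knocked-out troponins are frozen in TF1;
#' nodes with no functional governor are never available.
#'
#' @param lattice A `lattice_geometry` with the influence map built.
#' @param ru_states Integer vector of regulatory states per troponin site.
#' @return Tibble with `node` (global thin node id) and logical `available`.
#' @export
node_availability <- function(lattice, ru_states) {
  tr <- lattice$troponins
  stopifnot(!is.null(tr$influence), !is.null(tr$functional),
            length(ru_states) == nrow(tr))
  active <- tr$functional & ru_states == 3L
  avail_nodes <- unique(unlist(tr$influence[active]))
  thin_nodes <- lattice$nodes$node[lattice$nodes$kind == "thin"]
  tibble::tibble(node = thin_nodes, available = thin_nodes %in% avail_nodes)
}
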