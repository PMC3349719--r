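#' Stiffness scaling factors
#'
#' Multiplicative scalers applied to the filament element spring constants,
#' plus the cross-bridge spring constant. `k_fil_scale` scales thick and
#' thin elements simultaneously (the "k_fil = 0.1X" style of condition);
#' `k_m_scale` and `k_a_scale` scale them independently.
#'
#' @param k_m_scale,k_a_scale,k_fil_scale Dimensionless multipliers on the
#'   base element stiffnesses.
#' @param k_xb Cross-bridge spring constant (pN/nm), default 3.
#' @export
stiffness_scalers <- function(k_m_scale = 1, k_a_scale = 1, k_fil_scale = 1,
                              k_xb = 3) {
  stopifnot(k_m_scale > 0, k_a_scale > 0, k_fil_scale > 0, k_xb > 0)
  structure(list(k_m_scale = k_m_scale, k_a_scale = k_a_scale,
                 k_fil_scale = k_fil_scale, k_xb = k_xb),
            class = "stiffness_scalers")
}

element_stiffness <- function(lattice, scalers) {
  el <- lattice$elements
  sc <- ifelse(el$kind == "thick",
               scalers$k_m_scale * scalers$k_fil_scale,
               scalers$k_a_scale * scalers$k_fil_scale)
  el$k * sc
}

#' Assemble the instantaneous force-balance system
#'
#' Builds the symmetric sparse stiffness matrix `K` and boundary vector `V`
#' of the 1-D force balance `K u = V` over all filament nodes, where `u` is
#' the vector of node displacements from their unstrained rest positions.
#' `K` holds the filament element springs (scaled by the stiffness scalers)
#' plus one `k_xb` spring for every attached cross-bridge, coupling its
#' myosin node to its actin partner node. `V` carries the pre-strain of the
#' attached cross-bridge springs; the fixed M-line (thick) and Z-line
#' (thin) anchors enter through the anchor elements under isometric
#' conditions. With no attachments `V = 0` and the solution is the rest
#' configuration.
#'
#' @param lattice A `lattice_geometry`.
#' @param attachments Data frame of attached cross-bridges with columns
#'   `myosin_node`, `actin_node` (global node ids) and `rest_offset` (nm),
#'   the spring rest value of the axial offset `p_m - p_a` (0 for a
#'   pre-stroke bridge, the power-stroke distance for a post-stroke one).
#'   `NULL` or zero rows means no attached cross-bridges.
#' @param scalers A [stiffness_scalers()] object.
#' @return A `stiffness_system` list: `K` (sparse symmetric), `V`,
#'   `attachments`, `scalers` and the lattice reference.
#' @export
assemble_system <- function(lattice, attachments = NULL,
                            scalers = stiffness_scalers()) {
  stopifnot(inherits(lattice, "lattice_geometry"))
  n <- nrow(lattice$nodes)
  el <- lattice$elements
  k_el <- element_stiffness(lattice, scalers)

  if (is.null(attachments)) {
    attachments <- tibble::tibble(myosin_node = integer(), actin_node = integer(),
                                  rest_offset = numeric())
  }
  attachments <- tibble::as_tibble(attachments)
  if (nrow(attachments) > 0) {
    if (anyDuplicated(attachments$actin_node)) {
      stop("invalid state: more than one cross-bridge attached to a single actin node",
           call. = FALSE)
    }
    kinds <- lattice$nodes$kind
    if (any(kinds[attachments$myosin_node] != "thick") ||
        any(kinds[attachments$actin_node] != "thin")) {
      stop("attachments must link a thick-filament (myosin) node to a thin-filament (actin) node",
           call. = FALSE)
    }
  }

  # element springs
  ii <- jj <- xx <- list()
  wall <- el$node_a == 0L
  # anchor springs: diagonal only
  ii[[1]] <- el$node_b[wall]; jj[[1]] <- el$node_b[wall]; xx[[1]] <- k_el[wall]
  a <- el$node_a[!wall]; b <- el$node_b[!wall]; k <- k_el[!wall]
  ii[[2]] <- c(a, b, a, b); jj[[2]] <- c(a, b, b, a); xx[[2]] <- c(k, k, -k, -k)

  V <- numeric(n)
  if (nrow(attachments) > 0) {
    m <- attachments$myosin_node; ac <- attachments$actin_node
    kxb <- scalers$k_xb
    ii[[3]] <- c(m, ac, m, ac); jj[[3]] <- c(m, ac, ac, m)
    xx[[3]] <- rep(c(kxb, kxb, -kxb, -kxb), each = length(m))
    # pre-strain c = (rest offset between the nodes) - (spring rest offset)
    y0 <- lattice$nodes$position[m] - lattice$nodes$position[ac]
    cc <- y0 - attachments$rest_offset
    # accumulate (a myosin node can host several attached heads)
    agg <- rowsum(c(-kxb * cc, kxb * cc), group = c(m, ac))
    V[as.integer(rownames(agg))] <- agg[, 1]
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n), symmetric = FALSE)
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)

  structure(list(K = K, V = V, lattice = lattice, attachments = attachments,
                 scalers = scalers),
            class = "stiffness_system")
}

#' Solve node positions from the force balance
#'
#' Solves `K u = V` by sparse Cholesky factorisation (the system is
#' symmetric positive definite whenever every connected component has a
#' boundary anchor), then reports absolute node positions, the boundary
#' force and the distortion of every attached cross-bridge. Inertial and
#' viscous terms are absent: the balance is instantaneous.
#'
#' The boundary force is the summed tension of the thin-filament Z-line
#' anchor elements; by global statics it equals the summed M-line anchor
#' tension of the thick filaments (both are returned). Distortion `x` of an
#' attached cross-bridge is the axial offset `p_m - p_a` of its myosin node
#' relative to its actin partner (positive = myosin displaced toward the
#' Z-line), the coordinate on which the strain-dependent rates depend.
#'
#' @param system A `stiffness_system` from [assemble_system()].
#' @param tol Relative residual tolerance for the solve (default `1e-8`).
#' @return List with `positions` (tibble: node, rest, displacement,
#'   position), `boundary_force` (pN, Z-line readout), `boundary_force_m`
#'   (M-line readout), and `distortions` (tibble per attachment).
#' @export
solve_positions <- function(system, tol = 1e-8) {
  stopifnot(inherits(system, "stiffness_system"))
  K <- system$K; V <- system$V
  lat <- system$lattice
  u <- tryCatch(as.numeric(Matrix::solve(K, V)),
                error = function(e) stop("singular or indefinite stiffness matrix: ",
                                         conditionMessage(e), call. = FALSE))
  res <- max(abs(as.numeric(K %*% u) - V))
  scale <- max(abs(V), 1)
  if (res > tol * scale) {
    stop(sprintf("force-balance residual %.3g exceeds tolerance", res), call. = FALSE)
  }
  nodes <- lat$nodes
  k_el <- element_stiffness(lat, system$scalers)
  anchors <- lat$elements$role == "anchor"
  anchor_el <- lat$elements[anchors, ]
  anchor_k <- k_el[anchors]
  thin_a <- anchor_el$kind == "thin"
  # Z-line anchors stretch when their end node moves toward the M-line
  f_z <- sum(anchor_k[thin_a] * (-u[anchor_el$node_b[thin_a]]))
  f_m <- sum(anchor_k[!thin_a] * u[anchor_el$node_b[!thin_a]])

  att <- system$attachments
  distortions <- tibble::tibble(
    myosin_node = att$myosin_node,
    actin_node = att$actin_node,
    x = (nodes$position[att$myosin_node] + u[att$myosin_node]) -
      (nodes$position[att$actin_node] + u[att$actin_node]),
    rest_offset = att$rest_offset
  )
  distortions$force <- system$scalers$k_xb * (distortions$x - distortions$rest_offset)

  list(
    positions = tibble::tibble(node = nodes$node, rest = nodes$position,
                               displacement = u, position = nodes$position + u),
    boundary_force = f_z,
    boundary_force_m = f_m,
    distortions = distortions
  )
}
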