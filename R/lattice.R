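#' Build the half-sarcomere filament lattice
#'
#' Constructs the static geometry of a half-sarcomere: thick and thin
#' filaments discretised into chains of linear spring elements, the
#' myosin-to-actin pairing map, and troponin placement along the two helices
#' of every thin filament.
#'
#' The default geometry is 4 thick filaments (60 nodes each, 14.3 nm element
#' rest length, span ~858 nm) and 8 thin filaments (90 nodes each, 12.3 nm
#' rest length, span ~1107 nm), giving the physiological 2:1 thin:thick
#' count ratio. Each thick filament carries 6 myosins per ~43 nm (3-node)
#' repeat, two per node, directed toward its six neighbouring thin filaments
#' under toroidal (wrap-around) neighbour relations so every filament has
#' full coordination. Thin-filament nodes are grouped into 3-node (~37 nm)
#' co-linear runs that alternate between the two actin helices; each repeat
#' carries one troponin site per helix, anchored at the repeat's centre node,
#' i.e. 60 troponin sites per thin filament.
#'
#' Thick filaments are anchored at the M-line, thin filaments at the Z-line;
#' mechanics are axial (1-D) and isometric. The element counts reported in
#' `params` (61/91 per thick/thin filament) include the free-tip stub
#' element, which carries no load; each filament has `nodes` mechanically
#' active springs (anchor element plus internal elements).
#'
#' @param n_thick,n_thin Number of thick and thin filaments.
#' @param nodes_per_thick,nodes_per_thin Nodes per filament.
#' @param rest_len_thick,rest_len_thin Element rest lengths (nm).
#' @param k_m,k_a Element spring constants (pN/nm) for thick and thin
#'   filaments at 1X scaling.
#' @param hs_length Half-sarcomere length, M-line to Z-line (nm). Sets the
#'   axial register between the two filament families.
#' @param reach Maximum axial offset (nm) between a myosin node and a
#'   candidate actin binding node in the pairing map.
#' @return A `lattice_geometry` object: a list with `params`, and tibbles
#'   `nodes`, `elements`, `myosins` (with list-column `candidates`) and
#'   `troponins`.
#' @examples
#' lat <- build_lattice()
#' lat$params$span_thick
#' @export
build_lattice <- function(n_thick = 4, n_thin = 8,
                          nodes_per_thick = 60, nodes_per_thin = 90,
                          rest_len_thick = 14.3, rest_len_thin = 12.3,
                          k_m = 6060, k_a = 5230,
                          hs_length = 1150, reach = 8) {
  stopifnot(n_thick >= 1, n_thin >= 1, nodes_per_thick >= 3, nodes_per_thin >= 3,
            rest_len_thick > 0, rest_len_thin > 0, k_m > 0, k_a > 0, reach > 0)

  n_fil <- n_thick + n_thin
  # node table: thick filaments first (indexed from the M-line), then thin
  # filaments (indexed from the Z-line), filament-major so nodes of one
  # filament are contiguous in global numbering.
  thick_nodes <- tidyr::expand_grid(filament = seq_len(n_thick),
                                    index = seq_len(nodes_per_thick)) |>
    dplyr::mutate(kind = "thick",
                  position = .data$index * rest_len_thick,
                  helix = NA_character_)
  thin_nodes <- tidyr::expand_grid(filament = n_thick + seq_len(n_thin),
                                   index = seq_len(nodes_per_thin)) |>
    dplyr::mutate(kind = "thin",
                  position = hs_length - .data$index * rest_len_thin,
                  run = ceiling(.data$index / 3),
                  helix = ifelse(.data$run %% 2 == 1, "A", "B")) |>
    dplyr::select(-"run")
  nodes <- dplyr::bind_rows(thick_nodes, thin_nodes) |>
    dplyr::mutate(node = dplyr::row_number(), .before = 1)

  # spring elements: one anchor element per filament (node 0 denotes the
  # fixed wall: M-line for thick, Z-line for thin) plus internal elements.
  elements <- purrr::map_dfr(seq_len(n_fil), function(f) {
    fn <- nodes[nodes$filament == f, ]
    k_el <- if (fn$kind[1] == "thick") k_m else k_a
    tibble::tibble(
      filament = f,
      kind = fn$kind[1],
      node_a = c(0L, fn$node[-nrow(fn)]),
      node_b = fn$node,
      k = k_el,
      role = c("anchor", rep("internal", nrow(fn) - 1L))
    )
  }) |>
    dplyr::mutate(element = dplyr::row_number(), .before = 1)

  # toroidal facing map: thick filament t faces six thin filaments
  facing <- lapply(seq_len(n_thick), function(t) {
    n_thick + ((2L * (t - 1L) + 0:5) %% n_thin) + 1L
  })

  # myosins: 2 per thick node; node c of each 3-node repeat hosts the heads
  # directed toward facing neighbours 2c+1 and 2c+2.
  myo <- thick_nodes_tbl <- nodes[nodes$kind == "thick", ]
  myosins <- purrr::map_dfr(seq_len(nrow(myo)), function(i) {
    nd <- myo[i, ]
    c_col <- (nd$index - 1L) %% 3L
    neigh <- facing[[nd$filament]][c(2L * c_col + 1L, 2L * c_col + 2L)]
    tibble::tibble(node = nd$node, thick_filament = nd$filament,
                   position = nd$position, facing_thin = neigh)
  }) |>
    dplyr::mutate(myosin = dplyr::row_number(), .before = 1)

  # candidate actin nodes within axial reach on the facing thin filament
  thin_tbl <- nodes[nodes$kind == "thin", ]
  cand <- purrr::map2(myosins$position, myosins$facing_thin, function(p, f) {
    tn <- thin_tbl[thin_tbl$filament == f, ]
    off <- p - tn$position
    keep <- abs(off) <= reach
    tn$node[keep][order(abs(off[keep]))]
  })
  myosins$candidates <- cand
  if (all(lengths(cand) == 0L)) {
    stop("pairing map is empty: no actin node lies within reach of any myosin; ",
         "check hs_length/reach/filament counts", call. = FALSE)
  }

  # troponins: one per helix per 3-node repeat, anchored at the centre node
  troponins <- purrr::map_dfr(n_thick + seq_len(n_thin), function(f) {
    tn <- thin_tbl[thin_tbl$filament == f, ]
    n_rep <- floor(nrow(tn) / 3)
    tidyr::expand_grid(repeat_id = seq_len(n_rep), helix = c("A", "B")) |>
      dplyr::mutate(thin_filament = f,
                    anchor_index = 3L * .data$repeat_id - 1L,
                    anchor = tn$node[.data$anchor_index])
  }) |>
    dplyr::arrange(.data$thin_filament, .data$helix, .data$repeat_id) |>
    dplyr::mutate(troponin = dplyr::row_number(), .before = 1)

  # same-helix neighbour topology (adjacent ~37 nm repeats along one helix)
  troponins <- troponins |>
    dplyr::group_by(.data$thin_filament, .data$helix) |>
    dplyr::mutate(prev = dplyr::lag(.data$troponin),
                  nxt = dplyr::lead(.data$troponin)) |>
    dplyr::ungroup()

  out <- list(
    params = list(
      n_thick = n_thick, n_thin = n_thin,
      nodes_per_thick = nodes_per_thick, nodes_per_thin = nodes_per_thin,
      elements_per_thick = nodes_per_thick + 1L,
      elements_per_thin = nodes_per_thin + 1L,
      rest_len_thick = rest_len_thick, rest_len_thin = rest_len_thin,
      base_k_m = k_m, base_k_a = k_a,
      hs_length = hs_length, reach = reach,
      span_thick = nodes_per_thick * rest_len_thick,
      span_thin = nodes_per_thin * rest_len_thin,
      n_myosins = nrow(myosins),
      n_troponins = nrow(troponins),
      troponins_per_thin = nrow(troponins) / n_thin
    ),
    nodes = nodes,
    elements = elements,
    myosins = myosins,
    troponins = troponins
  )
  class(out) <- "lattice_geometry"
  out
}

#' @export
print.lattice_geometry <- function(x, ...) {
  p <- x$params
  cat("<lattice_geometry>\n")
  cat(sprintf("  %d thick filaments (%d nodes, span %.1f nm), %d thin filaments (%d nodes, span %.1f nm)\n",
              p$n_thick, p$nodes_per_thick, p$span_thick,
              p$n_thin, p$nodes_per_thin, p$span_thin))
  cat(sprintf("  %d myosins, %d troponin sites (%g per thin filament)\n",
              p$n_myosins, p$n_troponins, p$troponins_per_thin))
  if (!is.null(x$layout)) {
    cat(sprintf("  layout: rho_Tn = %g (%d functional), RU_span = %s actins\n",
                x$layout$rho_tn, sum(x$troponins$functional),
                ifelse(is.null(x$layout$ru_span), "<unset>", x$layout$ru_span)))
  }
  invisible(x)
}

#' Randomly knock out troponin complexes
#'
#' Marks each troponin site as functional with independent probability
#' `rho_tn` (the functional troponin density). Knocked-out troponins are
#' frozen in the Ca-free state and never activate their actin nodes, which
#' emulates titration of Ca-binding-competent troponin along thin filaments.
#'
#' The knockout is drawn once per troponin complex anchor (a ~37-nm repeat
#' of the thin filament) and applied to both helices' sites at that anchor,
#' so each actin node's governance scales linearly with `rho_tn` when the
#' activation span is one structural regulatory unit. Marginally every
#' troponin site is functional with probability `rho_tn`.
#'
#' @param lattice A `lattice_geometry`.
#' @param rho_tn Fraction of functional troponin sites, in `[0, 1]`.
#' @param seed Optional integer seed for the knockout draw (reproducible).
#' @return The lattice with a logical `functional` column on `$troponins`
#'   and a `$layout` record.
#' @export
assign_troponin <- function(lattice, rho_tn = 1, seed = NULL) {
  stopifnot(inherits(lattice, "lattice_geometry"), rho_tn >= 0, rho_tn <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  tr <- lattice$troponins
  n <- nrow(tr)
  complex_id <- match(paste(tr$thin_filament, tr$repeat_id),
                      unique(paste(tr$thin_filament, tr$repeat_id)))
  lattice$troponins$functional <- if (rho_tn >= 1) rep(TRUE, n)
    else if (rho_tn <= 0) rep(FALSE, n)
    else (stats::runif(max(complex_id)) < rho_tn)[complex_id]
  lattice$layout <- c(lattice$layout[setdiff(names(lattice$layout), c("rho_tn", "seed"))],
                      list(rho_tn = rho_tn, seed = seed))
  lattice
}

ru_span_table <- tibble::tibble(
  actins = c(7L, 9L, 11L, 14L),
  span_nm = c(37, 50, 62, 75),
  structural_ru = c(1, 4 / 3, 5 / 3, 2)
)

#' Build the troponin-to-actin influence map
#'
#' Fills, for every troponin site, the set of actin nodes whose availability
#' it governs: a contiguous run of nodes on the troponin's thin filament
#' centred on its anchor. The regulatory-unit activation span `ru_span` is
#' given in actin monomers (7, 9, 11 or 14, corresponding to 37, 50, 62 or
#' 75 nm of thin filament) and is snapped to the 12.3-nm node grid as the
#' anchor node plus `floor((span_nm/2)/12.3)` nodes on each side. With a
#' span of 7 actins the influence sets of one helix tile the filament
#' without overlap; larger spans overlap adjacent same-helix sets, and the
#' overlap width grows with the span.
#'
#' @param lattice A `lattice_geometry` (troponins assigned or not).
#' @param ru_span Activation span in actin monomers: one of 7, 9, 11, 14.
#' @return The lattice with a list-column `influence` (global actin node
#'   ids) on `$troponins`.
#' @export
influence_map <- function(lattice, ru_span = 9) {
  stopifnot(inherits(lattice, "lattice_geometry"))
  if (!ru_span %in% ru_span_table$actins) {
    stop("ru_span must be one of ", paste(ru_span_table$actins, collapse = ", "),
         " actin monomers (the node grid supports these discrete spans)",
         call. = FALSE)
  }
  span_nm <- ru_span_table$span_nm[match(ru_span, ru_span_table$actins)]
  hw <- floor((span_nm / 2) / lattice$params$rest_len_thin)
  nodes <- lattice$nodes
  tr <- lattice$troponins
  anchor_index <- nodes$index[tr$anchor]
  npt <- lattice$params$nodes_per_thin
  first_node <- vapply(tr$thin_filament, function(f) {
    min(nodes$node[nodes$filament == f])
  }, integer(1))
  tr$influence <- purrr::map2(anchor_index, first_node, function(ai, fn) {
    idx <- max(1L, ai - hw):min(npt, ai + hw)
    as.integer(fn + idx - 1L)
  })
  lattice$troponins <- tr
  lattice$layout <- c(lattice$layout[setdiff(names(lattice$layout),
                                             c("ru_span", "ru_span_nm", "half_width"))],
                      list(ru_span = ru_span, ru_span_nm = span_nm, half_width = hw))
  lattice
}

#' Governing troponins of each actin node
#'
#' Inverts the influence map: for every thin-filament node, the troponin
#' sites whose influence set contains it. Ungoverned nodes (possible at
#' chain ends or after knockout) have empty governor sets and are never
#' available for myosin binding.
#'
#' @param lattice A `lattice_geometry` with the influence map built.
#' @return Tibble with `node` and list-column `governors` (troponin ids).
#' @export
node_governors <- function(lattice) {
  stopifnot(!is.null(lattice$troponins$influence))
  thin_nodes <- lattice$nodes$node[lattice$nodes$kind == "thin"]
  pairs <- tidyr::unnest(lattice$troponins[, c("troponin", "influence")],
                         cols = "influence")
  gov <- split(pairs$troponin, factor(pairs$influence, levels = thin_nodes))
  tibble::tibble(node = thin_nodes, governors = unname(lapply(gov, as.integer)))
}

#' Export lattice geometry for inspection
#'
#' Serialises node coordinates, the pairing map and troponin placement to a
#' JSON string (or file) for external inspection.
#'
#' @param lattice A `lattice_geometry`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
lattice_export <- function(lattice, path = NULL) {
  doc <- list(
    params = lattice$params,
    layout = lattice$layout,
    nodes = lattice$nodes,
    myosins = dplyr::mutate(lattice$myosins,
                            candidates = purrr::map(.data$candidates, as.integer)),
    troponins = lattice$troponins
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
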