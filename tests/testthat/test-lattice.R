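test_that("default lattice reproduces the half-sarcomere geometry", {
  lat <- build_lattice()
  p <- lat$params
  expect_equal(p$n_thick, 4)
  expect_equal(p$n_thin, 8)
  expect_equal(p$n_thin / p$n_thick, 2)
  expect_equal(p$span_thick, 60 * 14.3)   # ~858 nm
  expect_equal(p$span_thin, 90 * 12.3)    # ~1107 nm
  expect_equal(p$elements_per_thick, 61)
  expect_equal(p$elements_per_thin, 91)
  expect_equal(sum(lat$nodes$kind == "thick"), 4 * 60)
  expect_equal(sum(lat$nodes$kind == "thin"), 8 * 90)
})

test_that("myosin count matches the 6-per-43-nm stoichiometry", {
  lat <- build_lattice()
  # enumerate 3-node (~43 nm) repeats of the pairing map and count heads
  myo <- lat$myosins
  nodes <- lat$nodes
  repeats_per_fil <- lat$params$nodes_per_thick / 3
  counts <- table(paste(myo$thick_filament,
                        ceiling(nodes$index[myo$node] / 3)))
  expect_true(all(counts == 6))
  expect_equal(nrow(myo), lat$params$n_thick * repeats_per_fil * 6)  # 480
})

test_that("pairing map is symmetric-consistent and deterministic", {
  lat <- build_lattice()
  # an actin node lists exactly the myosins that list it (inversion check)
  pairs <- tidyr::unnest(lat$myosins[, c("myosin", "candidates")],
                         cols = "candidates")
  inv <- split(pairs$myosin, pairs$candidates)
  for (nd in sample(names(inv), 20)) {
    ms <- inv[[nd]]
    expect_true(all(vapply(ms, function(m) {
      as.integer(nd) %in% lat$myosins$candidates[[m]]
    }, logical(1))))
  }
  # candidate nodes live on the facing filament, within reach
  expect_true(all(lat$nodes$filament[pairs$candidates] ==
                  lat$myosins$facing_thin[pairs$myosin]))
  off <- abs(lat$myosins$position[pairs$myosin] -
             lat$nodes$position[pairs$candidates])
  expect_true(all(off <= lat$params$reach))
  # determinism: identical config -> identical geometry
  expect_identical(build_lattice(), lat)
})

test_that("minimal 1-thick/2-thin lattice is legal and fully paired", {
  lat <- build_lattice(n_thick = 1, n_thin = 2)
  expect_equal(lat$params$n_myosins, 120)
  # every myosin in the overlap region faces at least one actin node
  in_overlap <- lat$myosins$position >
    min(lat$nodes$position[lat$nodes$kind == "thin"])
  expect_true(all(lengths(lat$myosins$candidates[in_overlap]) >= 1))
})

test_that("troponin placement follows the helix structure", {
  lat <- build_lattice()
  tr <- lat$troponins
  expect_equal(nrow(tr), 8 * 60)        # 60 sites per thin filament
  # adjacent troponins along one helix are ~37 nm apart
  sp <- tr |>
    dplyr::mutate(pos = lat$nodes$position[.data$anchor]) |>
    dplyr::group_by(.data$thin_filament, .data$helix) |>
    dplyr::summarise(d = list(abs(diff(.data$pos))), .groups = "drop")
  expect_true(all(abs(unlist(sp$d) - 3 * 12.3) < 1e-9))
  # helix assignment of nodes alternates every 3-node (~37 nm) run
  thin1 <- lat$nodes[lat$nodes$filament == 5, ]
  runs <- split(thin1$helix, ceiling(thin1$index / 3))
  expect_true(all(vapply(runs, function(h) length(unique(h)) == 1, logical(1))))
  expect_true(all(diff(vapply(runs, function(h) h[1] == "A", logical(1))) != 0))
})

test_that("troponin knockout is Bernoulli(rho) and reproducible", {
  lat <- build_lattice()
  expect_true(all(assign_troponin(lat, 1)$troponins$functional))
  expect_false(any(assign_troponin(lat, 0)$troponins$functional))
  a <- assign_troponin(lat, 0.5, seed = 7)
  b <- assign_troponin(lat, 0.5, seed = 7)
  expect_identical(a$troponins$functional, b$troponins$functional)
  # aggregate over many draws: realized fraction within 3 SE of rho
  n_sites <- nrow(lat$troponins)
  draws <- vapply(1:40, function(s) {
    sum(assign_troponin(lat, 0.5, seed = s)$troponins$functional)
  }, numeric(1))
  expect_binomial(sum(draws), 40 * n_sites, 0.5)
})

test_that("influence map snaps spans to the node grid per the span table", {
  lat <- standard_lattice()
  expect_error(influence_map(lat, ru_span = 8), "ru_span")
  hw <- function(span) {
    l <- influence_map(lat, ru_span = span)
    l$layout$half_width
  }
  expect_equal(vapply(c(7, 9, 11, 14), hw, numeric(1)), c(1, 2, 2, 3))
})

test_that("span 7 influence sets tile each helix without overlap", {
  lat <- standard_lattice(ru_span = 7)
  tr <- lat$troponins
  for (f in unique(tr$thin_filament)[1:2]) {
    for (h in c("A", "B")) {
      sets <- tr$influence[tr$thin_filament == f & tr$helix == h]
      all_nodes <- unlist(sets)
      expect_equal(anyDuplicated(all_nodes), 0)  # pairwise disjoint
    }
  }
})

test_that("span 14 coverage matches the enumeration oracle", {
  lat <- standard_lattice(ru_span = 14)
  tr <- lat$troponins
  # oracle: enumerate per-helix coverage on one 90-node filament directly
  f <- tr$thin_filament[1]
  idx_of <- lat$nodes$index
  for (h in c("A", "B")) {
    anchors <- idx_of[tr$anchor[tr$thin_filament == f & tr$helix == h]]
    cover_oracle <- vapply(1:90, function(j) sum(abs(j - anchors) <= 3), numeric(1))
    sets <- tr$influence[tr$thin_filament == f & tr$helix == h]
    cover_impl <- tabulate(idx_of[unlist(sets)], nbins = 90)
    expect_equal(cover_impl, cover_oracle)
    # interior nodes are always covered by >= 2 same-helix troponins
    interior <- 5:86
    expect_true(all(cover_oracle[interior] >= 2))
  }
})

test_that("knockout leaves coverage only through neighbour overlap", {
  # span 7: influence sets tile, so a knocked-out complex leaves its whole
  # run ungoverned and those nodes are never available
  lat7 <- standard_lattice(ru_span = 7)
  pair <- which(lat7$troponins$thin_filament == 5 &
                lat7$troponins$repeat_id == 10)
  lat7$troponins$functional[pair] <- FALSE
  run_nodes <- sort(unique(unlist(lat7$troponins$influence[pair])))
  av <- node_availability(lat7, rep(3L, nrow(lat7$troponins)))
  expect_false(any(av$available[match(run_nodes, av$node)]))
  expect_true(all(av$available[setdiff(seq_len(nrow(av)),
                                       match(run_nodes, av$node))]))

  # span 9: overlap from surviving neighbours still covers the run's edge
  # nodes; only nodes beyond every neighbour's reach stay dark
  lat9 <- standard_lattice(ru_span = 9)
  pair9 <- which(lat9$troponins$thin_filament == 5 &
                 lat9$troponins$repeat_id == 10)
  lat9$troponins$functional[pair9] <- FALSE
  run_nodes9 <- sort(unique(unlist(lat9$troponins$influence[pair9])))
  av9 <- node_availability(lat9, rep(3L, nrow(lat9$troponins)))
  # oracle: a node stays available iff a surviving troponin's influence
  # contains it
  surv <- which(lat9$troponins$functional)
  covered <- sort(unique(unlist(lat9$troponins$influence[surv])))
  expect_equal(av9$node[av9$available], covered)
  dark <- setdiff(run_nodes9, covered)
  expect_gt(length(dark), 0)            # some loss
  expect_lt(length(dark), length(run_nodes9))  # but neighbours fill edges
})

test_that("coverage is conserved and grows monotonically with span", {
  lat <- standard_lattice()
  n_pairs <- vapply(c(7, 9, 11, 14), function(sp) {
    l <- influence_map(lat, ru_span = sp)
    # every thin node governed at rho = 1 (no governance gaps)
    gov <- node_governors(l)
    expect_true(all(lengths(gov$governors) >= 1))
    sum(lengths(l$troponins$influence))
  }, numeric(1))
  expect_true(all(diff(n_pairs) >= 0))
})

test_that("geometry export round-trips through JSON", {
  lat <- tiny_lattice()
  js <- lattice_export(lat)
  doc <- jsonlite::fromJSON(js)
  expect_equal(doc$params$n_myosins, lat$params$n_myosins)
  expect_equal(nrow(doc$nodes), nrow(lat$nodes))
})
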