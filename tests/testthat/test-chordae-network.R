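test_that("default network reproduces the declared chordae structure", {
  net <- build_network(seed = 3)
  expect_equal(sum(net$nodes$role == "pm_origin"), 17)

  # insertion counts per group and papillary muscle
  grp <- vapply(net$chords, `[[`, "", "group")
  pm <- vapply(net$chords, `[[`, "", "pm")
  n_ins <- vapply(net$chords, function(ch) length(ch$insertion_nodes), 0L)
  counts <- tapply(n_ins, list(grp, pm), sum)
  spec <- chordae_count_spec()$insertions
  expect_equal(counts[rownames(spec), colnames(spec)],
               spec, ignore_attr = TRUE)
  expect_equal(sum(counts["PML_marginal", ]), 13)
  expect_equal(sum(counts["AML_strut", ]), 7)

  # discretization contract: positive rest lengths, path cap, ~1.5 mm mean
  expect_true(all(net$segments$rest_length > 0))
  expect_true(all(net$segments$area0 > 0))
  expect_true(all(vapply(net$chords, function(ch) length(ch$segments), 0L) <= 10))
  expect_lt(abs(mean(net$segments$rest_length) - 1.5), 0.5)

  # determinism for a fixed seed
  net2 <- build_network(seed = 3)
  expect_identical(net$nodes, net2$nodes)
  expect_identical(net$segments, net2$segments)
  net3 <- build_network(seed = 4)
  expect_false(isTRUE(all.equal(net$nodes$x, net3$nodes$x)))
})

test_that("rupture scenarios remove the narrated chordae sets", {
  net <- build_network(seed = 1)
  expect_length(scenario_segments(net, "control")$removed_segments, 0)
  expect_error(scenario_segments(net, "isolated_P4"), "unknown scenario")

  seg_info <- function(ids) net$segments[net$segments$id %in% ids, ]
  iso <- scenario_segments(net, "isolated_P2")
  info <- seg_info(iso$removed_segments)
  expect_true(all(info$scallop == "P2"))
  expect_true(all(info$group %in% c("PML_marginal", "PML_intermediate")))
  # ... and it removes ALL P2 marginal/intermediate chords
  p2mi <- net$segments$id[net$segments$scallop == "P2" &
                            net$segments$group %in%
                            c("PML_marginal", "PML_intermediate")]
  expect_setequal(iso$removed_segments, p2mi)

  # monotone severity: partial within total, isolated within partial
  part <- scenario_segments(net, "partial_P2P3")$removed_segments
  tot <- scenario_segments(net, "total_P2P3")$removed_segments
  expect_true(all(iso$removed_segments %in% part))
  expect_true(all(part %in% tot))
  expect_true(any(seg_info(tot)$group == "PML_basal"))
  expect_false(any(seg_info(part)$group == "PML_basal"))

  # override is validated and taken verbatim
  ov <- scenario_segments(net, "isolated_P1", override = net$segments$id[1:3])
  expect_equal(ov$removed_segments, net$segments$id[1:3])
  expect_error(scenario_segments(net, "isolated_P1", override = "nope"),
               "unknown segments")
})

test_that("single straight chord carries exactly the applied axial pull", {
  og <- example_ogden()
  for (n_el in c(1, 2, 5)) {
    net <- make_single_chord(n_el = n_el)
    sol <- solve_static_tensions(net, NULL,
                                 load_case(insertion_loads = list(i = c(0, 0, 1))),
                                 og)
    expect_true(sol$converged)
    expect_equal(unname(sol$segment_tensions), rep(1, n_el), tolerance = 1e-7)
  }

  # mesh refinement: 1 vs 2 elements gives the same chord tension
  t1 <- solve_static_tensions(make_single_chord(n_el = 1), NULL,
                              load_case(insertion_loads = list(i = c(0, 0, 1))),
                              og)$segment_tensions[[1]]
  t2 <- solve_static_tensions(make_single_chord(n_el = 2), NULL,
                              load_case(insertion_loads = list(i = c(0, 0, 1))),
                              og)$segment_tensions[[1]]
  expect_equal(t1, t2, tolerance = 1e-6)
})

test_that("symmetric V carries F / (2 cos theta) per leg", {
  og <- example_ogden()
  for (th in c(20, 30, 45)) {
    net <- make_v_network(theta_deg = th)
    Fz <- 0.8
    sol <- solve_static_tensions(net, NULL,
                                 load_case(insertion_loads = list(apex = c(0, 0, Fz))),
                                 og)
    expect_true(sol$converged)
    # closed form holds in the deformed configuration: use the deformed
    # half-angle (small change at these loads, so compare loosely to the
    # undeformed formula too)
    pos <- sol$node_positions
    d <- pos["apex", ] - pos["o1", ]
    cos_def <- d[3] / sqrt(sum(d^2))
    expect_equal(unname(sol$segment_tensions[["s1"]]), Fz / (2 * cos_def),
                 tolerance = 1e-6)
    expect_equal(unname(sol$segment_tensions[["s1"]]),
                 Fz / (2 * cos(th * pi / 180)), tolerance = 0.1)
    expect_equal(sol$segment_tensions[["s1"]], sol$segment_tensions[["s2"]],
                 tolerance = 1e-9)
  }
})

test_that("zero load gives zero tensions and displacements", {
  og <- example_ogden()
  net <- make_v_network()
  sol <- solve_static_tensions(net, NULL,
                               load_case(insertion_loads = list(apex = c(0, 0, 0))),
                               og)
  expect_true(sol$converged)
  expect_true(all(sol$segment_tensions == 0))
  expect_true(all(sol$node_displacements == 0))
})

test_that("removing one of two parallel chords raises the survivor's tension", {
  og <- example_ogden()
  net <- make_parallel_pair()
  ld <- load_case(insertion_loads = list(i = c(0, 0, 1)))
  both <- solve_static_tensions(net, NULL, ld, og)
  one <- solve_static_tensions(net,
                               structure(list(name = "cut", removed_segments = "s2"),
                                         class = "rupture_scenario"),
                               ld, og)
  expect_equal(one$segment_tensions[["s2"]], 0)
  expect_gt(one$segment_tensions[["s1"]], both$segment_tensions[["s1"]])
  expect_equal(one$segment_tensions[["s1"]], 1, tolerance = 1e-7)
  expect_equal(both$segment_tensions[["s1"]] + both$segment_tensions[["s2"]],
               1, tolerance = 1e-7)
})

test_that("orphaned insertions are unloaded and reported slack", {
  og <- example_ogden()
  net <- make_single_chord(n_el = 2)
  sol <- solve_static_tensions(net,
                               structure(list(name = "cut",
                                              removed_segments = c("s1", "s2")),
                                         class = "rupture_scenario"),
                               load_case(insertion_loads = list(i = c(0, 0, 1))),
                               og)
  expect_true(sol$converged)
  expect_true(all(sol$segment_tensions == 0))
  expect_equal(sol$slack_chords, "c1")
})

test_that("full network equilibrium balances papillary reactions against loads", {
  og <- example_ogden()
  net <- build_network(seed = 1)
  sol <- solve_static_tensions(net, NULL, load_case(), og)
  expect_true(sol$converged)
  expect_true(all(sol$segment_tensions >= 0))

  loads <- chordaemr:::.pressure_loads(net, load_case())
  total_load <- Reduce(`+`, loads)
  reactions <- colSums(pm_reactions(net, sol))
  expect_lt(sqrt(sum((reactions - total_load)^2)) / sqrt(sum(total_load^2)),
            1e-6)

  # papillary force distribution rows sum to 100
  d <- pm_force_distribution(net, sol)
  sums <- tapply(d$percent, d$pm, sum)
  expect_true(all(abs(sums - 100) < 0.1))

  # near-linear load scaling at small strain
  small <- load_case(transmitral_pressure_mmHg = 0.05)
  base <- solve_static_tensions(net, NULL, small, og)
  for (s in c(0.5, 2)) {
    scaled <- load_case(transmitral_pressure_mmHg = 0.05 * s)
    sols <- solve_static_tensions(net, NULL, scaled, og)
    nz <- base$segment_tensions > 1e-12
    ratio <- sols$segment_tensions[nz] / base$segment_tensions[nz]
    expect_true(all(abs(ratio - s) < 0.01 * s))
  }
})

test_that("group forces aggregate origin-adjacent tension vectors", {
  og <- example_ogden()
  net <- make_v_network(theta_deg = 30)
  Fz <- 0.6
  sol <- solve_static_tensions(net, NULL,
                               load_case(insertion_loads = list(apex = c(0, 0, Fz))),
                               og)
  # single-chord group (per PM): force equals that chord's tension vector
  gf1 <- group_force(net, sol, "PML_marginal", pm = "APM")
  expect_equal(gf1$magnitude, unname(sol$segment_tensions[["s1"]]),
               tolerance = 1e-9)
  # mirrored pair: lateral components cancel; magnitude < scalar sum
  gf <- group_force(net, sol, "PML_marginal")
  expect_equal(gf$vector[1], 0, tolerance = 1e-8)
  expect_lt(gf$magnitude, sum(sol$segment_tensions) - 1e-6)
  expect_equal(gf$magnitude, Fz, tolerance = 1e-6)   # balances applied load
  expect_error(group_force(net, sol, "not_a_group"), "unknown group")

  # toy hand-summed oracle on the parallel pair
  net2 <- make_parallel_pair()
  sol2 <- solve_static_tensions(net2, NULL,
                                load_case(insertion_loads = list(i = c(0, 0, 1))),
                                og)
  gf2 <- group_force(net2, sol2, "PML_basal")
  hand <- sol2$segment_tensions[["s1"]] * c(0, 0, 1) +
    sol2$segment_tensions[["s2"]] * c(0, 0, 1)
  expect_equal(gf2$vector, hand, tolerance = 1e-9)

  expect_error(pm_force_distribution(net, structure(
    list(segment_tensions = stats::setNames(c(0, 0), c("s1", "s2")),
         node_positions = sol$node_positions, converged = TRUE),
    class = "tension_solution")), "slack")
})

test_that("scenario comparison reports zero change for control and zero tension when removed", {
  og <- example_ogden()
  net <- make_parallel_pair()
  ld <- load_case(insertion_loads = list(i = c(0, 0, 1)))
  sc <- list(structure(list(name = "control", removed_segments = character(0)),
                       class = "rupture_scenario"),
             structure(list(name = "cut", removed_segments = "s2"),
                       class = "rupture_scenario"))
  cmp <- compare_scenarios(net, sc, ld, og)
  ctrl_rows <- cmp$forces[cmp$forces$scenario == "control", ]
  expect_true(all(abs(ctrl_rows$pct_change_vs_control) < 1e-9))
  expect_equal(cmp$solutions$cut$segment_tensions[["s2"]], 0)
  expect_error(compare_scenarios(net, sc[2], ld, og), "control")
})

test_that("network JSON round-trips and tension CSV export is complete", {
  net <- build_network(seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, f)
  back <- read_network_json(f)
  expect_equal(back$nodes$id, net$nodes$id)
  expect_equal(back$segments$rest_length, net$segments$rest_length,
               tolerance = 1e-12)
  expect_equal(length(back$chords), length(net$chords))

  og <- example_ogden()
  v <- make_v_network()
  sol <- solve_static_tensions(v, NULL,
                               load_case(insertion_loads = list(apex = c(0, 0, 1))),
                               og)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tension_csv(v, sol, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 2)
  expect_equal(df$tension_N, unname(sol$segment_tensions[df$segment_id]),
               tolerance = 1e-12)
})
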