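# Idealized mitral chordae apparatus: network construction, rupture
# scenarios, and force aggregation per chordae group and papillary muscle.
#
# Coordinates are millimeters, right-handed, with the mitral annulus in the
# z = 0 plane and the ventricle at z < 0. Forces are newtons; pressures are
# converted at 1 mmHg = 133.322 Pa.

MMHG_TO_PA <- 133.322

CHORDAE_GROUPS <- c("AML_marginal", "AML_strut", "PML_marginal",
                    "PML_intermediate", "PML_basal")

#' Default chordae structure counts
#'
#' Origin and insertion counts of the reference patient-derived chordae
#' apparatus: 17 chordae origins on the two papillary muscle tips, and
#' leaflet insertion counts per chordae group and papillary muscle
#' (anterolateral APM, posteromedial PPM).
#'
#' @return List with `origins` (leaflet x PM matrix of origin counts) and
#'   `insertions` (group x PM matrix of insertion counts).
#' @export
chordae_count_spec <- function() {
  origins <- matrix(c(5, 3,
                      4, 5), nrow = 2, byrow = TRUE,
                    dimnames = list(c("AML", "PML"), c("APM", "PPM")))
  insertions <- matrix(c(8, 6,
                         3, 4,
                         7, 6,
                         7, 1,
                         5, 6), nrow = 5, byrow = TRUE,
                       dimnames = list(CHORDAE_GROUPS, c("APM", "PPM")))
  list(origins = origins, insertions = insertions)
}

#' Geometry parameters of the idealized mitral apparatus
#'
#' The generator builds a D-shaped (elliptic) annulus in the z = 0 plane,
#' leaflet insertion arcs for the anterior leaflet and the three posterior
#' scallops (P1 anterolateral, P2 central, P3 posteromedial), and two
#' papillary muscle tips below the annulus.
#'
#' @param commissural_radius Annulus semi-axis along the commissural (x)
#'   direction, mm.
#' @param ap_radius Annulus semi-axis along the anteroposterior (y)
#'   direction, mm.
#' @param pm_depth Depth of the papillary tips below the annulus, mm.
#' @param apm_xy,ppm_xy In-plane (x, y) positions of the APM and PPM tips, mm.
#' @param radial_frac Named fractions of the annulus radius at which each
#'   insertion type sits (free edge inward, basal outward).
#' @param z_insert Named heights (mm, negative = ventricular side) of each
#'   insertion type.
#' @param jitter_deg,jitter_frac,jitter_z Seeded jitter amplitudes applied to
#'   insertion angle (degrees), radial fraction and height (mm).
#' @return List of geometry parameters.
#' @export
network_geometry <- function(commissural_radius = 19, ap_radius = 15,
                             pm_depth = 14,
                             apm_xy = c(-11, -3), ppm_xy = c(9, -7),
                             radial_frac = c(marginal = 0.45,
                                             intermediate = 0.60,
                                             basal = 0.85, strut = 0.60),
                             z_insert = c(marginal = -7, intermediate = -5,
                                          basal = -2, strut = -4),
                             jitter_deg = 3, jitter_frac = 0.03,
                             jitter_z = 0.5) {
  list(commissural_radius = commissural_radius, ap_radius = ap_radius,
       pm_depth = pm_depth, apm_xy = apm_xy, ppm_xy = ppm_xy,
       radial_frac = radial_frac, z_insert = z_insert,
       jitter_deg = jitter_deg, jitter_frac = jitter_frac,
       jitter_z = jitter_z)
}

# scallop sector boundaries (degrees, annular angle): anterior arc is the
# AML; the posterior arc is split into thirds P1 | P2 | P3
.scallop_of_angle <- function(theta) {
  ifelse(theta < 180, "AML",
         ifelse(theta < 240, "P1", ifelse(theta < 300, "P2", "P3")))
}

# angular placement window per (leaflet, pm): APM serves the anterolateral
# side, PPM the posteromedial side, overlapping over the central region
.angle_range <- function(leaflet, pm) {
  if (leaflet == "AML") {
    if (pm == "APM") c(95, 170) else c(10, 85)
  } else {
    if (pm == "APM") c(185, 295) else c(245, 355)
  }
}

.insertion_kind <- function(group) {
  switch(group,
         AML_marginal = "marginal", AML_strut = "strut",
         PML_marginal = "marginal", PML_intermediate = "intermediate",
         PML_basal = "basal")
}

#' Build an idealized chordae network
#'
#' Constructs a chordae apparatus with the requested origin and insertion
#' counts (defaults from [chordae_count_spec()]): papillary origin nodes at
#' the two PM tips, leaflet insertion points on the annular scallop arcs,
#' and chords discretized into truss segments with an average element length
#' near `avg_element_mm`, at most `max_path_elements` elements from origin
#' to any insertion. Each chord runs unbranched from an origin node to one
#' insertion; several chords share each origin node (point insertions on
#' the papillary tips). Cross-sections default to 0.71 mm^2
#' (basal/intermediate), 2.05 mm^2 (strut) and 0.38 mm^2 (marginal).
#' Construction is deterministic for a fixed seed.
#'
#' @param spec Counts, as from [chordae_count_spec()].
#' @param geometry Geometry parameters, as from [network_geometry()].
#' @param seed Integer seed for the jitter (required for determinism).
#' @param avg_element_mm Target truss element length, mm.
#' @param max_path_elements Cap on elements along any origin-to-insertion
#'   path.
#' @param areas Named cross-sectional areas per group, mm^2.
#' @return An object of class `chordae_network` with `nodes` and `segments`
#'   data frames and a `chords` list.
#' @export
build_network <- function(spec = chordae_count_spec(),
                          geometry = network_geometry(),
                          seed = 1L,
                          avg_element_mm = 1.5,
                          max_path_elements = 10,
                          areas = c(AML_marginal = 0.38, AML_strut = 2.05,
                                    PML_marginal = 0.38,
                                    PML_intermediate = 0.71,
                                    PML_basal = 0.71)) {
  if (any(spec$origins < 0) || any(spec$insertions < 0))
    stop("build_network: counts must be non-negative", call. = FALSE)
  for (g in CHORDAE_GROUPS) {
    lf <- if (startsWith(g, "AML")) "AML" else "PML"
    for (pm in c("APM", "PPM"))
      if (spec$insertions[g, pm] > 0 && spec$origins[lf, pm] == 0)
        stop(sprintf("build_network: group %s has insertions from %s but no %s origins (infeasible spec)",
                     g, pm, lf), call. = FALSE)
  }
  rng <- .seeded_rng(seed)

  nodes <- list()   # each: id, xyz, role, anchor
  segments <- list() # each: id, n1, n2, group, scallop, area0, rest_length, pm
  chords <- list()
  nid <- 0L; sid <- 0L; cid <- 0L

  add_node <- function(xyz, role, anchor) {
    nid <<- nid + 1L
    id <- sprintf("n%03d", nid)
    nodes[[nid]] <<- list(id = id, xyz = xyz, role = role, anchor = anchor)
    id
  }
  add_segment <- function(n1, n2, group, scallop, area0, len, pm) {
    sid <<- sid + 1L
    id <- sprintf("s%03d", sid)
    segments[[sid]] <<- list(id = id, n1 = n1, n2 = n2, group = group,
                             scallop = scallop, area0 = area0,
                             rest_length = len, pm = pm)
    id
  }
  node_xyz <- function(id) nodes[[match(id, vapply(nodes, `[[`, "", "id"))]]$xyz

  # chain of elements from node id `from` (position p0) to position p1;
  # returns list(end_node, segment_ids)
  add_chain <- function(from, p0, p1, n_el, group, scallop, area0, pm,
                        end_role = "branch", end_anchor = pm) {
    segs <- character(0)
    prev <- from; prev_p <- p0
    for (k in seq_len(n_el)) {
      p <- p0 + (p1 - p0) * k / n_el
      if (k < n_el) {
        nd <- add_node(p, "branch", pm)
      } else {
        nd <- add_node(p, end_role, end_anchor)
      }
      segs <- c(segs, add_segment(prev, nd, group, scallop, area0,
                                  sqrt(sum((p - prev_p)^2)), pm))
      prev <- nd; prev_p <- p
    }
    list(end_node = prev, segments = segs)
  }

  n_elements <- function(len, cap) max(1L, min(as.integer(round(len / avg_element_mm)), cap))

  # papillary origin nodes, spread on a small disc around each PM tip
  pm_tip <- list(APM = c(geometry$apm_xy, -geometry$pm_depth),
                 PPM = c(geometry$ppm_xy, -geometry$pm_depth))
  origin_ids <- list()
  for (pm in c("APM", "PPM")) {
    for (lf in c("AML", "PML")) {
      n <- spec$origins[lf, pm]
      ids <- character(0)
      if (n > 0) {
        ang <- 2 * pi * ((seq_len(n) - 0.5) / n) +
          (if (lf == "PML") pi / 5 else 0)
        for (k in seq_len(n)) {
          off <- c(1.4 * cos(ang[k]), 1.4 * sin(ang[k]),
                   0.4 * (rng() - 0.5))
          ids <- c(ids, add_node(pm_tip[[pm]] + off, "pm_origin", pm))
        }
      }
      origin_ids[[paste(lf, pm, sep = ".")]] <- ids
    }
  }

  a <- geometry$commissural_radius; b <- geometry$ap_radius
  for (g in CHORDAE_GROUPS) {
    lf <- if (startsWith(g, "AML")) "AML" else "PML"
    kind <- .insertion_kind(g)
    for (pm in c("APM", "PPM")) {
      n_ins <- spec$insertions[g, pm]
      if (n_ins == 0) next
      rng_ang <- .angle_range(lf, pm)
      theta <- rng_ang[1] + (rng_ang[2] - rng_ang[1]) *
        ((seq_len(n_ins) - 0.5) / n_ins)
      theta <- theta + geometry$jitter_deg * (2 * vapply(theta, function(.) rng(), 0) - 1)
      theta <- pmin(pmax(theta, rng_ang[1]), rng_ang[2])
      frac <- geometry$radial_frac[kind] *
        (1 + geometry$jitter_frac * (2 * vapply(theta, function(.) rng(), 0) - 1))
      zz <- geometry$z_insert[kind] +
        geometry$jitter_z * (2 * vapply(theta, function(.) rng(), 0) - 1)
      pts <- lapply(seq_len(n_ins), function(i) {
        th <- theta[i] * pi / 180
        c(frac[i] * a * cos(th), frac[i] * b * sin(th), zz[i])
      })
      scallop <- if (lf == "AML") rep("AML", n_ins) else .scallop_of_angle(theta)

      origins <- origin_ids[[paste(lf, pm, sep = ".")]]
      # one unbranched chord per insertion; origins are shared round-robin
      # over the angle-sorted insertions, so each origin node spawns
      # several chords (point insertions on the papillary tips)
      ord <- order(theta)
      assign_origin <- origins[((seq_len(n_ins) - 1L) %% length(origins)) + 1L]
      for (k in seq_len(n_ins)) {
        i <- ord[k]
        o_id <- assign_origin[k]
        o_p <- node_xyz(o_id)
        cid <- cid + 1L
        p1 <- pts[[i]]
        d <- sqrt(sum((p1 - o_p)^2))
        ch <- add_chain(o_id, o_p, p1, n_elements(d, max_path_elements),
                        g, scallop[i], areas[[g]], pm,
                        end_role = "insertion", end_anchor = "leaflet")
        chords[[cid]] <- list(id = sprintf("c%03d", cid),
                              segments = ch$segments, group = g, pm = pm,
                              scallop = scallop[i],
                              mean_angle_deg = theta[i],
                              origin_node = o_id,
                              insertion_nodes = ch$end_node)
      }
    }
  }

  nodes_df <- data.frame(
    id = vapply(nodes, `[[`, "", "id"),
    x = vapply(nodes, function(n) n$xyz[1], 0),
    y = vapply(nodes, function(n) n$xyz[2], 0),
    z = vapply(nodes, function(n) n$xyz[3], 0),
    role = vapply(nodes, `[[`, "", "role"),
    anchor = vapply(nodes, `[[`, "", "anchor"),
    stringsAsFactors = FALSE)
  segments_df <- data.frame(
    id = vapply(segments, `[[`, "", "id"),
    n1 = vapply(segments, `[[`, "", "n1"),
    n2 = vapply(segments, `[[`, "", "n2"),
    group = vapply(segments, `[[`, "", "group"),
    scallop = vapply(segments, `[[`, "", "scallop"),
    area0 = vapply(segments, `[[`, 0, "area0"),
    rest_length = vapply(segments, `[[`, 0, "rest_length"),
    pm = vapply(segments, `[[`, "", "pm"),
    stringsAsFactors = FALSE)

  structure(list(nodes = nodes_df, segments = segments_df, chords = chords,
                 spec = spec, geometry = geometry, seed = seed),
            class = "chordae_network")
}

#' @export
print.chordae_network <- function(x, ...) {
  cat("Idealized mitral chordae network\n")
  cat(sprintf("  %d nodes (%d papillary origins, %d leaflet insertions), %d segments, %d chords\n",
              nrow(x$nodes), sum(x$nodes$role == "pm_origin"),
              sum(x$nodes$role == "insertion"), nrow(x$segments),
              length(x$chords)))
  tab <- table(vapply(x$chords, `[[`, "", "group"),
               vapply(x$chords, `[[`, "", "pm"))
  print(tab)
  invisible(x)
}

#' Names of the modeled valve conditions
#'
#' The control plus seven progressive posterior-leaflet chordae rupture
#' scenarios: isolated scallop prolapse (marginal + intermediate chordae of
#' one scallop removed), partial double scallop prolapse (P2 plus the
#' adjacent half of a neighbour) and total double scallop prolapse (basal
#' chordae of both scallops removed as well).
#'
#' @return Character vector of scenario names in order of severity.
#' @export
scenario_names <- function() {
  c("control", "isolated_P3", "isolated_P1", "partial_P2P1", "isolated_P2",
    "partial_P2P3", "total_P2P3", "total_P2P1")
}

# chords (not segments) matching group set + scallop predicate
.chords_matching <- function(network, groups, pred) {
  keep <- vapply(network$chords, function(ch)
    ch$group %in% groups && pred(ch), TRUE)
  network$chords[keep]
}

.chord_segments <- function(chords) unique(unlist(lapply(chords, `[[`, "segments")))

#' Removed-segment set of a rupture scenario
#'
#' Builds the explicit removed-segment set for a named valve condition.
#' Isolated scenarios remove all posterior marginal and intermediate chordae
#' of one scallop; partial double scenarios add the marginal/intermediate
#' chordae of the P2-adjacent half of the second scallop; total double
#' scenarios additionally remove the basal chordae of both involved
#' scallops. An explicit `override` segment-id set replaces the default.
#'
#' @param network A [build_network()] object.
#' @param name One of [scenario_names()].
#' @param override Optional explicit character vector of segment ids.
#' @return An object of class `rupture_scenario`: list with `name` and
#'   `removed_segments`.
#' @export
scenario_segments <- function(network, name, override = NULL) {
  if (!name %in% scenario_names())
    stop(sprintf("scenario_segments: unknown scenario '%s'", name), call. = FALSE)
  if (!is.null(override)) {
    bad <- setdiff(override, network$segments$id)
    if (length(bad))
      stop("scenario_segments: override references unknown segments: ",
           paste(bad, collapse = ", "), call. = FALSE)
    return(structure(list(name = name, removed_segments = override),
                     class = "rupture_scenario"))
  }
  mi <- c("PML_marginal", "PML_intermediate")
  sector_mid <- c(P1 = 210, P3 = 330)   # P2-adjacent halves: P1 above 210, P3 below 330
  in_scallop <- function(s) function(ch) ch$scallop == s
  adjacent_half <- function(s) function(ch) {
    if (ch$scallop != s) return(FALSE)
    if (s == "P1") ch$mean_angle_deg >= sector_mid["P1"]
    else ch$mean_angle_deg <= sector_mid["P3"]
  }
  removed_chords <- switch(
    name,
    control = list(),
    isolated_P1 = .chords_matching(network, mi, in_scallop("P1")),
    isolated_P2 = .chords_matching(network, mi, in_scallop("P2")),
    isolated_P3 = .chords_matching(network, mi, in_scallop("P3")),
    partial_P2P1 = c(.chords_matching(network, mi, in_scallop("P2")),
                     .chords_matching(network, mi, adjacent_half("P1"))),
    partial_P2P3 = c(.chords_matching(network, mi, in_scallop("P2")),
                     .chords_matching(network, mi, adjacent_half("P3"))),
    total_P2P1 = c(.chords_matching(network, mi, in_scallop("P2")),
                   .chords_matching(network, mi, adjacent_half("P1")),
                   .chords_matching(network, "PML_basal",
                                    function(ch) ch$scallop %in% c("P2", "P1"))),
    total_P2P3 = c(.chords_matching(network, mi, in_scallop("P2")),
                   .chords_matching(network, mi, adjacent_half("P3")),
                   .chords_matching(network, "PML_basal",
                                    function(ch) ch$scallop %in% c("P2", "P3"))))
  structure(list(name = name,
                 removed_segments = .chord_segments(removed_chords)),
            class = "rupture_scenario")
}

#' @export
print.rupture_scenario <- function(x, ...) {
  cat(sprintf("Rupture scenario '%s': %d segment(s) removed\n",
              x$name, length(x$removed_segments)))
  invisible(x)
}

#' Quasi-static load case for the chordae network
#'
#' Either supply explicit per-insertion force vectors, or a transmitral
#' pressure that is converted to axial pulls on the insertion nodes via
#' per-group tributary leaflet areas (the leaflet hands its pressure load to
#' each chord along the chord's line of action).
#'
#' @param transmitral_pressure_mmHg Peak systolic transmitral pressure, mmHg.
#' @param insertion_loads Optional named list: insertion node id -> force
#'   vector (N). When given, pressure-derived loads are not used.
#' @param total_tributary_area_mm2 Total leaflet area handing load to the
#'   chordae, mm^2.
#' @param group_weights Relative per-insertion tributary weight of each
#'   chordae group (basal and strut chordae shield more leaflet area).
#' @param pm_displacements Optional named list APM/PPM -> 3-vector (mm)
#'   rigidly displacing that papillary tip's origin nodes.
#' @return An object of class `load_case`.
#' @export
load_case <- function(transmitral_pressure_mmHg = 120,
                      insertion_loads = NULL,
                      total_tributary_area_mm2 = 700,
                      group_weights = c(AML_marginal = 0.8, AML_strut = 3.5,
                                        PML_marginal = 0.35,
                                        PML_intermediate = 0.8,
                                        PML_basal = 3.0),
                      pm_displacements = NULL) {
  if (transmitral_pressure_mmHg < 0)
    stop("load_case: pressure must be non-negative", call. = FALSE)
  structure(list(transmitral_pressure_mmHg = transmitral_pressure_mmHg,
                 insertion_loads = insertion_loads,
                 total_tributary_area_mm2 = total_tributary_area_mm2,
                 group_weights = group_weights,
                 pm_displacements = pm_displacements),
            class = "load_case")
}

# Axial pull on each insertion node: pressure x tributary area along the
# terminal segment direction (away from the chord). Returns named list of
# 3-vectors in N.
.pressure_loads <- function(network, load) {
  ins_chord <- list()
  for (ch in network$chords)
    for (nd in ch$insertion_nodes) ins_chord[[nd]] <- ch
  w <- vapply(names(ins_chord), function(nd)
    load$group_weights[[ins_chord[[nd]]$group]], 0)
  area_per <- load$total_tributary_area_mm2 * w / sum(w)   # mm^2
  p_mpa <- load$transmitral_pressure_mmHg * MMHG_TO_PA * 1e-6  # N/mm^2
  xyz <- as.matrix(network$nodes[, c("x", "y", "z")])
  rownames(xyz) <- network$nodes$id
  loads <- list()
  for (nd in names(ins_chord)) {
    ch <- ins_chord[[nd]]
    # terminal segment of the branch ending at this insertion
    seg_row <- network$segments[network$segments$id %in% ch$segments &
                                  (network$segments$n2 == nd |
                                     network$segments$n1 == nd), , drop = FALSE]
    seg_row <- seg_row[1, ]
    other <- if (seg_row$n2 == nd) seg_row$n1 else seg_row$n2
    dir <- xyz[nd, ] - xyz[other, ]
    dir <- dir / sqrt(sum(dir^2))
    loads[[nd]] <- p_mpa * area_per[[nd]] * dir
  }
  loads
}

# connected component labels of nodes over the active segments
.components <- function(node_ids, seg_n1, seg_n2) {
  idx <- seq_along(node_ids)
  names(idx) <- node_ids
  parent <- idx
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(seg_n1)) {
    a <- find(idx[[seg_n1[k]]]); b <- find(idx[[seg_n2[k]]])
    if (a != b) parent[a] <- b
  }
  vapply(idx, find, 0L)
}

#' Solve tension-only static equilibrium of the chordae network
#'
#' Quasi-static nonlinear truss equilibrium under the given load case with
#' the segments of `scenario` removed. Each segment carries the tension-only
#' axial force of [ogden_chord_force()] at its current stretch; papillary
#' origin nodes are fixed (optionally displaced per the load case); all
#' other connected nodes equilibrate. Newton's method with load stepping is
#' used; insertion nodes disconnected from every papillary origin after the
#' removal are unloaded and their chords reported slack.
#'
#' @param network A [build_network()] object.
#' @param scenario A [scenario_segments()] object, or `NULL` for control.
#' @param load A [load_case()].
#' @param ogden Chordae [ogden_params()].
#' @param n_steps Number of equal load increments.
#' @param tol_rel Convergence tolerance on the residual force norm, relative
#'   to the applied load norm.
#' @param max_iter Newton iteration cap per load step.
#' @return An object of class `tension_solution`: named `segment_tensions`
#'   (N), `node_displacements` (mm, rows named by node id), `converged`,
#'   `residual` (N), `residual_history` and `slack_chords`.
#' @export
solve_static_tensions <- function(network, scenario = NULL, load = load_case(),
                                  ogden, n_steps = 10, tol_rel = 1e-8,
                                  max_iter = 50) {
  stopifnot(inherits(network, "chordae_network"), inherits(ogden, "ogden_params"))
  removed <- if (is.null(scenario)) character(0) else scenario$removed_segments
  seg <- network$segments
  active <- !(seg$id %in% removed)
  nodes <- network$nodes
  nn <- nrow(nodes)
  xyz <- unname(as.matrix(nodes[, c("x", "y", "z")]))
  rownames(xyz) <- nodes$id
  idx <- seq_len(nn); names(idx) <- nodes$id

  # loads
  loads <- load$insertion_loads
  if (is.null(loads)) loads <- .pressure_loads(network, load)
  bad <- setdiff(names(loads), nodes$id[nodes$role == "insertion"])
  if (length(bad))
    stop("solve_static_tensions: loads on non-insertion nodes: ",
         paste(bad, collapse = ", "), call. = FALSE)

  # connectivity after removal: drop loads on orphaned insertions
  comp <- .components(nodes$id, seg$n1[active], seg$n2[active])
  origin_comps <- unique(comp[idx[nodes$id[nodes$role == "pm_origin"]]])
  connected <- comp %in% origin_comps
  slack_chords <- character(0)
  for (ch in network$chords) {
    if (any(ch$insertion_nodes %in% names(loads)) &&
        !all(connected[idx[ch$insertion_nodes]]))
      slack_chords <- c(slack_chords, ch$id)
  }
  loads <- loads[connected[idx[names(loads)]]]

  # papillary displacements
  x0 <- xyz
  if (!is.null(load$pm_displacements)) {
    for (pm in names(load$pm_displacements)) {
      sel <- nodes$role == "pm_origin" & nodes$anchor == pm
      x0[sel, ] <- x0[sel, ] + rep(load$pm_displacements[[pm]], each = sum(sel))
    }
  }

  free <- which(nodes$role != "pm_origin" & connected)
  fmap <- integer(nn); fmap[free] <- seq_along(free)
  ndof <- 3L * length(free)

  Fext_full <- matrix(0, nn, 3)
  for (nd in names(loads)) Fext_full[idx[[nd]], ] <- loads[[nd]]
  load_norm <- sqrt(sum(Fext_full^2))

  tensions <- stats::setNames(numeric(nrow(seg)), seg$id)
  x <- x0
  residual_history <- numeric(0)
  converged <- TRUE
  res_norm <- 0

  if (load_norm > 0 && any(active)) {
    sa <- which(active)
    i1 <- idx[seg$n1[sa]]; i2 <- idx[seg$n2[sa]]
    L0 <- seg$rest_length[sa]; A0 <- seg$area0[sa]

    seg_state <- function(x) {
      d <- x[i2, , drop = FALSE] - x[i1, , drop = FALSE]
      L <- sqrt(rowSums(d^2))
      list(d = d, L = L, lam = L / L0)
    }
    internal_force <- function(st) {
      Tn <- ogden_chord_force(st$lam, ogden, 1) * A0
      Fint <- matrix(0, nn, 3)
      u <- st$d / st$L
      fvec <- u * Tn
      for (r in seq_along(sa)) {
        Fint[i1[r], ] <- Fint[i1[r], ] + fvec[r, ]
        Fint[i2[r], ] <- Fint[i2[r], ] - fvec[r, ]
      }
      list(Fint = Fint, Tn = Tn)
    }

    for (s in seq_len(n_steps)) {
      Fs <- Fext_full * (s / n_steps)
      tol <- tol_rel * max(sqrt(sum(Fs^2)), 1e-12)
      st <- seg_state(x)
      fi <- internal_force(st)
      R <- (Fs + fi$Fint)[free, , drop = FALSE]
      res_norm <- sqrt(sum(R^2))
      it <- 0
      while (res_norm > tol && it < max_iter) {
        it <- it + 1
        # assemble tangent (triplets)
        ii <- integer(0); jj <- integer(0); vv <- numeric(0)
        for (r in seq_along(sa)) {
          lam <- st$lam[r]
          u <- st$d[r, ] / st$L[r]
          kax <- if (lam >= 1) {
            a <- ogden$alpha
            A0[r] * sum(ogden$mu * ((a - 1) * lam^(a - 2) +
                                      (a / 2 + 1) * lam^(-a / 2 - 2))) / L0[r]
          } else 0
          kg <- fi$Tn[r] / st$L[r]
          Ke <- (kax - kg) * tcrossprod(u) + kg * diag(3)
          f1 <- fmap[i1[r]]; f2 <- fmap[i2[r]]
          if (f1 > 0) {
            base1 <- 3 * (f1 - 1)
            ii <- c(ii, rep(base1 + 1:3, 3)); jj <- c(jj, rep(base1 + 1:3, each = 3))
            vv <- c(vv, as.numeric(Ke))
          }
          if (f2 > 0) {
            base2 <- 3 * (f2 - 1)
            ii <- c(ii, rep(base2 + 1:3, 3)); jj <- c(jj, rep(base2 + 1:3, each = 3))
            vv <- c(vv, as.numeric(Ke))
          }
          if (f1 > 0 && f2 > 0) {
            base1 <- 3 * (f1 - 1); base2 <- 3 * (f2 - 1)
            ii <- c(ii, rep(base1 + 1:3, 3), rep(base2 + 1:3, 3))
            jj <- c(jj, rep(base2 + 1:3, each = 3), rep(base1 + 1:3, each = 3))
            vv <- c(vv, as.numeric(-Ke), as.numeric(-Ke))
          }
        }
        K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ndof, ndof))
        eps_reg <- 1e-7 * max(Matrix::diag(K), 1e-12)
        K <- K + Matrix::Diagonal(ndof, eps_reg)
        dx <- tryCatch(
          as.numeric(Matrix::solve(K, as.numeric(t(R)))),
          error = function(e) {
            dmin <- which.min(Matrix::diag(K))
            nd_bad <- nodes$id[free[(dmin - 1) %/% 3 + 1]]
            stop(sprintf("solve_static_tensions: singular tangent (mechanism) at node %s",
                         nd_bad), call. = FALSE)
          })
        dX <- matrix(dx, ncol = 3, byrow = TRUE)
        # cap the largest nodal move per iteration (stiff chordae laws make
        # the first Newton steps overshoot badly otherwise)
        max_move <- sqrt(max(rowSums(dX^2)))
        cap <- 0.5 * mean(L0)
        if (max_move > cap) dX <- dX * (cap / max_move)
        # backtracking line search on the residual norm
        step <- 1
        repeat {
          x_try <- x
          x_try[free, ] <- x[free, , drop = FALSE] + step * dX
          st_try <- seg_state(x_try)
          fi_try <- internal_force(st_try)
          R_try <- (Fs + fi_try$Fint)[free, , drop = FALSE]
          rn_try <- sqrt(sum(R_try^2))
          if (rn_try < res_norm || step < 1 / 64) break
          step <- step / 2
        }
        x <- x_try; st <- st_try; fi <- fi_try; R <- R_try
        res_norm <- rn_try
        residual_history <- c(residual_history, res_norm)
      }
      if (res_norm > tol) {
        converged <- FALSE
        stop(sprintf(paste0(
          "solve_static_tensions: no convergence at load step %d/%d ",
          "(residual %.3e N, tol %.3e N); residual history: %s"),
          s, n_steps, res_norm, tol,
          paste(sprintf("%.2e", utils::tail(residual_history, 8)),
                collapse = " ")), call. = FALSE)
      }
    }
    tensions[sa] <- ogden_chord_force(seg_state(x)$lam, ogden, 1) * A0
  }
  tensions[seg$id %in% removed] <- 0

  disp <- x - x0
  rownames(disp) <- nodes$id
  structure(list(segment_tensions = tensions, node_displacements = disp,
                 node_positions = x, converged = converged,
                 residual = res_norm, residual_history = residual_history,
                 slack_chords = slack_chords,
                 removed_segments = removed),
            class = "tension_solution")
}

#' @export
print.tension_solution <- function(x, ...) {
  cat(sprintf("Chordae tension solution: %s, residual %.3e N\n",
              if (x$converged) "converged" else "NOT converged", x$residual))
  cat(sprintf("  %d segments, max tension %.4g N, %d slack chord(s)\n",
              length(x$segment_tensions), max(x$segment_tensions),
              length(x$slack_chords)))
  invisible(x)
}

# origin-adjacent segment id and its unit direction (origin end -> distal)
# in the deformed configuration
.chord_root <- function(network, solution, ch) {
  sid <- ch$segments[1]
  row <- network$segments[network$segments$id == sid, ]
  pos <- solution$node_positions
  o <- ch$origin_node
  other <- if (row$n1 == o) row$n2 else row$n1
  dir <- pos[other, ] - pos[o, ]
  list(sid = sid, dir = dir / sqrt(sum(dir^2)))
}

#' Net force carried by a chordae group
#'
#' Vector sum, over every chord of a group (optionally restricted to one
#' papillary muscle), of the tension in the chord's origin-adjacent segment
#' times that segment's unit direction. This is the net pull the group
#' exerts on its papillary tips.
#'
#' @param network A [build_network()] object.
#' @param solution A converged [solve_static_tensions()] result.
#' @param group One of the chordae group labels.
#' @param pm Optional `"APM"` or `"PPM"`.
#' @return List with `vector` (length-3, N) and `magnitude` (N).
#' @export
group_force <- function(network, solution, group, pm = NULL) {
  if (!group %in% CHORDAE_GROUPS)
    stop(sprintf("group_force: unknown group '%s'", group), call. = FALSE)
  if (!solution$converged)
    stop("group_force: solution did not converge", call. = FALSE)
  v <- c(0, 0, 0)
  for (ch in network$chords) {
    if (ch$group != group) next
    if (!is.null(pm) && ch$pm != pm) next
    root <- .chord_root(network, solution, ch)
    v <- v + solution$segment_tensions[[root$sid]] * root$dir
  }
  list(vector = v, magnitude = sqrt(sum(v^2)))
}

#' Distribution of papillary muscle force among chordae groups
#'
#' For each papillary muscle, the percentage of its total chordal load
#' (scalar sum of origin-adjacent chord tensions) carried by each chordae
#' group. Rows sum to 100 per papillary muscle.
#'
#' @inheritParams group_force
#' @return Data frame with columns `pm`, `group`, `percent`.
#' @export
pm_force_distribution <- function(network, solution) {
  out <- list()
  for (pm in c("APM", "PPM")) {
    tens <- stats::setNames(numeric(length(CHORDAE_GROUPS)), CHORDAE_GROUPS)
    for (ch in network$chords) {
      if (ch$pm != pm) next
      root <- .chord_root(network, solution, ch)
      tens[ch$group] <- tens[ch$group] + solution$segment_tensions[[root$sid]]
    }
    tot <- sum(tens)
    if (tot <= 0)
      stop(sprintf("pm_force_distribution: all chords from %s are slack (undefined distribution)",
                   pm), call. = FALSE)
    out[[pm]] <- data.frame(pm = pm, group = CHORDAE_GROUPS,
                            percent = 100 * tens / tot,
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Compare chordae group forces across rupture scenarios
#'
#' Solves the network for each scenario and tabulates per-group net force
#' magnitudes and their percent change relative to control.
#'
#' @param network A [build_network()] object.
#' @param scenarios Character vector of scenario names (must include
#'   `"control"`) or list of [scenario_segments()] objects.
#' @param load A [load_case()].
#' @param ogden Chordae [ogden_params()].
#' @return List with `forces` (data frame scenario x group magnitudes and
#'   percent change vs control) and `solutions` (named list).
#' @export
compare_scenarios <- function(network, scenarios = scenario_names(),
                              load = load_case(), ogden) {
  if (is.character(scenarios))
    scenarios <- lapply(scenarios, function(nm) scenario_segments(network, nm))
  nm <- vapply(scenarios, `[[`, "", "name")
  if (!"control" %in% nm)
    stop("compare_scenarios: scenarios must include control", call. = FALSE)
  sols <- list()
  rows <- list()
  for (sc in scenarios) {
    sol <- solve_static_tensions(network, sc, load, ogden)
    sols[[sc$name]] <- sol
    for (g in CHORDAE_GROUPS) {
      gf <- group_force(network, sol, g)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, group = g, magnitude_N = gf$magnitude)
    }
  }
  forces <- do.call(rbind, rows)
  ctrl <- forces[forces$scenario == "control", c("group", "magnitude_N")]
  names(ctrl)[2] <- "control_N"
  forces <- merge(forces, ctrl, by = "group", sort = FALSE)
  forces$pct_change_vs_control <- ifelse(
    forces$control_N > 0,
    100 * (forces$magnitude_N - forces$control_N) / forces$control_N,
    ifelse(forces$magnitude_N == 0, 0, NA_real_))
  forces <- forces[order(match(forces$scenario, nm),
                         match(forces$group, CHORDAE_GROUPS)),
                   c("scenario", "group", "magnitude_N",
                     "pct_change_vs_control")]
  rownames(forces) <- NULL
  list(forces = forces, solutions = sols)
}

#' Write / read a chordae network as JSON
#'
#' Serialises the network in a plain schema: `nodes` (id, xyz_mm, role,
#' anchor), `segments` (id, n1, n2, group, scallop, area0_mm2, pm,
#' rest_length_mm) and `chords` (id, group, pm, scallop, segments).
#'
#' @param network A [build_network()] object.
#' @param path Output / input file path.
#' @return `write_network_json` returns `path` invisibly;
#'   `read_network_json` returns a `chordae_network`.
#' @export
write_network_json <- function(network, path) {
  nodes <- lapply(seq_len(nrow(network$nodes)), function(i) {
    r <- network$nodes[i, ]
    list(id = r$id, xyz_mm = c(r$x, r$y, r$z), role = r$role, anchor = r$anchor)
  })
  segs <- lapply(seq_len(nrow(network$segments)), function(i) {
    r <- network$segments[i, ]
    list(id = r$id, n1 = r$n1, n2 = r$n2, group = r$group, scallop = r$scallop,
         area0_mm2 = r$area0, rest_length_mm = r$rest_length, pm = r$pm)
  })
  chords <- lapply(network$chords, function(ch)
    list(id = ch$id, group = ch$group, pm = ch$pm, scallop = ch$scallop,
         mean_angle_deg = ch$mean_angle_deg, origin_node = ch$origin_node,
         insertion_nodes = I(ch$insertion_nodes), segments = I(ch$segments)))
  jsonlite::write_json(list(nodes = nodes, segments = segs, chords = chords),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- do.call(rbind, lapply(j$nodes, function(n)
    data.frame(id = n$id, x = n$xyz_mm[[1]], y = n$xyz_mm[[2]],
               z = n$xyz_mm[[3]], role = n$role, anchor = n$anchor)))
  segs <- do.call(rbind, lapply(j$segments, function(s)
    data.frame(id = s$id, n1 = s$n1, n2 = s$n2, group = s$group,
               scallop = s$scallop, area0 = s$area0_mm2,
               rest_length = s$rest_length_mm, pm = s$pm)))
  chords <- lapply(j$chords, function(ch)
    list(id = ch$id, segments = unlist(ch$segments), group = ch$group,
         pm = ch$pm, scallop = ch$scallop,
         mean_angle_deg = ch$mean_angle_deg,
         origin_node = ch$origin_node,
         insertion_nodes = unlist(ch$insertion_nodes)))
  structure(list(nodes = nodes, segments = segs, chords = chords,
                 spec = NULL, geometry = NULL, seed = NA_integer_),
            class = "chordae_network")
}

#' Export segment tensions as CSV
#'
#' Writes one row per segment: `segment_id, group, scallop, pm, tension_N`.
#'
#' @inheritParams group_force
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tension_csv <- function(network, solution, path) {
  df <- data.frame(segment_id = network$segments$id,
                   group = network$segments$group,
                   scallop = network$segments$scallop,
                   pm = network$segments$pm,
                   tension_N = as.numeric(
                     solution$segment_tensions[network$segments$id]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
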