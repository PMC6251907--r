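# Hand-built miniature chordae networks with known closed-form statics,
# shared across test files.

# straight vertical chord from a fixed origin to an insertion, split into
# n_el equal elements
make_single_chord <- function(length_mm = 10, area0 = 0.38, n_el = 2) {
  z <- seq(0, length_mm, length.out = n_el + 1)
  ids <- c("o", if (n_el > 1) sprintf("m%d", seq_len(n_el - 1)), "i")
  nodes <- data.frame(
    id = ids, x = 0, y = 0, z = z,
    role = c("pm_origin", rep("branch", n_el - 1), "insertion"),
    anchor = c("APM", rep("APM", n_el - 1), "leaflet"),
    stringsAsFactors = FALSE)
  segs <- data.frame(
    id = sprintf("s%d", seq_len(n_el)),
    n1 = ids[-length(ids)], n2 = ids[-1],
    group = "PML_marginal", scallop = "P2", area0 = area0,
    rest_length = diff(z), pm = "APM", stringsAsFactors = FALSE)
  chords <- list(list(id = "c1", segments = segs$id, group = "PML_marginal",
                      pm = "APM", scallop = "P2", mean_angle_deg = 270,
                      origin_node = "o", insertion_nodes = "i"))
  structure(list(nodes = nodes, segments = segs, chords = chords),
            class = "chordae_network")
}

# symmetric two-chord "V": both origins fixed, one shared insertion node at
# the apex; each chord makes half-angle theta with the load axis (z)
make_v_network <- function(theta_deg = 30, leg_mm = 10, area0 = 0.38) {
  th <- theta_deg * pi / 180
  dx <- leg_mm * sin(th); dz <- leg_mm * cos(th)
  nodes <- data.frame(
    id = c("o1", "o2", "apex"),
    x = c(-dx, dx, 0), y = 0, z = c(0, 0, dz),
    role = c("pm_origin", "pm_origin", "insertion"),
    anchor = c("APM", "PPM", "leaflet"), stringsAsFactors = FALSE)
  segs <- data.frame(
    id = c("s1", "s2"), n1 = c("o1", "o2"), n2 = c("apex", "apex"),
    group = "PML_marginal", scallop = "P2", area0 = area0,
    rest_length = leg_mm, pm = c("APM", "PPM"), stringsAsFactors = FALSE)
  chords <- list(
    list(id = "c1", segments = "s1", group = "PML_marginal", pm = "APM",
         scallop = "P2", mean_angle_deg = 260, origin_node = "o1",
         insertion_nodes = "apex"),
    list(id = "c2", segments = "s2", group = "PML_marginal", pm = "PPM",
         scallop = "P2", mean_angle_deg = 280, origin_node = "o2",
         insertion_nodes = "apex"))
  structure(list(nodes = nodes, segments = segs, chords = chords),
            class = "chordae_network")
}

# two parallel vertical chords sharing one loaded insertion node
make_parallel_pair <- function(length_mm = 10, area0 = 0.38) {
  nodes <- data.frame(
    id = c("o1", "o2", "i"),
    x = c(0, 0, 0), y = 0, z = c(0, 0, length_mm),
    role = c("pm_origin", "pm_origin", "insertion"),
    anchor = c("APM", "PPM", "leaflet"), stringsAsFactors = FALSE)
  segs <- data.frame(
    id = c("s1", "s2"), n1 = c("o1", "o2"), n2 = c("i", "i"),
    group = "PML_basal", scallop = "P2", area0 = area0,
    rest_length = length_mm, pm = c("APM", "PPM"), stringsAsFactors = FALSE)
  chords <- list(
    list(id = "c1", segments = "s1", group = "PML_basal", pm = "APM",
         scallop = "P2", mean_angle_deg = 260, origin_node = "o1",
         insertion_nodes = "i"),
    list(id = "c2", segments = "s2", group = "PML_basal", pm = "PPM",
         scallop = "P2", mean_angle_deg = 280, origin_node = "o2",
         insertion_nodes = "i"))
  structure(list(nodes = nodes, segments = segs, chords = chords),
            class = "chordae_network")
}

# papillary reaction forces of a solution: at each origin node, the sum of
# adjacent segment tensions pulling along the deformed segment directions
pm_reactions <- function(network, solution) {
  pos <- solution$node_positions
  out <- matrix(0, 0, 3)
  for (o in network$nodes$id[network$nodes$role == "pm_origin"]) {
    f <- c(0, 0, 0)
    adj <- network$segments[network$segments$n1 == o |
                              network$segments$n2 == o, , drop = FALSE]
    for (k in seq_len(nrow(adj))) {
      other <- if (adj$n1[k] == o) adj$n2[k] else adj$n1[k]
      d <- pos[other, ] - pos[o, ]
      f <- f + solution$segment_tensions[[adj$id[k]]] * d / sqrt(sum(d^2))
    }
    out <- rbind(out, f)
  }
  out
}

example_ogden <- function() ogden_params(mu = 0.18, alpha = 20)
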