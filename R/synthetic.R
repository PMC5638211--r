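#' Sample a complex contact topology
#'
#' Builds the connected contact graph of one complex. The chain topology is
#' the canonical test case for conditional-dependence methods: in a chain
#' A-B-C the endpoints co-elute through the shared middle subunit, so their
#' marginal correlation is high while their partial correlation given B is
#' near zero.
#'
#' @param n_subunits Number of subunits (>= 2).
#' @param kind One of `"chain"`, `"star"`, `"ring"`, `"random-tree"`.
#' @param seed Seed for `"random-tree"` (ignored otherwise).
#' @param vertex_names Optional character vector of subunit names.
#' @return An [igraph::graph] with named vertices.
#' @export
sample_complex_topology <- function(n_subunits,
                                    kind = c("chain", "star", "ring",
                                             "random-tree"),
                                    seed = NULL, vertex_names = NULL) {
  kind <- match.arg(kind)
  if (n_subunits < 2L) stopf("a complex needs at least 2 subunits")
  if (is.null(vertex_names))
    vertex_names <- paste0("P", seq_len(n_subunits))
  edges <- switch(kind,
    chain = cbind(seq_len(n_subunits - 1L), seq_len(n_subunits - 1L) + 1L),
    star = cbind(1L, seq.int(2L, n_subunits)),
    ring = {
      if (n_subunits < 3L) stopf("a ring needs at least 3 subunits")
      cbind(seq_len(n_subunits), c(seq.int(2L, n_subunits), 1L))
    },
    `random-tree` = with_seed(seed, {
      # random recruitment order: each new subunit attaches to a uniform
      # previous one, giving a uniform-ish random tree
      if (n_subunits == 2L) cbind(1L, 2L)
      else cbind(vapply(seq.int(2L, n_subunits),
                        function(i) sample.int(i - 1L, 1L), integer(1L)),
                 seq.int(2L, n_subunits))
    }))
  g <- igraph::make_empty_graph(n = n_subunits, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- vertex_names
  g
}

#' Define a synthetic CF-MS ground truth
#'
#' Fixes the complexes, their contact graphs, and the generator parameters
#' of a simulated co-fractionation study. Defaults describe the package's
#' standard validation scenario: 5 chain complexes of 5 subunits separated
#' in 40 experiments of 50 fractions each, with partial dissociation
#' (`p_break = 0.3`), log-normal quantitation noise, and dropout of
#' low-abundance identifications to exact zeros.
#'
#' @param n_complexes Number of complexes (default 5).
#' @param n_subunits Subunits per complex (default 5).
#' @param kind Topology of every complex (see [sample_complex_topology()]).
#' @param n_experiments Fractionation experiments (default 40).
#' @param fractions_per_experiment Fractions per experiment (default 50).
#' @param peak_sd_range Range of chromatographic peak widths, in fractions
#'   (default c(1, 3)).
#' @param intensity_scale Median species peak intensity, in arbitrary MS
#'   units (default 1e5).
#' @param p_break Probability that each contact independently dissociates in
#'   a given experiment (default 0.3); the resulting connected subcomplexes
#'   are the eluting species.
#' @param dispersion Standard deviation of the multiplicative log-normal
#'   quantitation noise, on the log scale (default 0.25).
#' @param dropout Fraction of detectable positive measurements dropped to
#'   exact 0, emulating missed identifications (default 0.2).
#' @param p_present_range Range from which each complex's per-experiment
#'   expression probability is drawn (default c(0.15, 0.85)). CF-MS studies
#'   pool experiments from different cell types and lysis conditions, so a
#'   complex is typically absent from entire experiments -- ubiquitous
#'   complexes appear in most, compartment- or cell-type-specific ones in
#'   few. This reproduces the order-of-magnitude spread in per-complex
#'   observation depth seen in real CF-MS compendia, and the shared
#'   presence/absence pattern it induces correlates *every* pair of
#'   co-complex subunits, direct or not, which is the main confounder of
#'   the marginal-correlation baseline.
#' @param complex_scale_sdlog Log-scale standard deviation of the
#'   per-complex median abundance (default 2): protein complexes span
#'   several orders of magnitude in cellular abundance and MS
#'   detectability.
#' @param seed Master seed for dataset generation.
#' @return List of class `synthetic_truth`: `graphs` (list of igraphs with
#'   globally unique vertex names `C<k>_P<i>`), plus all parameters.
#' @export
synthetic_truth <- function(n_complexes = 5L, n_subunits = 5L,
                            kind = "chain", n_experiments = 40L,
                            fractions_per_experiment = 50L,
                            peak_sd_range = c(1, 3), intensity_scale = 1e5,
                            p_break = 0.3, dispersion = 0.25, dropout = 0.2,
                            p_present_range = c(0.15, 0.85),
                            complex_scale_sdlog = 2,
                            seed = 1L) {
  if (p_break < 0 || p_break > 1) stopf("p_break must be in [0, 1]")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (any(p_present_range <= 0) || any(p_present_range > 1))
    stopf("p_present_range must lie in (0, 1]")
  graphs <- lapply(seq_len(n_complexes), function(k) {
    sample_complex_topology(
      n_subunits, kind, seed = if (is.null(seed)) NULL else seed + k,
      vertex_names = sprintf("C%d_P%d", k, seq_len(n_subunits)))
  })
  names(graphs) <- sprintf("complex_%d", seq_len(n_complexes))
  per_complex <- with_seed(
    if (is.null(seed)) NULL else seed + 7919L,
    list(scales = stats::rlnorm(n_complexes, log(intensity_scale),
                                complex_scale_sdlog),
         p_present = stats::runif(n_complexes, p_present_range[1L],
                                  p_present_range[2L])))
  complex_scales <- stats::setNames(per_complex$scales, names(graphs))
  complex_p_present <- stats::setNames(per_complex$p_present, names(graphs))
  structure(list(graphs = graphs, n_experiments = n_experiments,
                 fractions_per_experiment = fractions_per_experiment,
                 peak_sd_range = peak_sd_range,
                 intensity_scale = intensity_scale, p_break = p_break,
                 dispersion = dispersion, dropout = dropout,
                 p_present_range = p_present_range,
                 complex_p_present = complex_p_present,
                 complex_scale_sdlog = complex_scale_sdlog,
                 complex_scales = complex_scales, seed = seed),
            class = "synthetic_truth")
}

#' Simulate one fractionation experiment
#'
#' One pass of the generative model: every contact of every complex breaks
#' independently with probability `p_break`; the connected components of
#' what remains are the eluting species. Each species receives a Gaussian
#' elution peak (uniform random center along the gradient, width drawn from
#' `peak_sd_range`, log-normal intensity around `intensity_scale`), and a
#' protein's abundance in a fraction is the sum over the species containing
#' it, times multiplicative log-normal noise. Measurements below a detection
#' floor (1e-5 of the experiment maximum, a typical MS dynamic range) are
#' zeroed, and a further random `dropout` fraction of the remaining positive
#' measurements is set to exact 0.
#'
#' @param truth A [synthetic_truth()].
#' @param experiment_label Label for the resulting fractions.
#' @param seed Optional seed for this experiment (when called directly);
#'   [generate_dataset()] instead drives one seeded RNG stream.
#' @return An [elution_matrix] for one experiment.
#' @export
simulate_fractionation_experiment <- function(truth, experiment_label = "exp1",
                                              seed = NULL) {
  run <- function() {
    fr <- seq_len(truth$fractions_per_experiment)
    proteins <- unlist(lapply(truth$graphs, function(g) igraph::V(g)$name))
    vals <- matrix(0, length(proteins), length(fr),
                   dimnames = list(proteins, sprintf("f%d", fr)))
    for (cid in names(truth$graphs)) {
      g <- truth$graphs[[cid]]
      scale_c <- if (is.null(truth$complex_scales)) truth$intensity_scale
                 else truth$complex_scales[[cid]]
      if (stats::runif(1L) >= truth$complex_p_present[[cid]])
        next  # complex not expressed in this experiment
      ne <- igraph::ecount(g)
      keep <- stats::runif(ne) >= truth$p_break
      sub <- igraph::subgraph_from_edges(g, igraph::E(g)[keep],
                                         delete.vertices = FALSE)
      comp <- igraph::components(sub)
      for (cc in seq_len(comp$no)) {
        members <- igraph::V(g)$name[comp$membership == cc]
        center <- stats::runif(1L, 1, truth$fractions_per_experiment)
        width <- stats::runif(1L, truth$peak_sd_range[1L],
                              truth$peak_sd_range[2L])
        intensity <- stats::rlnorm(1L, log(scale_c), 0.5)
        peak <- intensity * exp(-(fr - center)^2 / (2 * width^2))
        vals[members, ] <- vals[members, , drop = FALSE] +
          matrix(peak, length(members), length(fr), byrow = TRUE)
      }
    }
    noise <- matrix(stats::rlnorm(length(vals), 0, truth$dispersion),
                    nrow(vals), ncol(vals))
    vals <- vals * noise
    # detection floor: MS cannot see ~5 orders of magnitude below the top signal
    vals[vals < max(vals) * 1e-5] <- 0
    if (truth$dropout > 0) {
      pos <- which(vals > 0)
      drop <- pos[stats::runif(length(pos)) < truth$dropout]
      vals[drop] <- 0
    }
    elution_matrix(vals, experiment_label)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a full synthetic CF-MS dataset
#'
#' Simulates `n_experiments` independent fractionation experiments from one
#' ground truth and concatenates them column-wise, together with the
#' benchmark implied by the truth graphs: within-complex pairs labeled
#' contacting when the truth has an edge (nominal interface area 100
#' square Angstroms) and non-contacting otherwise. Fully reproducible from
#' `truth$seed`.
#'
#' @param truth A [synthetic_truth()].
#' @return List with `elution` ([elution_matrix]), `benchmark`
#'   (`structure_benchmark`), and `truth`.
#' @export
generate_dataset <- function(truth) {
  mats <- with_seed(truth$seed, {
    lapply(seq_len(truth$n_experiments), function(e) {
      simulate_fractionation_experiment(
        truth, experiment_label = sprintf("exp%02d", e))
    })
  })
  elution <- concat_experiments(mats)
  benchmark <- truth_benchmark(truth)
  list(elution = elution, benchmark = benchmark, truth = truth)
}

#' Benchmark implied by a synthetic truth
#'
#' @param truth A [synthetic_truth()].
#' @param min_subunits Passed to [build_structure_benchmark()].
#' @return A `structure_benchmark` labeling truth edges as contacting.
#' @export
truth_benchmark <- function(truth, min_subunits = 2L) {
  rows <- lapply(names(truth$graphs), function(cid) {
    g <- truth$graphs[[cid]]
    mem <- sort(igraph::V(g)$name)
    cmb <- utils::combn(mem, 2L)
    is_edge <- mapply(function(a, b) {
      igraph::are_adjacent(g, a, b)
    }, cmb[1L, ], cmb[2L, ])
    data.frame(complex_id = cid, protein_a = cmb[1L, ], protein_b = cmb[2L, ],
               interface_area = ifelse(is_edge, 100, 0),
               stringsAsFactors = FALSE)
  })
  build_structure_benchmark(do.call(rbind, rows), min_subunits = min_subunits)
}

#' Complex catalog implied by a synthetic truth
#'
#' @param truth A [synthetic_truth()].
#' @return Named list of member vectors, as [read_complex_catalog()] returns.
#' @export
truth_catalog <- function(truth) {
  lapply(truth$graphs, function(g) igraph::V(g)$name)
}
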