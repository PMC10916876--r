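#' Simulation scenario for paired panels and compound screens
#'
#' Defines the statistical structure the pipeline assumes, at desk scale: a
#' baseline of independent standard-normal morphological features; a small
#' set of planted feature subsets; continuous readouts that are noisy linear
#' functions of their planted subset; perturbation groups whose members are
#' mean-shifted on a planted subset (so that (readout, group) pairs sharing
#' a subset form recoverable terms); a pool of negative controls drawn from
#' baseline; and a compound screen whose active compounds are shifted on one
#' planted subset.
#'
#' The default scenario: 200 features; 5 readouts of which 4 are planted on
#' disjoint 8-feature subsets; 15 perturbation groups of 14 profiles each of
#' which the first 4 are shifted by delta = 1.5 sd on the matching readout's
#' subset; 30 negative controls (240 profiles in total); readout noise
#' sd 0.5; compound screen of 400 compounds at 35 % prevalence with an
#' activity effect of 1 sd on the first planted subset. All randomness flows
#' from `seed` through named child streams, so adding a stage never perturbs
#' earlier draws.
#'
#' @param n_features number of morphological features.
#' @param n_readouts number of continuous readouts; the first `n_planted`
#'   are planted, the rest are pure noise.
#' @param n_planted number of planted (readout, group) associations.
#' @param subset_size size of each planted feature subset.
#' @param n_groups,group_size non-control perturbation groups and their
#'   sizes; groups beyond `n_planted` have no effect.
#' @param controls number of negative-control profiles.
#' @param delta group mean shift on the planted subset, in sd units.
#' @param readout_noise sd of the readout noise; `Inf` makes every readout
#'   pure noise (the all-noise scenario).
#' @param activity_effect shift (sd units) of active compounds on the first
#'   planted subset.
#' @param n_compounds,prevalence compound-screen size and active fraction.
#' @param seed integer master seed.
#' @return a `sim_scenario` list including `planted_map` (readout ->
#'   feature subset), `group_effect_map` (group -> subset + shift) and
#'   `planted_pairs` (the ground-truth (readout, group) associations).
#' @export
sim_scenario <- function(n_features = 200L, n_readouts = 5L, n_planted = 4L,
                         subset_size = 8L, n_groups = 15L, group_size = 14L,
                         controls = 30L, delta = 1.5, readout_noise = 0.5,
                         activity_effect = 1.0, n_compounds = 400L,
                         prevalence = 0.35, seed = 1L) {
  stopifnot(n_features >= n_planted * subset_size, n_readouts >= n_planted,
            n_planted >= 1L, n_groups >= n_planted, group_size >= 1L,
            controls >= 1L, delta >= 0, activity_effect >= 0,
            prevalence > 0, prevalence < 1)
  feats <- sprintf("f%03d", seq_len(n_features))
  readouts <- sprintf("readout_%02d", seq_len(n_readouts))
  groups <- sprintf("process_%02d", seq_len(n_groups))

  pool <- with_preserved_rng({
    set.seed(derive_seed(seed, 1L))  # stream: subsets
    sample(feats, n_planted * subset_size)
  })
  planted_map <- stats::setNames(
    split(pool, rep(seq_len(n_planted), each = subset_size)),
    readouts[seq_len(n_planted)])
  weights <- with_preserved_rng({
    set.seed(derive_seed(seed, 2L))  # stream: weights
    stats::setNames(lapply(seq_len(n_planted), function(i)
      stats::runif(subset_size, 0.5, 1.5)), readouts[seq_len(n_planted)])
  })
  group_effect_map <- stats::setNames(
    lapply(seq_len(n_groups), function(g) {
      if (g <= n_planted) list(features = planted_map[[g]], shift = delta)
      else list(features = character(0), shift = 0)
    }), groups)
  planted_pairs <- if (delta > 0 && !is.infinite(readout_noise)) {
    data.frame(readout = readouts[seq_len(n_planted)],
               group = groups[seq_len(n_planted)])
  } else {
    data.frame(readout = character(0), group = character(0))
  }
  structure(list(n_features = as.integer(n_features), feature_names = feats,
                 n_readouts = as.integer(n_readouts),
                 readout_names = readouts,
                 n_planted = as.integer(n_planted),
                 subset_size = as.integer(subset_size),
                 n_groups = as.integer(n_groups), group_names = groups,
                 group_size = as.integer(group_size),
                 controls = as.integer(controls), delta = delta,
                 readout_noise = readout_noise, weights = weights,
                 planted_map = planted_map,
                 group_effect_map = group_effect_map,
                 planted_pairs = planted_pairs,
                 activity_effect = activity_effect,
                 n_compounds = as.integer(n_compounds),
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @rdname sim_scenario
#' @export
null_scenario <- function(seed = 1L, ...) {
  sim_scenario(delta = 0, readout_noise = Inf, seed = seed, ...)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("sim_scenario:", x$n_features, "features |", x$n_readouts,
      "readouts (", x$n_planted, "planted ) |", x$n_groups, "groups x",
      x$group_size, "+", x$controls, "controls | delta =", x$delta,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Generate a paired perturbation panel
#'
#' Draws the gene-perturbation-style dataset: profiles (controls + group
#' members, baseline standard normal with group shifts on planted subsets),
#' readouts (noisy linear functions of their planted subsets with weights
#' fixed per scenario), metadata and the readout annotation map. Fully
#' deterministic per scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `profiles` (`morph_table`), `readouts`
#'   (`health_table`), `meta` (`perturbation_meta`), `annotations`
#'   (readout -> level-1/level-2 map) and `truth` (planted maps and pairs).
#' @export
generate_crispr_panel <- function(scenario) {
  sc <- scenario
  n <- sc$controls + sc$n_groups * sc$group_size
  ids <- c(sprintf("ctrl_%03d", seq_len(sc$controls)),
           unlist(lapply(seq_len(sc$n_groups), function(g)
             sprintf("%s_rep%02d", sc$group_names[g], seq_len(sc$group_size)))))
  group_of <- c(rep("negative_control", sc$controls),
                rep(sc$group_names, each = sc$group_size))

  X <- with_preserved_rng({
    set.seed(derive_seed(sc$seed, 3L))  # stream: features
    matrix(stats::rnorm(n * sc$n_features), n, sc$n_features)
  })
  dimnames(X) <- list(ids, sc$feature_names)
  for (g in sc$group_names) {
    eff <- sc$group_effect_map[[g]]
    if (length(eff$features) && eff$shift != 0) {
      X[group_of == g, eff$features] <- X[group_of == g, eff$features] +
        eff$shift
    }
  }

  Y <- with_preserved_rng({
    set.seed(derive_seed(sc$seed, 4L))  # stream: readout noise
    out <- matrix(NA_real_, n, sc$n_readouts,
                  dimnames = list(ids, sc$readout_names))
    for (r in sc$readout_names) {
      if (!is.infinite(sc$readout_noise) && r %in% names(sc$planted_map)) {
        signal <- X[, sc$planted_map[[r]], drop = FALSE] %*% sc$weights[[r]]
        out[, r] <- signal + stats::rnorm(n, sd = sc$readout_noise)
      } else {
        out[, r] <- stats::rnorm(n)
      }
    }
    out
  })

  meta <- perturbation_meta(data.frame(
    row_id = ids,
    perturbation_id = sub("_rep[0-9]+$", "", ids),
    cell_line = "simulated",
    group_label = group_of,
    is_negative_control = group_of == "negative_control"))
  annotations <- data.frame(
    readout_name = sc$readout_names,
    level1_assay = ifelse(seq_len(sc$n_readouts) %% 2L == 1L,
                          "viability", "cell_cycle"),
    level2_measurement = ifelse(seq_len(sc$n_readouts) %% 2L == 1L,
                                "intensity", "count"))
  list(profiles = morph_table(X), readouts = health_table(Y), meta = meta,
       annotations = annotations,
       truth = list(planted_map = sc$planted_map,
                    group_effect_map = sc$group_effect_map,
                    planted_pairs = sc$planted_pairs))
}

#' Generate a compound activity screen
#'
#' Baseline standard-normal profiles; a `prevalence` fraction of compounds
#' is active and shifted by `activity_effect` sd on the first planted
#' subset, so activity is carried by the features of exactly one synthetic
#' term.
#'
#' @param scenario a [sim_scenario()].
#' @param screen_seed seed for the screen's own draws (labels and feature
#'   noise); defaults to the scenario seed. Varying it draws independent
#'   screens against the same planted truth.
#' @param active_readout index (or name) of the planted readout whose
#'   feature subset carries the activity effect; default the first.
#' @return list with `profiles` (`morph_table`), `labels` (named 0/1
#'   integer vector) and `truth` (`active_subset`, `effect`).
#' @export
generate_compound_screen <- function(scenario, screen_seed = scenario$seed,
                                     active_readout = 1L) {
  sc <- scenario
  sc$seed <- as.integer(screen_seed)
  n <- sc$n_compounds
  n_active <- round(sc$prevalence * n)
  if (min(n_active, n - n_active) < 8L) {
    stop("prevalence leaves < 8 samples in the minority class", call. = FALSE)
  }
  ids <- sprintf("cpd_%04d", seq_len(n))
  labels <- with_preserved_rng({
    set.seed(derive_seed(sc$seed, 5L))  # stream: labels
    l <- stats::setNames(integer(n), ids)
    l[sample.int(n, n_active)] <- 1L
    l
  })
  X <- with_preserved_rng({
    set.seed(derive_seed(sc$seed, 6L))  # stream: screen features
    matrix(stats::rnorm(n * sc$n_features), n, sc$n_features)
  })
  dimnames(X) <- list(ids, sc$feature_names)
  subset <- sc$planted_map[[active_readout]]
  if (is.null(subset)) stop("active_readout is not a planted readout",
                            call. = FALSE)
  if (sc$activity_effect != 0) {
    X[labels == 1L, subset] <- X[labels == 1L, subset] + sc$activity_effect
  }
  list(profiles = morph_table(X), labels = labels,
       truth = list(active_subset = subset, effect = sc$activity_effect))
}

#' Write a simulated dataset to disk
#'
#' Writes the panel tables (profiles, readouts, metadata, annotations), the
#' compound screen and a ground-truth JSON of the planted maps, for use by
#' external harnesses and the command-line interface.
#'
#' @param scenario a [sim_scenario()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_simulated <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- generate_crispr_panel(scenario)
  screen <- generate_compound_screen(scenario)
  files <- c(
    profiles = file.path(dir, "crispr_profiles.csv"),
    readouts = file.path(dir, "crispr_readouts.csv"),
    meta = file.path(dir, "crispr_meta.csv"),
    annotations = file.path(dir, "readout_annotations.csv"),
    screen = file.path(dir, "compound_profiles.csv"),
    labels = file.path(dir, "compound_labels.csv"),
    truth = file.path(dir, "ground_truth.json"))
  write_table(panel$profiles, files[["profiles"]])
  write_table(panel$readouts, files[["readouts"]])
  utils::write.csv(panel$meta, files[["meta"]], row.names = FALSE)
  utils::write.csv(panel$annotations, files[["annotations"]], row.names = FALSE)
  write_table(screen$profiles, files[["screen"]])
  utils::write.csv(data.frame(row_id = names(screen$labels),
                              active = unname(screen$labels)),
                   files[["labels"]], row.names = FALSE)
  truth <- list(planted_map = panel$truth$planted_map,
                planted_pairs = panel$truth$planted_pairs,
                active_subset = screen$truth$active_subset,
                effect = screen$truth$effect,
                seed = scenario$seed)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, pretty = TRUE),
             files[["truth"]])
  invisible(files)
}
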