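#' Read a skeleton from an SWC file
#'
#' Standard 7-column SWC dialect: `id type x y z radius parent`, `#`
#' comments and blank lines allowed, 1-based ids, `parent = -1` for
#' roots (multi-root forests accepted). Type codes 2 (axon) and 3
#' (dendrite) set the compartment; mixed or other codes default to the
#' majority compartment.
#'
#' @param path SWC file path.
#' @param neuron_id Identifier to attach (default the file name).
#' @return A [skeleton()]; coordinates are taken as um.
#' @export
read_swc <- function(path, neuron_id = sub("\\.swc$", "", basename(path))) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lines[keep]
  if (length(rows) == 0L) stop("no data rows in ", path, call. = FALSE)
  parsed <- lapply(seq_along(rows), function(k) {
    f <- strsplit(trimws(rows[k]), "\\s+")[[1]]
    if (length(f) != 7L || anyNA(suppressWarnings(as.numeric(f)))) {
      stop(sprintf("malformed SWC row at line %d of %s",
                   which(keep)[k], path), call. = FALSE)
    }
    as.numeric(f)
  })
  m <- do.call(rbind, parsed)
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  id_map <- match(m[, "parent"], m[, "id"])
  has_parent <- m[, "parent"] != -1
  if (any(has_parent & is.na(id_map))) {
    stop("SWC parent id not found in ", path, call. = FALSE)
  }
  edges <- cbind(which(has_parent), id_map[has_parent])
  types <- m[, "type"]
  compartment <- if (sum(types == 2) >= sum(types == 3)) "axon" else
    "dendrite"
  skel <- skeleton(m[, c("x", "y", "z")],
                   matrix(edges, ncol = 2L), compartment, neuron_id)
  skel$swc <- m
  skel
}

#' Write a skeleton to an SWC file
#'
#' Emits the standard 7 columns; the skeleton's edges are converted to a
#' parent forest by breadth-first traversal from each component root.
#' Round-trips through [read_swc()] losslessly for vertices, edges and
#' compartment.
#'
#' @param skel A [skeleton()].
#' @param path Output path.
#' @param radius Radius column value (default 0.1).
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path, radius = 0.1) {
  n <- nrow(skel$vertices)
  adj <- vector("list", n)
  for (e in seq_len(nrow(skel$edges))) {
    i <- skel$edges[e, 1L]; j <- skel$edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(-1L, n)
  visited <- rep(FALSE, n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    queue <- root
    visited[root] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
  }
  type <- if (skel$compartment == "axon") 2L else 3L
  out <- sprintf("%d %d %.6f %.6f %.6f %.3f %d",
                 seq_len(n), type,
                 skel$vertices[, 1L], skel$vertices[, 2L],
                 skel$vertices[, 3L], radius, parent)
  writeLines(c("# SWC export", out), path)
  invisible(path)
}

#' Run the full synthetic like-to-like pipeline
#'
#' Generates a population and anatomy from a config, assigns cohorts,
#' fits the axonal-scale, joint and synaptic-scale models for the
#' requested metric, runs the paired cohort tests, the centered-binning
#' summaries, and the common-input (rho) analysis, and optionally writes
#' the tables to an output directory along with a ground-truth YAML
#' sidecar and a run manifest.
#'
#' @param config A [synthetic_config()].
#' @param metric Similarity metric for the single-metric models.
#' @param out_dir Optional directory for CSV/YAML outputs.
#' @param method Model backend (`"glm"` fallback by default; `"glmm"`
#'   for Laplace random intercepts).
#' @param n_boot Bootstrap resamples for the bin summaries.
#' @return List with `population`, `anatomy`, `pairs` (with cohorts),
#'   `fits`, `slopes`, `cohort_tests`, `bins`, `rho`, `rho_test`.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         metric = "sim_feature", out_dir = NULL,
                         method = "glm", n_boot = 200) {
  pop <- generate_population(config)
  anat <- generate_anatomy(pop)
  pairs <- anat$pairs
  cohorts <- do.call(rbind, lapply(unique(pairs$pre_id), function(i)
    build_cohorts(i, pop$neurons, pairs, target_region = c("V1", "HVA"))))
  pairs$cohort <- cohorts$cohort[match(
    paste(pairs$pre_id, pairs$post_id),
    paste(cohorts$presyn_id, cohorts$post_id))]
  fits <- list(
    axonal = fit_ld_model(pairs, metric, method = method),
    joint = fit_nsyn_model(pairs, metric, method = method),
    synaptic = fit_density_model(pairs[pairs$ld_um > 0, ], metric,
                                 method = method))
  slopes <- do.call(rbind, lapply(fits, conditional_slopes))
  admissible <- filter_projections(pairs)
  slopes$admissible <- slopes$projection %in% admissible |
    slopes$scale != "synaptic"
  cohort_tests <- paired_cohort_test(pairs, metric = metric)
  bins <- list(
    ld = center_and_bin(pairs, "ld", metric, n_boot = n_boot),
    density = center_and_bin(pairs, "density", metric, n_boot = n_boot))
  set.seed(config$seed + 3L)
  rho <- rho_analysis(pairs, feature_sim_lookup(pop$features))
  rho_test <- compare_rho(rho)
  out <- list(population = pop, anatomy = anat, pairs = pairs,
              fits = fits, slopes = slopes, cohort_tests = cohort_tests,
              bins = bins, rho = rho, rho_test = rho_test,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pop$neurons, file.path(out_dir, "neurons.csv"),
                     row.names = FALSE)
    utils::write.csv(pairs, file.path(out_dir, "pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(slopes, file.path(out_dir, "slopes.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort_tests, file.path(out_dir, "cohort_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(rho, file.path(out_dir, "rho_results.csv"),
                     row.names = FALSE)
    truth <- anat$truth
    truth$beta_axonal <- as.list(truth$beta_axonal)
    truth$beta_synaptic <- as.list(truth$beta_synaptic)
    truth$target_community <- as.list(truth$target_community)
    truth$u_axonal <- as.list(truth$u_axonal)
    truth$u_synaptic <- as.list(truth$u_synaptic)
    truth$community <- as.list(truth$community)
    truth$tweedie <- list(xi = truth$tweedie$xi, phi = truth$tweedie$phi)
    yaml::write_yaml(truth, file.path(out_dir, "ground_truth.yaml"))
    manifest <- list(
      package = "likewire",
      version = as.character(utils::packageVersion("likewire")),
      seed = config$seed, metric = metric, method = method,
      n_pairs = nrow(pairs), timestamp = format(Sys.time(), tz = "UTC"))
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  out
}
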