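#' Construct a neuron skeleton
#'
#' A skeleton is a piecewise-linear arbor: 3D vertices (micrometres) and
#' undirected edges between them, labelled as axonal or dendritic
#' compartment. Edges must connect distinct, valid vertices.
#'
#' @param vertices Numeric matrix, n x 3, coordinates in um.
#' @param edges Integer matrix, m x 2, 1-based vertex indices.
#' @param compartment `"axon"` or `"dendrite"`.
#' @param neuron_id Identifier carried through downstream tables.
#' @return Object of class `skeleton`.
#' @export
skeleton <- function(vertices, edges, compartment = c("axon", "dendrite"),
                     neuron_id = NA) {
  compartment <- match.arg(compartment)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3", call. = FALSE)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > nrow(vertices))) {
      stop("edge indices out of range", call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loop edges are not allowed", call. = FALSE)
    }
  }
  structure(list(vertices = vertices, edges = edges,
                 compartment = compartment, neuron_id = neuron_id),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %s, %d vertices, %d edges, cable %.2f um\n",
              x$compartment, nrow(x$vertices), nrow(x$edges),
              cable_length(x)))
  invisible(x)
}

#' Edge lengths of a skeleton
#' @param skel A [skeleton()].
#' @return Numeric vector of Euclidean edge lengths (um).
#' @export
edge_lengths <- function(skel) {
  if (nrow(skel$edges) == 0L) return(numeric(0))
  d <- skel$vertices[skel$edges[, 1L], , drop = FALSE] -
    skel$vertices[skel$edges[, 2L], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Total cable length of a skeleton
#' @param skel A [skeleton()].
#' @return Total edge length in um.
#' @export
cable_length <- function(skel) sum(edge_lengths(skel))

#' Discretize a skeleton so no edge exceeds a maximum length
#'
#' Subdivides every edge longer than `max_edge` into equal sub-edges whose
#' interior vertices lie on the original segment, preserving total cable
#' length exactly (up to floating point). Zero-length edges are dropped
#' with a warning.
#'
#' @param skel A [skeleton()].
#' @param max_edge Maximum allowed edge length (um), default 1.
#' @return A discretized [skeleton()].
#' @export
discretize_skeleton <- function(skel, max_edge = 1) {
  stopifnot(inherits(skel, "skeleton"), max_edge > 0)
  len <- edge_lengths(skel)
  if (any(len == 0)) {
    warning("dropping ", sum(len == 0), " zero-length edge(s)")
    skel$edges <- skel$edges[len > 0, , drop = FALSE]
    len <- len[len > 0]
  }
  if (all(len <= max_edge)) return(skel)
  verts <- skel$vertices
  new_edges <- vector("list", nrow(skel$edges))
  extra <- list()
  n_vert <- nrow(verts)
  for (e in seq_len(nrow(skel$edges))) {
    i <- skel$edges[e, 1L]; j <- skel$edges[e, 2L]
    k <- ceiling(len[e] / max_edge)
    if (k <= 1L) {
      new_edges[[e]] <- c(i, j)
    } else {
      t <- seq_len(k - 1L) / k
      mids <- outer(1 - t, verts[i, ]) + outer(t, verts[j, ])
      ids <- n_vert + seq_len(k - 1L)
      n_vert <- n_vert + k - 1L
      extra[[length(extra) + 1L]] <- mids
      chain <- c(i, ids, j)
      new_edges[[e]] <- cbind(chain[-length(chain)], chain[-1L])
    }
  }
  verts <- rbind(verts, do.call(rbind, extra))
  edges <- do.call(rbind, lapply(new_edges, function(x)
    if (is.null(dim(x))) matrix(x, ncol = 2L) else x))
  skeleton(verts, edges, skel$compartment, skel$neuron_id)
}

#' Find proximal vertex pairs between two skeletons (grid spatial index)
#'
#' Returns all pairs of vertices, one from each skeleton, whose Euclidean
#' distance is at most `radius` (closed ball). Uses a uniform-grid spatial
#' hash with cell size `radius`, so only the 27 neighbouring cells of each
#' query vertex are examined; results are identical to the brute-force
#' all-pairs computation.
#'
#' @param a,b [skeleton()] objects (order is arbitrary for the pair set).
#' @param radius Proximity radius in um, default 5.
#' @return Integer matrix with columns `a_vertex`, `b_vertex` (possibly
#'   zero rows), one row per proximal pair.
#' @export
find_proximities <- function(a, b, radius = 5) {
  stopifnot(inherits(a, "skeleton"), inherits(b, "skeleton"), radius > 0)
  va <- a$vertices; vb <- b$vertices
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("a_vertex", "b_vertex")))
  if (nrow(va) == 0L || nrow(vb) == 0L) return(out)
  cell <- function(v) floor(v / radius)
  key <- function(cv) paste(cv[, 1L], cv[, 2L], cv[, 3L], sep = "|")
  ca <- cell(va)
  buckets <- split(seq_len(nrow(va)), key(ca))
  cb <- cell(vb)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  r2 <- radius^2
  res_a <- vector("list", nrow(vb))
  res_b <- vector("list", nrow(vb))
  for (j in seq_len(nrow(vb))) {
    neigh_keys <- key(sweep(offs, 2L, cb[j, ], `+`))
    cand <- unlist(buckets[neigh_keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    d2 <- (va[cand, 1L] - vb[j, 1L])^2 + (va[cand, 2L] - vb[j, 2L])^2 +
      (va[cand, 3L] - vb[j, 3L])^2
    hit <- cand[d2 <= r2]
    if (length(hit)) {
      res_a[[j]] <- hit
      res_b[[j]] <- rep.int(j, length(hit))
    }
  }
  ia <- unlist(res_a, use.names = FALSE)
  ib <- unlist(res_b, use.names = FALSE)
  if (length(ia) == 0L) return(out)
  m <- cbind(a_vertex = ia, b_vertex = ib)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Brute-force proximal vertex pairs (oracle)
#'
#' All-pairs O(n*m) reference for [find_proximities()]; used to verify the
#' spatial index on random scenes.
#' @inheritParams find_proximities
#' @return Same format as [find_proximities()].
#' @export
find_proximities_brute <- function(a, b, radius = 5) {
  va <- a$vertices; vb <- b$vertices
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("a_vertex", "b_vertex")))
  if (nrow(va) == 0L || nrow(vb) == 0L) return(out)
  r2 <- radius^2
  res <- lapply(seq_len(nrow(vb)), function(j) {
    d2 <- (va[, 1L] - vb[j, 1L])^2 + (va[, 2L] - vb[j, 2L])^2 +
      (va[, 3L] - vb[j, 3L])^2
    hit <- which(d2 <= r2)
    if (length(hit)) cbind(hit, j) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(out)
  m <- cbind(a_vertex = as.integer(res[, 1L]),
             b_vertex = as.integer(res[, 2L]))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Axon-dendrite co-travel distance (Ld)
#'
#' Ld is the total length of dendritic cable travelling within `radius` of
#' the axon: both skeletons are discretized to at most 1 um edges, the
#' proximal vertex pairs are found, and the lengths of dendritic edges with
#' at least one endpoint in the proximal vertex set are summed (each edge
#' counted once). Returns the proximity object used downstream for synapse
#' assignment.
#'
#' @param axon Axonal [skeleton()] of the presynaptic neuron.
#' @param dend Dendritic [skeleton()] of the candidate partner.
#' @param radius Proximity radius in um (default 5).
#' @param max_edge Discretization bound in um (default 1).
#' @return Object of class `proximity` with fields `pre_id`, `post_id`,
#'   `ld_um`, `pairs` (proximal vertex pairs), `axon`, `dend` (the
#'   discretized skeletons), and `radius`.
#' @export
compute_ld <- function(axon, dend, radius = 5, max_edge = 1) {
  stopifnot(axon$compartment == "axon", dend$compartment == "dendrite")
  axon <- discretize_skeleton(axon, max_edge)
  dend <- discretize_skeleton(dend, max_edge)
  pairs <- find_proximities(axon, dend, radius)
  ld <- 0
  if (nrow(pairs) > 0L) {
    prox_dend <- unique(pairs[, 2L])
    len <- edge_lengths(dend)
    touch <- dend$edges[, 1L] %in% prox_dend | dend$edges[, 2L] %in% prox_dend
    ld <- sum(len[touch])
  }
  structure(list(pre_id = axon$neuron_id, post_id = dend$neuron_id,
                 ld_um = ld, pairs = pairs, axon = axon, dend = dend,
                 radius = radius),
            class = "proximity")
}

#' @export
print.proximity <- function(x, ...) {
  cat(sprintf("<proximity> pre %s -> post %s: Ld = %.3f um, %d proximal pairs\n",
              x$pre_id, x$post_id, x$ld_um, nrow(x$pairs)))
  invisible(x)
}

#' Assign synapses to an axon-dendrite proximity
#'
#' A synapse belongs to the proximity if its position lies within `radius`
#' (default 3 um) of any proximal vertex -- of either skeleton, the union
#' of the proximal pair set. Synapses whose pre/post ids do not match the
#' proximity are rejected; synapses farther than the radius are flagged
#' unassigned.
#'
#' @param synapses Data frame with columns `synapse_id, pre_id, post_id,
#'   x_um, y_um, z_um, cleft_volume_voxels`.
#' @param prox A `proximity` from [compute_ld()].
#' @param radius Assignment radius in um (default 3).
#' @return The proximity with `synapses` (data frame gaining a logical
#'   `assigned` column) attached.
#' @export
assign_synapses <- function(synapses, prox, radius = 3) {
  stopifnot(inherits(prox, "proximity"))
  req <- c("synapse_id", "pre_id", "post_id", "x_um", "y_um", "z_um")
  if (!all(req %in% names(synapses))) {
    stop("`synapses` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  bad <- synapses$pre_id != prox$pre_id | synapses$post_id != prox$post_id
  if (any(bad)) {
    stop(sum(bad), " synapse(s) do not match the proximity's pre/post ids",
         call. = FALSE)
  }
  if (nrow(prox$pairs) == 0L) {
    synapses$assigned <- rep(FALSE, nrow(synapses))
  } else {
    pv <- rbind(prox$axon$vertices[unique(prox$pairs[, 1L]), , drop = FALSE],
                prox$dend$vertices[unique(prox$pairs[, 2L]), , drop = FALSE])
    pos <- as.matrix(synapses[, c("x_um", "y_um", "z_um")])
    synapses$assigned <- vapply(seq_len(nrow(pos)), function(i) {
      d2 <- (pv[, 1L] - pos[i, 1L])^2 + (pv[, 2L] - pos[i, 2L])^2 +
        (pv[, 3L] - pos[i, 3L])^2
      any(d2 <= radius^2)
    }, logical(1))
  }
  prox$synapses <- synapses
  prox
}

#' Projection type of a neuron pair
#'
#' Maps (presynaptic area, postsynaptic area) to the four projection
#' classes used throughout the analysis: V1 intra-area, HVA intra-area,
#' feedforward (V1 to HVA) and feedback (HVA to V1). The higher visual
#' areas AL and RL are pooled into HVA.
#'
#' @param pre_area,post_area Character vectors over `{V1, AL, RL, HVA}`.
#' @param pre_layer,post_layer Optional layer labels; when both given, an
#'   `area_layer` attribute-style refinement `"V1-L4->HVA-L2/3"` etc. is
#'   returned instead of the 4-way label.
#' @return Factor with levels `V1->V1, HVA->HVA, V1->HVA, HVA->V1` (or a
#'   character vector of area-layer labels).
#' @export
projection_type <- function(pre_area, post_area,
                            pre_layer = NULL, post_layer = NULL) {
  to_group <- function(a) {
    g <- ifelse(a == "V1", "V1", ifelse(a %in% c("AL", "RL", "HVA"), "HVA",
                                        NA_character_))
    if (anyNA(g)) stop("unknown area: ",
                       paste(unique(a[is.na(g)]), collapse = ", "),
                       call. = FALSE)
    g
  }
  g1 <- to_group(pre_area); g2 <- to_group(post_area)
  if (!is.null(pre_layer) && !is.null(post_layer)) {
    return(paste0(g1, "-", pre_layer, "->", g2, "-", post_layer))
  }
  factor(paste0(g1, "->", g2),
         levels = c("V1->V1", "HVA->HVA", "V1->HVA", "HVA->V1"))
}

#' Assign anatomical cohorts for one presynaptic neuron
#'
#' Candidates failing the functional inclusion thresholds (CCmax > 0.4 and
#' CCabs > 0.2 by default) are excluded. Among included candidates:
#' `connected` have at least one synapse; `adp_control` have axon-dendrite
#' proximity (Ld > 0) but no synapse; `same_region_control` have no
#' proximity, no synapse, and sit in the same region as the postsynaptic
#' target region. A candidate qualifying for both controls goes to the ADP
#' control (precedence rule).
#'
#' @param presyn_id Presynaptic neuron id.
#' @param neurons Neuron table with `neuron_id, area, cc_max, cc_abs`.
#' @param pairs Pair table with `pre_id, post_id, ld_um, nsyn`.
#' @param target_region Region(s) defining the same-region pool; defaults
#'   to the regions of the connected postsynaptic targets.
#' @param cc_max_min,cc_abs_min Inclusion thresholds (defaults 0.4, 0.2).
#' @return Data frame `post_id, cohort` with cohort in
#'   `{connected, adp_control, same_region_control, excluded}`.
#' @export
build_cohorts <- function(presyn_id, neurons, pairs, target_region = NULL,
                          cc_max_min = 0.4, cc_abs_min = 0.2) {
  if (!presyn_id %in% pairs$pre_id) {
    stop("presyn ", presyn_id, " absent from pair table", call. = FALSE)
  }
  p <- pairs[pairs$pre_id == presyn_id, , drop = FALSE]
  idx <- match(p$post_id, neurons$neuron_id)
  if (anyNA(idx)) stop("candidate neurons missing from neuron table",
                       call. = FALSE)
  nb <- neurons[idx, , drop = FALSE]
  region_of <- function(a) ifelse(a == "V1", "V1", "HVA")
  if (is.null(target_region)) {
    target_region <- unique(region_of(nb$area[p$nsyn > 0]))
  }
  included <- nb$cc_max > cc_max_min & nb$cc_abs > cc_abs_min
  cohort <- rep("excluded", nrow(p))
  conn <- included & p$nsyn >= 1
  adp <- included & !conn & p$ld_um > 0
  same <- included & !conn & !adp & region_of(nb$area) %in% target_region
  cohort[conn] <- "connected"
  cohort[adp] <- "adp_control"
  cohort[same] <- "same_region_control"
  data.frame(presyn_id = presyn_id, post_id = p$post_id, cohort = cohort,
             stringsAsFactors = FALSE)
}
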