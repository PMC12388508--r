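# farthest-point (maximin) seeding: first centre is the point farthest from
# the grand mean, each next centre the point maximizing its minimum distance
# to the centres chosen so far; deterministic given the data
maximin_centers <- function(coords, k) {
  d0 <- rowSums(sweep(coords, 2, colMeans(coords))^2)
  idx <- which.max(d0)
  mind <- rowSums(sweep(coords, 2, coords[idx[1], ])^2)
  while (length(idx) < k) {
    nxt <- which.max(mind)
    idx <- c(idx, nxt)
    mind <- pmin(mind, rowSums(sweep(coords, 2, coords[nxt, ])^2))
  }
  coords[idx, , drop = FALSE]
}

# best of: n_init random starts (stats::kmeans multi-start) and one
# deterministic maximin-seeded run; random starts alone routinely miss the
# global optimum when k equals the number of tight well-separated clumps
best_kmeans <- function(coords, k, n_init, max_iter) {
  if (k == nrow(coords)) {
    # one atom per cluster: the exact optimum, which stats::kmeans refuses
    return(structure(list(cluster = seq_len(k), centers = coords,
                          totss = sum(scale(coords, scale = FALSE)^2),
                          withinss = rep(0, k), tot.withinss = 0,
                          size = rep(1L, k)),
                     class = "kmeans"))
  }
  fit_r <- suppressWarnings(
    kmeans(coords, centers = k, nstart = n_init, iter.max = max_iter)
  )
  fit_m <- tryCatch(
    suppressWarnings(
      kmeans(coords, centers = maximin_centers(coords, k), iter.max = max_iter)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit_m) && fit_m$tot.withinss < fit_r$tot.withinss) fit_m else fit_r
}

#' K-means scan over ligand-atom coordinates
#'
#' Clusters the 3D coordinates of superligand atoms for every cluster count
#' in `k_grid` (the published protocol scans 200 to 400 in steps of 10) and
#' records, per k: the total within-cluster sum of squares (WCSS), the
#' uniqueness score (fraction of cluster x complex pairs holding at most one
#' atom) and the occupancy score (fraction holding exactly one atom). Each
#' run is seeded deterministically from `seed` and uses `n_init` random
#' starts.
#'
#' @param atoms Tibble with `x`, `y`, `z` and a `complex` column naming the
#'   source complex of each atom (a [build_superligand()] output qualifies).
#' @param k_grid Integer vector of cluster counts to evaluate.
#' @param seed Integer seed; run for grid entry i is seeded `seed + i`.
#' @param n_init Random initializations per run.
#' @param max_iter Maximum k-means iterations.
#' @return An object of class `atom_cluster_scan`: tibble with one row per k
#'   (`k`, `wcss`, `uniqueness`, `occupancy`, `fit` list column of `kmeans`
#'   objects), retaining `atoms` as an attribute.
#' @export
cluster_ligand_atoms <- function(atoms, k_grid, seed = 1L, n_init = 50L,
                                 max_iter = 50L) {
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  M <- nrow(coords)
  if (any(k_grid > M)) {
    abort(paste0("k = ", max(k_grid), " exceeds the number of atoms (", M, ")"))
  }
  scan <- purrr::imap(k_grid, function(k, i) {
    set.seed(seed + i)
    fit <- best_kmeans(coords, k, n_init, max_iter)
    occ <- table(factor(fit$cluster, levels = seq_len(k)), atoms$complex)
    tibble(k = k, wcss = fit$tot.withinss,
           uniqueness = mean(occ <= 1), occupancy = mean(occ == 1),
           fit = list(fit))
  }) %>% bind_rows()
  structure(scan, class = c("atom_cluster_scan", class(scan)),
            atoms = atoms, seed = seed)
}

#' Choose the cluster count from a k-means scan
#'
#' Among cluster counts whose uniqueness score (fraction of cluster x complex
#' pairs with at most one atom) meets `uniqueness_floor`, picks the k
#' maximizing occupancy (fraction of pairs with exactly one atom — the
#' protocol's "one ligand atom per structure per cluster" ideal applied in
#' both directions), breaking ties by minimal WCSS and then by smaller k.
#' The rule and floor are explicit configuration; see the methods vignette
#' for why occupancy rather than WCSS alone drives the choice.
#'
#' @param scan An `atom_cluster_scan` (or any tibble with `k`, `wcss`,
#'   `uniqueness`, `occupancy`).
#' @param uniqueness_floor Minimum admissible uniqueness (default 0.95).
#' @return The selected k (integer).
#' @export
select_k <- function(scan, uniqueness_floor = 0.95) {
  ok <- scan[scan$uniqueness >= uniqueness_floor, , drop = FALSE]
  if (nrow(ok) == 0) {
    abort(paste0("no k meets uniqueness floor ", uniqueness_floor,
                 "; best attainable uniqueness is ",
                 format(max(scan$uniqueness), digits = 4), " at k = ",
                 scan$k[which.max(scan$uniqueness)]))
  }
  ok <- ok[order(-ok$occupancy, ok$wcss, ok$k), , drop = FALSE]
  as.integer(ok$k[1])
}

#' Final ligand-atom clustering at a chosen k
#'
#' Refits k-means at the selected cluster count with a larger number of
#' random starts (the published final fit uses 500 repetitions, 100
#' iterations) and returns the atoms annotated with their cluster id plus a
#' per-cluster summary (size, centroid, small-molecule atom fraction banded
#' low / mixed / high at 0.3 and 0.7).
#'
#' @param atoms Superligand atom tibble (`x`, `y`, `z`, `complex`, and
#'   optionally `ltype`).
#' @param k Cluster count.
#' @param seed Integer seed.
#' @param n_init,max_iter Final-fit k-means controls.
#' @return List: `atoms` (input plus `cluster`), `clusters` (tibble
#'   `cluster`, `size`, `cx`, `cy`, `cz`, `sm_fraction`, `enrichment_band`),
#'   `fit` (the `kmeans` object).
#' @export
final_atom_clusters <- function(atoms, k, seed = 1L, n_init = 500L,
                                max_iter = 100L) {
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (k > nrow(coords)) abort("k exceeds the number of atoms")
  set.seed(seed)
  fit <- best_kmeans(coords, k, n_init, max_iter)
  atoms$cluster <- fit$cluster
  clusters <- atoms %>%
    group_by(.data$cluster) %>%
    summarise(size = n(),
              cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
              sm_fraction = if ("ltype" %in% names(atoms))
                mean(.data$ltype == "small_molecule") else NA_real_,
              .groups = "drop") %>%
    mutate(enrichment_band = dplyr::case_when(
      is.na(.data$sm_fraction) ~ NA_character_,
      .data$sm_fraction < 0.3 ~ "low",
      .data$sm_fraction > 0.7 ~ "high",
      TRUE ~ "mixed"
    ))
  list(atoms = atoms, clusters = clusters, fit = fit)
}

#' Identify residue/ligand-atom contacts per complex
#'
#' For each holo chain, finds every (residue, ligand atom) pair within
#' `cutoff` of each other, using only the chain's own co-crystallized
#' ligand(s), all in a common frame. Each record carries the complex, the
#' residue's aligned position, the ligand atom id and its atom-cluster id —
#' the four attributes of the published contact table. Apo chains contribute
#' no records.
#'
#' @param atoms Protein atom tibble in the reference frame (`chain_ref`,
#'   `resnum`, `icode`, `x`, `y`, `z`).
#' @param clustered_atoms Superligand atoms with a `cluster` column (see
#'   [final_atom_clusters()]): `atom_id`, `complex`, `cluster`, coordinates.
#' @param pos_map Position map to resolve aligned positions.
#' @param cutoff Angstrom threshold (default 4.5, inclusive).
#' @return Tibble of raw contact records: `complex`, `position`,
#'   `lig_atom_id`, `cluster`, `dist`.
#' @export
find_contacts <- function(atoms, clustered_atoms, pos_map, cutoff = 4.5) {
  purrr::map(unique(atoms$chain_ref), function(cr) {
    la <- clustered_atoms[clustered_atoms$complex == cr, , drop = FALSE]
    if (nrow(la) == 0) return(NULL)
    pa <- atoms[atoms$chain_ref == cr, , drop = FALSE]
    P <- as.matrix(pa[, c("x", "y", "z")])
    L <- as.matrix(la[, c("x", "y", "z")])
    d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
    hits <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    pm <- pos_map[pos_map$chain_ref == cr, , drop = FALSE]
    pos <- pm$aligned_pos[match(paste(pa$resnum[hits[, 1]], pa$icode[hits[, 1]]),
                                paste(pm$resnum, pm$icode))]
    tibble(complex = cr,
           position = pos,
           lig_atom_id = la$atom_id[hits[, 2]],
           cluster = la$cluster[hits[, 2]],
           dist = sqrt(pmax(d2[hits], 0))) %>%
      filter(!is.na(.data$position))
  }) %>% bind_rows()
}

#' Aggregate raw contacts into recurrence-filtered edges
#'
#' Deduplicates the raw atom-level records to (aligned position, atom
#' cluster) pairs, computes each pair's frequency as the number of distinct
#' supporting complexes over `n_complexes`, and retains pairs present in
#' strictly more than `min_fraction` of complexes (a contact seen in exactly
#' 10% of complexes is dropped).
#'
#' @param records Raw contact records from [find_contacts()].
#' @param n_complexes Number of complexes in the dataset.
#' @param min_fraction Strict recurrence threshold (default 0.10).
#' @return Edge tibble: `position`, `cluster`, `n_support`, `frequency`,
#'   sorted by position then cluster (independent of record order).
#' @export
aggregate_contacts <- function(records, n_complexes, min_fraction = 0.10) {
  if (nrow(records) == 0) {
    return(tibble(position = integer(), cluster = integer(),
                  n_support = integer(), frequency = numeric()))
  }
  records %>%
    distinct(.data$position, .data$cluster, .data$complex) %>%
    count(.data$position, .data$cluster, name = "n_support") %>%
    mutate(frequency = .data$n_support / n_complexes) %>%
    filter(.data$frequency > min_fraction) %>%
    arrange(.data$position, .data$cluster)
}

#' Build the bipartite protein-ligand contact network
#'
#' Residue nodes (aligned positions, annotated with neqSL, variability
#' category and flexibility) on one side, ligand-atom-cluster nodes
#' (annotated with size and small-molecule enrichment) on the other; edges
#' are the recurrence-filtered contacts weighted by frequency.
#'
#' @param edges Edge tibble from [aggregate_contacts()].
#' @param profiles Optional per-position profiles ([position_profiles()]).
#' @param flexibility Optional per-position flexibility
#'   ([position_flexibility()]).
#' @param clusters Optional cluster summary ([final_atom_clusters()]
#'   `$clusters`).
#' @return An `igraph` bipartite graph (`type` FALSE for residues, TRUE for
#'   clusters).
#' @export
build_contact_network <- function(edges, profiles = NULL, flexibility = NULL,
                                  clusters = NULL) {
  res_ids <- sort(unique(edges$position))
  clu_ids <- sort(unique(edges$cluster))
  res_names <- paste0("pos", res_ids)
  clu_names <- paste0("clu", clu_ids)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(res_names, type = FALSE, kind = "residue",
                     position = res_ids) +
    igraph::vertices(clu_names, type = TRUE, kind = "cluster",
                     cluster = clu_ids)
  g <- igraph::add_edges(
    g, as.vector(rbind(paste0("pos", edges$position),
                       paste0("clu", edges$cluster)))
  )
  igraph::E(g)$frequency <- edges$frequency
  igraph::E(g)$n_support <- edges$n_support
  if (!is.null(profiles)) {
    idx <- match(res_ids, profiles$position)
    igraph::V(g)[res_names]$neq <- profiles$neq[idx]
    igraph::V(g)[res_names]$category <- profiles$category[idx]
  }
  if (!is.null(flexibility)) {
    idx <- match(res_ids, flexibility$position)
    igraph::V(g)[res_names]$mean_bnorm <- flexibility$mean_bnorm[idx]
    igraph::V(g)[res_names]$flex_class <- flexibility$flex_class[idx]
  }
  if (!is.null(clusters)) {
    idx <- match(clu_ids, clusters$cluster)
    igraph::V(g)[clu_names]$size <- clusters$size[idx]
    igraph::V(g)[clu_names]$enrichment_band <- clusters$enrichment_band[idx]
  }
  g
}

#' Per-class network metrics
#'
#' Summarises the contact network per residue class (e.g. rigid-variable,
#' flexible-variable, conserved): the mean over residues of their edge
#' count, the mean over edges of the contact frequency (conservation of the
#' link at the protein level), and the mean over edges of the connected
#' atom-cluster size (conservation at the ligand level), each with its
#' standard deviation.
#'
#' @param edges Edge tibble from [aggregate_contacts()].
#' @param position_classes Tibble `position`, `class` labelling every residue
#'   node.
#' @param cluster_sizes Tibble `cluster`, `size`.
#' @return Tibble with one row per class: `class`, `n_residues`,
#'   `avg_links`, `sd_links`, `avg_link_conservation`,
#'   `sd_link_conservation`, `avg_cluster_size`, `sd_cluster_size`. Classes
#'   with no residues yield an all-`NA` row.
#' @export
network_metrics <- function(edges, position_classes, cluster_sizes) {
  if (nrow(edges)) {
    annotated <- edges %>%
      left_join(position_classes, by = "position") %>%
      left_join(cluster_sizes, by = "cluster")
  } else {
    annotated <- tibble(position = integer(), cluster = integer(),
                        frequency = numeric(), class = character(),
                        size = numeric())
  }
  purrr::map(unique(position_classes$class), function(cl) {
    members <- position_classes$position[position_classes$class == cl]
    e <- annotated[!is.na(annotated$class) & annotated$class == cl, , drop = FALSE]
    if (length(members) == 0 || nrow(e) == 0) {
      return(tibble(class = cl, n_residues = length(members),
                    avg_links = NA_real_, sd_links = NA_real_,
                    avg_link_conservation = NA_real_,
                    sd_link_conservation = NA_real_,
                    avg_cluster_size = NA_real_, sd_cluster_size = NA_real_))
    }
    links <- purrr::map_int(members, function(p) sum(e$position == p))
    tibble(class = cl, n_residues = length(members),
           avg_links = mean(links), sd_links = sd(links),
           avg_link_conservation = mean(e$frequency),
           sd_link_conservation = sd(e$frequency),
           avg_cluster_size = mean(e$size),
           sd_cluster_size = sd(e$size))
  }) %>% bind_rows()
}

#' Write a contact network as GraphML plus node/edge TSVs
#'
#' @param g Bipartite `igraph` from [build_contact_network()].
#' @param stem Output path stem; writes `<stem>.graphml`,
#'   `<stem>_nodes.tsv`, `<stem>_edges.tsv`.
#' @return `stem`, invisibly.
#' @export
write_contact_network <- function(g, stem) {
  igraph::write_graph(g, paste0(stem, ".graphml"), format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  write.table(nodes, paste0(stem, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(edges, paste0(stem, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(stem)
}
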