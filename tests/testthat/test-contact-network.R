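test_that("k-means recovers separated triplets with the analytic WCSS", {
  # three triplets, each an equilateral-ish cluster with hand-computed WCSS
  pts <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),          # centroid (1/3, 1/3, 0)
    c(20, 0, 0), c(21, 0, 0), c(20, 1, 0),
    c(0, 20, 0), c(1, 20, 0), c(0, 21, 0)
  )
  atoms <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          complex = rep(c("c1", "c2", "c3"), times = 3))
  scan <- cluster_ligand_atoms(atoms, k_grid = 3, seed = 1, n_init = 10)
  fit <- scan$fit[[1]]
  expect_equal(length(unique(fit$cluster[1:3])), 1)
  expect_equal(length(unique(fit$cluster[4:6])), 1)
  expect_equal(length(unique(fit$cluster[7:9])), 1)
  # per-triplet WCSS: sum of squared distances to (1/3, 1/3, 0) = 4/3
  expect_equal(scan$wcss, 3 * 4 / 3, tolerance = 1e-9)
  # k = M: zero WCSS, full uniqueness
  scan_m <- cluster_ligand_atoms(atoms, k_grid = 9, seed = 1, n_init = 5)
  expect_equal(scan_m$wcss, 0, tolerance = 1e-12)
  expect_equal(scan_m$uniqueness, 1)
  expect_error(cluster_ligand_atoms(atoms, k_grid = 10, seed = 1), "exceeds")
})

test_that("final assignments are a fixed point: every atom at its nearest centroid", {
  set.seed(20)
  atoms <- tibble::tibble(x = runif(200, 0, 30), y = runif(200, 0, 30),
                          z = runif(200, 0, 30),
                          complex = sample(paste0("c", 1:10), 200, TRUE))
  fin <- final_atom_clusters(atoms, k = 5, seed = 2, n_init = 20)
  centers <- fin$fit$centers
  nearest <- apply(as.matrix(atoms[, c("x", "y", "z")]), 1, function(p) {
    which.min(colSums((t(centers) - p)^2))
  })
  expect_equal(unname(fin$atoms$cluster), unname(nearest))
  # objective is consistent: WCSS recomputed from assignments matches
  wcss <- sum(vapply(seq_len(5), function(k) {
    idx <- fin$atoms$cluster == k
    sum(sweep(as.matrix(atoms[idx, c("x", "y", "z")]), 2,
              centers[k, ])^2)
  }, numeric(1)))
  expect_equal(fin$fit$tot.withinss, wcss, tolerance = 1e-6)
})

test_that("select_k follows uniqueness floor then occupancy then WCSS dominance", {
  diag_tbl <- tibble::tibble(k = c(10, 20), wcss = c(10, 5),
                             uniqueness = c(0.99, 0.99), occupancy = c(0.9, 0.9))
  expect_equal(select_k(diag_tbl, uniqueness_floor = 0.95), 20)  # WCSS 5 wins
  diag_tbl2 <- tibble::tibble(k = c(10, 20), wcss = c(10, 5),
                              uniqueness = c(0.99, 0.5), occupancy = c(0.5, 0.9))
  expect_equal(select_k(diag_tbl2, uniqueness_floor = 0.95), 10)  # floor first
  diag_tbl3 <- tibble::tibble(k = c(10, 20), wcss = c(5, 5),
                              uniqueness = c(1, 1), occupancy = c(0.7, 0.9))
  expect_equal(select_k(diag_tbl3, uniqueness_floor = 0.95), 20)  # occupancy
  expect_error(select_k(diag_tbl2[2, ], uniqueness_floor = 0.95),
               "best attainable uniqueness")
})

test_that("the planted blob count is recovered from a k grid", {
  ls <- make_ligand_set(n_ligands = 12, n_blobs = 12, blocks = c(4, 4, 3, 1),
                        seed = 3)
  scan <- cluster_ligand_atoms(ls$atoms, k_grid = 6:20, seed = 5)
  expect_equal(select_k(scan), 12)
})

test_that("contact records match a brute-force triple loop", {
  set.seed(21)
  n_cpx <- 8
  atoms <- purrr::map(seq_len(n_cpx), function(i) {
    tibble::tibble(chain_ref = paste0("c", i), resnum = rep(1:10, each = 3),
                   icode = "", x = runif(30, 0, 15), y = runif(30, 0, 15),
                   z = runif(30, 0, 15))
  }) %>% dplyr::bind_rows()
  lig <- purrr::map(seq_len(n_cpx), function(i) {
    tibble::tibble(atom_id = (i - 1) * 5 + 1:5, complex = paste0("c", i),
                   cluster = sample(1:4, 5, TRUE),
                   x = runif(5, 0, 15), y = runif(5, 0, 15), z = runif(5, 0, 15))
  }) %>% dplyr::bind_rows()
  pm <- tidyr::crossing(chain_ref = paste0("c", 1:n_cpx), resnum = 1:10) %>%
    dplyr::mutate(aligned_pos = resnum, icode = "")
  rec <- find_contacts(atoms, lig, pm, cutoff = 4.5)
  # brute force over every (complex, protein atom, ligand atom) triple
  brute <- list()
  for (i in seq_len(nrow(atoms))) {
    for (j in seq_len(nrow(lig))) {
      if (atoms$chain_ref[i] != lig$complex[j]) next
      d <- sqrt(sum((unlist(atoms[i, c("x", "y", "z")]) -
                       unlist(lig[j, c("x", "y", "z")]))^2))
      if (d <= 4.5) {
        brute[[length(brute) + 1L]] <- paste(atoms$chain_ref[i],
                                             atoms$resnum[i], lig$atom_id[j])
      }
    }
  }
  expect_setequal(paste(rec$complex, rec$position, rec$lig_atom_id),
                  unlist(brute))
  # apo complex contributes nothing
  rec_apo <- find_contacts(atoms[atoms$chain_ref == "c1", ],
                           lig[lig$complex != "c1", ], pm)
  expect_equal(nrow(rec_apo), 0)
  # single exact pair
  a1 <- tibble::tibble(chain_ref = "z", resnum = 1L, icode = "",
                       x = 0, y = 0, z = 0)
  l1 <- tibble::tibble(atom_id = 1L, complex = "z", cluster = 7L,
                       x = 4.4, y = 0, z = 0)
  pm1 <- tibble::tibble(chain_ref = "z", resnum = 1L, aligned_pos = 1L, icode = "")
  r1 <- find_contacts(a1, l1, pm1)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$cluster, 7L)
})

test_that("edge sets shrink to empty as the cutoff goes to zero and grow with it", {
  set.seed(22)
  atoms <- tibble::tibble(chain_ref = "c1", resnum = 1:30, icode = "",
                          x = runif(30, 0, 10), y = runif(30, 0, 10),
                          z = runif(30, 0, 10))
  lig <- tibble::tibble(atom_id = 1:10, complex = "c1", cluster = 1:10,
                        x = runif(10, 0, 10), y = runif(10, 0, 10),
                        z = runif(10, 0, 10))
  pm <- tibble::tibble(chain_ref = "c1", resnum = 1:30, aligned_pos = 1:30,
                       icode = "")
  sizes <- vapply(c(0, 1, 2.5, 4.5, 8), function(ct) {
    nrow(find_contacts(atoms, lig, pm, cutoff = ct))
  }, numeric(1))
  expect_equal(sizes[1], 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("contact aggregation applies the strict >10% rule and ignores record order", {
  rec <- tibble::tibble(
    complex = c("c1", "c2", "c1", paste0("c", 1:2)),
    position = c(5L, 5L, 9L, 9L, 9L),
    cluster = c(1L, 1L, 2L, 3L, 3L),
    lig_atom_id = 1:5, dist = 4
  )
  # frequency exactly 0.10 is dropped; 0.2 retained
  out <- aggregate_contacts(rec, n_complexes = 10)
  expect_setequal(paste(out$position, out$cluster), c("5 1", "9 3"))
  expect_equal(out$frequency[out$position == 5], 0.2)
  out_1complex <- aggregate_contacts(rec[rec$complex == "c1" &
                                           rec$position == 9L &
                                           rec$cluster == 2L, ],
                                     n_complexes = 10)
  expect_equal(nrow(out_1complex), 0)
  set.seed(23)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_identical(aggregate_contacts(shuffled, 10), out)
  # duplicate atom-level records for one (complex, position, cluster) count once
  dup <- dplyr::bind_rows(rec, rec)
  expect_identical(aggregate_contacts(dup, 10), out)
})

test_that("planted recurrent contacts survive the filter and rare ones do not", {
  sc <- simulate_contact_records(n_complexes = 30, n_recurrent = 20,
                                 n_rare = 30, seed = 24)
  edges <- aggregate_contacts(sc$records, sc$n_complexes)
  expect_identical(dplyr::select(edges, position, cluster), sc$truth$recurrent)
  expect_equal(nrow(edges), 20)
  expect_true(all(edges$frequency > 0.10))
})

test_that("the contact network is bipartite with annotated nodes", {
  sc <- simulate_contact_records(seed = 25)
  edges <- aggregate_contacts(sc$records, sc$n_complexes)
  profiles <- tibble::tibble(position = unique(edges$position),
                             neq = runif(length(unique(edges$position)), 1, 5),
                             category = "variable")
  clusters <- tibble::tibble(cluster = unique(edges$cluster),
                             size = sample(5:50, length(unique(edges$cluster))),
                             enrichment_band = "mixed")
  g <- build_contact_network(edges, profiles, NULL, clusters)
  expect_true(igraph::is_bipartite(g))
  expect_equal(igraph::ecount(g), nrow(edges))
  types <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  ends <- igraph::ends(g, igraph::E(g))
  for (r in seq_len(nrow(ends))) {
    expect_true(xor(types[ends[r, 1]], types[ends[r, 2]]))
  }
  stem <- tempfile()
  write_contact_network(g, stem)
  expect_true(file.exists(paste0(stem, ".graphml")))
  g2 <- igraph::read_graph(paste0(stem, ".graphml"), format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
})

test_that("network metrics reproduce hand-computed and spreadsheet-style values", {
  # single residue with three edges
  edges <- tibble::tibble(position = c(7L, 7L, 7L), cluster = c(1L, 2L, 3L),
                          n_support = c(2L, 3L, 4L),
                          frequency = c(0.2, 0.3, 0.4))
  classes <- tibble::tibble(position = 7L, class = "variable")
  sizes <- tibble::tibble(cluster = 1:3, size = c(10, 20, 30))
  m <- network_metrics(edges, classes, sizes)
  expect_equal(m$avg_links, 3)
  expect_equal(m$avg_link_conservation, 0.3)
  expect_equal(m$avg_cluster_size, 20)

  # toy 6-residue / 4-cluster network recomputed independently
  set.seed(26)
  toy <- tibble::tibble(
    position = c(1L, 1L, 2L, 3L, 3L, 3L, 4L, 5L, 6L),
    cluster = c(1L, 2L, 2L, 1L, 3L, 4L, 4L, 3L, 2L),
    n_support = sample(2:9, 9, TRUE)
  ) %>% dplyr::mutate(frequency = n_support / 10)
  cls <- tibble::tibble(position = 1:6,
                        class = c("a", "a", "b", "b", "a", "b"))
  szs <- tibble::tibble(cluster = 1:4, size = c(5, 10, 15, 20))
  m2 <- network_metrics(toy, cls, szs)
  toy_a <- toy[toy$position %in% c(1, 2, 5), ]
  expect_equal(m2$avg_links[m2$class == "a"],
               mean(c(2, 1, 1)))
  expect_equal(m2$avg_link_conservation[m2$class == "a"],
               mean(toy_a$frequency))
  expect_equal(m2$avg_cluster_size[m2$class == "a"],
               mean(szs$size[match(toy_a$cluster, szs$cluster)]))
  expect_equal(m2$sd_cluster_size[m2$class == "b"],
               sd(szs$size[match(toy$cluster[toy$position %in% c(3, 4, 6)],
                                 szs$cluster)]))

  # class with zero residues and the empty edge set
  m3 <- network_metrics(toy, tibble::tibble(position = 99L, class = "ghost"), szs)
  expect_true(all(is.na(m3[, c("avg_links", "avg_cluster_size")])))
  m4 <- network_metrics(toy[0, ], cls, szs)
  expect_true(all(is.na(m4$avg_links)))
})

test_that("ligand-type enrichment bands follow the 0.3 / 0.7 thresholds", {
  atoms <- tibble::tibble(
    x = rep(c(0, 50, 100), each = 10) + runif(30, -0.1, 0.1),
    y = runif(30, -0.1, 0.1), z = runif(30, -0.1, 0.1),
    complex = rep(paste0("c", 1:10), 3),
    ltype = c(rep("small_molecule", 2), rep("peptide", 8),       # 0.2 -> low
              rep("small_molecule", 5), rep("peptide", 5),       # 0.5 -> mixed
              rep("small_molecule", 8), rep("peptide", 2))       # 0.8 -> high
  )
  fin <- final_atom_clusters(atoms, k = 3, seed = 4, n_init = 10)
  bands <- fin$clusters %>%
    dplyr::arrange(cx) %>%
    dplyr::pull(enrichment_band)
  expect_equal(bands, c("low", "mixed", "high"))
})
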