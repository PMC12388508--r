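#' Generate a synthetic structural-alphabet model
#'
#' Draws Gaussian emission means in descriptor space under a minimum
#' pairwise-separation constraint (in multiples of the emission standard
#' deviation), with isotropic covariances, near-uniform transitions with a
#' mild self-transition bias, and a uniform initial distribution. Used to
#' test decoding without the published alphabet parameters: with separation
#' >= 6 sigma, Viterbi decoding of descriptor sequences sampled from the
#' model recovers the generating letters essentially always.
#'
#' @param n_letters Number of letters (2 to 27; symbols are taken from the
#'   canonical `a, A..Z` labelling).
#' @param mean_separation Minimum pairwise mean distance, in multiples of
#'   `sigma`.
#' @param seed Integer seed (all randomness flows from it).
#' @param sigma Emission standard deviation (isotropic), Angstrom.
#' @param self_bias Extra self-transition mass (0..1).
#' @return An `alphabet_model`.
#' @export
make_alphabet <- function(n_letters, mean_separation = 6, seed = 1,
                          sigma = 0.3, self_bias = 0.2) {
  if (n_letters < 2 || n_letters > 27) abort("n_letters must be in 2..27")
  set.seed(seed)
  lo <- c(4.5, 4.5, 4.5, -4); hi <- c(7.5, 11, 7.5, 4)
  min_d <- mean_separation * sigma
  means <- matrix(NA_real_, n_letters, 4)
  placed <- 0L; attempts <- 0L
  while (placed < n_letters) {
    attempts <- attempts + 1L
    if (attempts > 50000L) {
      abort(paste0("infeasible mean separation ", mean_separation,
                   " sigma for ", n_letters, " letters in descriptor space"))
    }
    cand <- lo + runif(4) * (hi - lo)
    if (placed == 0L ||
        min(sqrt(colSums((t(means[seq_len(placed), , drop = FALSE]) - cand)^2))) >= min_d) {
      placed <- placed + 1L
      means[placed, ] <- cand
    }
  }
  n <- n_letters
  trans <- matrix((1 - self_bias) / n, n, n) + diag(self_bias, n)
  trans <- trans / rowSums(trans)
  alphabet_model(
    letters = the_canonical_letters()[seq_len(n)],
    means = means,
    covariances = diag(sigma^2, 4),
    transitions = trans,
    initial = rep(1 / n, n),
    ss_class = rep(c("helix", "strand", "loop"), length.out = n)
  )
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic multi-chain structure ensemble
#'
#' Builds an ensemble of Calpha-trace chains written as PDB files (two chains
#' per entry, each in its own random crystal frame), together with the
#' trivially exact aligned FASTA, an alphabet model matched to the planted
#' geometry, and a machine-readable ground-truth ledger. The generator
#' emulates the shape of a curated crystallographic ensemble: conformational
#' heterogeneity expressible as distinct structural letters at chosen
#' positions, planted B-factor hot spots, and holo chains carrying a ligand
#' atom cloud in a common groove.
#'
#' Chains are ideal alpha-helices split into segments by author-numbering
#' gaps (unmodelled-loop breaks). Each planted variable position is the
#' anchor of the final four-Calpha window of a segment; per chain, a letter
#' is drawn from `letter_distribution` and realised by displacing the
#' segment's last residue by that letter's characteristic offset. Because the
#' displaced residue belongs to exactly one window, the planted signal lands
#' on exactly the chosen aligned positions; all other encodable positions
#' carry the baseline helix letter. Coordinates are jittered by at most
#' `jitter` per component everywhere. B-factors follow a planted profile
#' (baseline `b_scale * 6`, bumps of `+3 * b_scale` at flexible positions)
#' under a per-chain affine distortion plus small per-residue noise, so the
#' within-structure z-score recovers exactly the planted flexible positions.
#'
#' @param n_chains Number of chains.
#' @param n_residues Residues per chain.
#' @param variable_positions Aligned positions (in `[3, n_residues - 1]`,
#'   pairwise at least 4 apart) with planted conformational heterogeneity.
#' @param flexible_positions Aligned positions with planted B-factor bumps.
#' @param apo_fraction Fraction of chains left ligand-free.
#' @param seed Integer seed.
#' @param dir Output directory for PDB files and FASTA (created).
#' @param letter_distribution Named probability vector over letters drawn at
#'   planted positions; must contain `"A"` (the baseline helix letter). The
#'   default reuses the letter proportions of a worked substituted-position
#'   distribution (majority conformer 67%).
#' @param variant_chains Draw planted variants for `"all"` chains (intrinsic
#'   variability) or only `"holo"` chains (ligand-induced variability; apo
#'   chains then always carry the baseline letter).
#' @param n_blobs Number of ligand-atom blobs in the groove.
#' @param jitter Maximum absolute coordinate jitter (Angstrom).
#' @param b_scale B-factor profile scale (bump height is `3 * b_scale`).
#' @return Object of class `synthetic_ensemble`: list with `dir`,
#'   `pdb_files`, `fasta`, `model` (the matched `alphabet_model`), `truth`
#'   (ground-truth ledger) and `params`.
#' @export
make_ensemble <- function(n_chains = 50, n_residues = 60,
                          variable_positions = c(10, 20, 30, 40, 50),
                          flexible_positions = c(24, 25, 26, 27, 28),
                          apo_fraction = 0.2, seed = 1,
                          dir = tempfile("ensemble"),
                          letter_distribution = c(A = 0.67, V = 0.13, W = 0.17,
                                                  a = 0.015, B = 0.015),
                          variant_chains = c("all", "holo"),
                          n_blobs = 8, jitter = 0.05, b_scale = 5) {
  variant_chains <- match.arg(variant_chains)
  vp <- sort(unique(as.integer(variable_positions)))
  if (length(vp) && (min(vp) < 3 || max(vp) > n_residues - 1)) {
    abort("variable positions must lie in [3, n_residues - 1]")
  }
  if (length(vp) > 1 && min(diff(vp)) < 4) {
    abort("variable positions must be at least 4 residues apart")
  }
  fp <- sort(unique(as.integer(flexible_positions)))
  if (length(fp) && (min(fp) < 1 || max(fp) > n_residues)) {
    abort("flexible positions out of range")
  }
  if (!"A" %in% names(letter_distribution)) {
    abort("letter_distribution must include the baseline letter 'A'")
  }
  if (abs(sum(letter_distribution) - 1) > 1e-9) {
    abort("letter_distribution must sum to 1")
  }
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ## --- segments: break numbering after each planted position + 1 ---------
  ends <- unique(c(vp + 1L, n_residues))
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  seg_of <- rep(seq_along(starts), times = ends - starts + 1L)
  resnum <- seq_len(n_residues) + 2L * (seg_of - 1L)  # +2 numbering gap per break

  template <- ideal_helix_coords(n_residues)
  seq_aa <- sample(setdiff(unique(aa_one(CANONICAL_AA3)), character(0)),
                   n_residues, replace = TRUE)

  ## --- variant geometry and the matched alphabet model -------------------
  variant_letters <- setdiff(names(letter_distribution), "A")
  offsets <- setNames((seq_along(variant_letters) + 1) %/% 2 * 2 *
                        rep_len(c(1, -1), length(variant_letters)),
                      variant_letters)  # +2, -2, +4, -4, ... Angstrom, radial
  displaced_window <- function(p, delta) {
    w <- template[(p - 2L):(p + 1L), , drop = FALSE]
    r <- p + 1L
    radial <- c(template[r, 1:2] / sqrt(sum(template[r, 1:2]^2)), 0)
    w[4, ] <- w[4, ] + delta * radial
    w
  }
  p0 <- if (length(vp)) vp[1] else max(3L, min(10L, n_residues - 1L))
  model_letters <- c("A", variant_letters)
  means <- rbind(A = fragment_descriptors(template[(p0 - 2L):(p0 + 1L), ]))
  for (v in variant_letters) {
    means <- rbind(means, fragment_descriptors(displaced_window(p0, offsets[[v]])))
  }
  rownames(means) <- model_letters
  ord <- order(match(model_letters, the_canonical_letters()))
  sigma_model <- 0.08
  sep <- min(dist(means))
  if (length(model_letters) > 1 && sep < 6 * sigma_model) {
    abort("generator self-check failed: planted letter means closer than 6 sigma")
  }
  n_l <- length(model_letters)
  trans <- matrix(0.8 / n_l, n_l, n_l) + diag(0.2, n_l)
  trans <- trans / rowSums(trans)
  model <- alphabet_model(model_letters[ord], means[ord, , drop = FALSE],
                          diag(sigma_model^2, 4), trans,
                          rep(1 / n_l, n_l),
                          rep(c("helix", "loop"), length.out = n_l))

  ## --- chain assembly ----------------------------------------------------
  entry_of <- (seq_len(n_chains) + 1L) %/% 2L
  chain_letter <- rep_len(c("A", "B"), n_chains)
  pdb_ids <- sprintf("S%03d", entry_of)
  chain_refs <- paste0(pdb_ids, "_", chain_letter)
  n_holo <- n_chains - round(apo_fraction * n_chains)
  holo <- sort(sample(n_chains, n_holo))
  draw_pool <- if (variant_chains == "all") seq_len(n_chains) else holo

  bump <- 3 * b_scale
  profile <- rep(6 * b_scale, n_residues)
  profile[fp] <- profile[fp] + bump

  ## groove: blob centres 4 Angstrom radially out from evenly spaced mid-chain residues
  anchor_res <- if (n_blobs > 0) {
    unique(round(seq(n_residues * 0.3, n_residues * 0.7, length.out = n_blobs)))
  } else integer()
  blob_centers <- t(vapply(anchor_res, function(r) {
    radial <- c(template[r, 1:2] / sqrt(sum(template[r, 1:2]^2)), 0)
    template[r, ] + 4.0 * radial
  }, numeric(3)))

  planted_letters <- list()
  chains_rows <- list()
  lig_rows <- list()
  for (i in seq_len(n_chains)) {
    coords <- template
    lets <- setNames(rep("A", length(vp)), vp)
    if (length(vp) && i %in% draw_pool) {
      lets[] <- sample(names(letter_distribution), length(vp), replace = TRUE,
                       prob = letter_distribution)
    }
    for (j in seq_along(vp)) {
      if (lets[j] != "A") {
        p <- vp[j]; r <- p + 1L
        radial <- c(template[r, 1:2] / sqrt(sum(template[r, 1:2]^2)), 0)
        coords[r, ] <- coords[r, ] + offsets[[lets[j]]] * radial
      }
    }
    coords <- coords + matrix(runif(3 * n_residues, -jitter, jitter),
                              n_residues, 3)
    a_j <- runif(1, 0.5, 2); b_j <- runif(1, -5, 10)
    bfac <- a_j * (profile + rnorm(n_residues, 0, b_scale / 5)) + b_j

    R <- random_rotation()
    shift <- c(250 * ((i - 1) %% 8), 250 * ((i - 1) %/% 8), 0) + runif(3, -5, 5)
    placed <- sweep(coords %*% t(R), 2, shift, "+")
    chains_rows[[i]] <- tibble(
      pdb_id = pdb_ids[i], chain_id = chain_letter[i], chain_ref = chain_refs[i],
      resnum = resnum, aa = seq_aa,
      x = placed[, 1], y = placed[, 2], z = placed[, 3], bfactor = bfac
    )
    if (i %in% holo && n_blobs > 0) {
      lig <- blob_centers + matrix(rnorm(3 * nrow(blob_centers), 0, 0.3),
                                   nrow(blob_centers), 3)
      lig <- sweep(lig %*% t(R), 2, shift, "+")
      lig_rows[[i]] <- tibble(
        pdb_id = pdb_ids[i], chain_id = chain_letter[i],
        x = lig[, 1], y = lig[, 2], z = lig[, 3]
      )
    }
    if (length(vp)) {
      planted_letters[[i]] <- tibble(chain_ref = chain_refs[i],
                                     position = vp, letter = unname(lets))
    }
  }
  chains <- bind_rows(chains_rows)
  ligs <- bind_rows(lig_rows)

  ## --- write PDB entries and FASTA ---------------------------------------
  aa3 <- setNames(CANONICAL_AA3, aa_one(CANONICAL_AA3))
  pdb_files <- purrr::map_chr(unique(pdb_ids), function(id) {
    path <- file.path(dir, paste0(id, ".pdb"))
    pc <- chains[chains$pdb_id == id, , drop = FALSE]
    lc <- if (nrow(ligs)) ligs[ligs$pdb_id == id, , drop = FALSE] else ligs
    n_p <- nrow(pc); n_l <- if (is.null(lc)) 0L else nrow(lc)
    suppressWarnings(bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = c(t(as.matrix(rbind(pc[, c("x", "y", "z")],
                                if (n_l) lc[, c("x", "y", "z")])))),
      type = c(rep("ATOM", n_p), rep("HETATM", n_l)),
      resno = c(pc$resnum, if (n_l) rep(900L, n_l)),
      resid = c(unname(aa3[pc$aa]), if (n_l) rep("LIG", n_l)),
      eleno = seq_len(n_p + n_l),
      elety = c(rep("CA", n_p), if (n_l) rep("C1", n_l)),
      chain = c(pc$chain_id, if (n_l) lc$chain_id),
      o = rep(1, n_p + n_l),
      b = c(round(pc$bfactor, 2), if (n_l) rep(30, n_l)),
      elesy = c(rep("C", n_p + n_l))
    ))
    txt <- readLines(path)
    writeLines(c(paste0("REMARK 900 SYNTHETIC ENSEMBLE SEED ", seed), txt), path)
    path
  })
  fasta <- file.path(dir, "alignment.fasta")
  writeLines(as.vector(rbind(paste0(">", chain_refs),
                             rep(paste(seq_aa, collapse = ""), n_chains))),
             fasta)

  truth <- list(
    planted_variable_positions = vp,
    planted_letters = bind_rows(planted_letters),
    planted_flexible_positions = fp,
    planted_atom_blobs = list(n = nrow(blob_centers), centers = blob_centers,
                              anchor_positions = anchor_res),
    holo_chains = chain_refs[holo],
    apo_chains = chain_refs[setdiff(seq_len(n_chains), holo)],
    seed = seed
  )
  jsonlite::write_json(
    list(planted_variable_positions = vp,
         planted_flexible_positions = fp,
         n_blobs = nrow(blob_centers),
         holo_chains = truth$holo_chains, seed = seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  structure(list(dir = dir, pdb_files = pdb_files, fasta = fasta,
                 model = model, truth = truth,
                 params = list(n_chains = n_chains, n_residues = n_residues,
                               apo_fraction = apo_fraction,
                               letter_distribution = letter_distribution,
                               variant_chains = variant_chains,
                               jitter = jitter, b_scale = b_scale)),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat("<synthetic_ensemble> ", x$params$n_chains, " chains x ",
      x$params$n_residues, " residues in ", x$dir, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic ligand set: atom blobs plus block fingerprints
#'
#' Produces (a) ligand atom clouds in which every ligand contributes exactly
#' one atom to each of `n_blobs` well-separated spatial blobs (so a k-means
#' scan recovers the blob count), and (b) binary fingerprints with
#' block-structured similarity: ligands inside a block share a template bit
#' pattern up to a small flip rate, blocks are mutually random (so
#' Ward clustering recovers the blocks and size-one blocks become dropped
#' singletons).
#'
#' @param n_ligands Number of ligands.
#' @param n_blobs Number of spatial atom blobs.
#' @param blocks Integer vector of block sizes summing to `n_ligands`
#'   (size-1 entries are planted outliers).
#' @param seed Integer seed.
#' @param n_bits Fingerprint length (166 mirrors the structural-key scheme).
#' @param flip_rate Within-block bit flip probability.
#' @return List: `atoms` (tibble `ligand_ref`, `complex`, `blob`, `x`, `y`,
#'   `z`), `fingerprints` (binary matrix, rownames ligand ids), `truth`
#'   (blob centers, block assignment, seed).
#' @export
make_ligand_set <- function(n_ligands = 12, n_blobs = 12,
                            blocks = c(4, 4, 3, 1), seed = 1, n_bits = 166,
                            flip_rate = 0.02) {
  if (sum(blocks) != n_ligands) abort("block sizes must sum to n_ligands")
  set.seed(seed)
  centers <- matrix(NA_real_, n_blobs, 3)
  placed <- 0L; attempts <- 0L
  while (placed < n_blobs) {
    attempts <- attempts + 1L
    if (attempts > 20000L) abort("cannot place well-separated blobs")
    cand <- runif(3, 0, max(20, 3 * n_blobs))
    if (placed == 0L ||
        min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))) >= 6) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  refs <- sprintf("lig%02d", seq_len(n_ligands))
  atoms <- purrr::map(seq_len(n_ligands), function(i) {
    jit <- matrix(rnorm(3 * n_blobs, 0, 0.25), n_blobs, 3)
    tibble(ligand_ref = refs[i], complex = sprintf("cpx%02d", i),
           blob = seq_len(n_blobs),
           x = centers[, 1] + jit[, 1], y = centers[, 2] + jit[, 2],
           z = centers[, 3] + jit[, 3])
  }) %>% bind_rows()

  block_of <- rep(seq_along(blocks), times = blocks)
  fp <- matrix(0L, n_ligands, n_bits, dimnames = list(refs, NULL))
  for (b in seq_along(blocks)) {
    template <- as.integer(runif(n_bits) < 0.35)
    for (i in which(block_of == b)) {
      flips <- runif(n_bits) < flip_rate
      fp[i, ] <- ifelse(flips, 1L - template, template)
    }
  }
  fp[rowSums(fp) == 0, 1] <- 1L  # guard: no empty fingerprint
  list(atoms = atoms, fingerprints = fp,
       truth = list(blob_centers = centers,
                    blocks = tibble(ligand_ref = refs, block = block_of),
                    singleton_blocks = which(blocks == 1), seed = seed))
}

#' Simulate raw contact records with planted recurrence structure
#'
#' Plants `n_recurrent` (position, atom-cluster) contacts supported by more
#' than 10% of complexes and `n_rare` contacts supported by at most 10%,
#' then expands them into atom-level records (one per supporting complex,
#' possibly several atoms per complex). The ledger lists which edges the
#' recurrence filter must retain.
#'
#' @param n_complexes Number of complexes.
#' @param n_recurrent,n_rare Planted edge counts.
#' @param seed Integer seed.
#' @return List: `records` (tibble as from [find_contacts()]), `n_complexes`,
#'   `truth` (`recurrent` and `rare` edge tibbles, seed).
#' @export
simulate_contact_records <- function(n_complexes = 30, n_recurrent = 20,
                                     n_rare = 30, seed = 1) {
  set.seed(seed)
  n_edges <- n_recurrent + n_rare
  pairs <- expand.grid(position = 1:40, cluster = 1:60)
  pairs <- pairs[sample(nrow(pairs), n_edges), ]
  rare_cap <- floor(0.10 * n_complexes)
  support <- c(sample((rare_cap + 1):n_complexes, n_recurrent, replace = TRUE),
               sample(seq_len(rare_cap), n_rare, replace = TRUE))
  records <- purrr::map(seq_len(n_edges), function(e) {
    cpx <- sample(n_complexes, support[e])
    k <- lengths(lapply(cpx, function(i) seq_len(sample(2, 1))))
    tibble(complex = sprintf("cpx%03d", rep(cpx, k)),
           position = pairs$position[e], cluster = pairs$cluster[e],
           lig_atom_id = sample(1e4, sum(k)),
           dist = runif(sum(k), 2.5, 4.5))
  }) %>% bind_rows()
  records <- records[sample(nrow(records)), ]
  as_edge_tbl <- function(df) {
    tibble(position = as.integer(df$position), cluster = as.integer(df$cluster)) %>%
      arrange(.data$position, .data$cluster)
  }
  list(records = records, n_complexes = n_complexes,
       truth = list(recurrent = as_edge_tbl(pairs[seq_len(n_recurrent), ]),
                    rare = as_edge_tbl(pairs[n_recurrent + seq_len(n_rare), ]),
                    seed = seed))
}
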