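# chunked minimum Euclidean distance from each row of X to the point set Y;
# plain double-loop arithmetic organized as matrix algebra, bit-equivalent to
# the brute-force rule
min_dist_to_set <- function(X, Y, chunk = 2048L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(Y) == 0) return(rep(Inf, nrow(X)))
  y2 <- rowSums(Y^2)
  out <- numeric(nrow(X))
  for (start in seq(1L, nrow(X), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(X))
    Xc <- X[idx, , drop = FALSE]
    d2 <- outer(rowSums(Xc^2), y2, "+") - 2 * Xc %*% t(Y)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets, via SVD of the cross-covariance with the standard
#' reflection correction (determinant forced to +1, so mirror solutions are
#' never returned). The transform maps mobile coordinates onto the reference
#' frame: `x' = x R^T + t`.
#'
#' @param mobile,reference Paired N x 3 coordinate matrices (N >= 3,
#'   non-collinear).
#' @return A list of class `rigid_transform`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom, after transformation).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3) {
    abort("mobile and reference must be paired N x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) abort("need at least 3 paired points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  A <- sweep(mobile, 2, mc); B <- sweep(reference, 2, rc)
  if (sum(svd(A)$d > 1e-8) < 2) abort("degenerate (collinear) point configuration")
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- rc - as.vector(R %*% mc)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords N x 3 matrix (or data frame with x/y/z columns).
#' @param tf A `rigid_transform`.
#' @return Transformed N x 3 matrix.
#' @export
transform_coords <- function(coords, tf) {
  X <- as.matrix(coords[, c(1, 2, 3)])
  sweep(X %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Superimpose every chain of an ensemble onto a reference chain
#'
#' Pairs chains through the alignment (Calpha atoms at aligned positions
#' resolved in both the chain and the reference), computes the Kabsch
#' transform for each chain, and applies it to the chain's residues, its
#' protein atoms and its assigned ligands' atoms. The reference chain
#' defaults to the first chain of the set; for real ensembles an arbitrary
#' well-resolved chain is the usual choice.
#'
#' @param structures A `structure_set`.
#' @param pos_map Position-map tibble from [read_alignment()] / an `msla`.
#' @param reference Chain identifier of the reference chain.
#' @return A list: `structures` (the set, all coordinates in the reference
#'   frame), `transforms` tibble (`chain_ref`, `rmsd`, `n_paired`, `transform`
#'   list column).
#' @export
superpose_ensemble <- function(structures, pos_map,
                               reference = structures$chains$chain_ref[1]) {
  chains <- structures$chains
  refs <- unique(chains$chain_ref)
  if (!reference %in% refs) abort(paste0("reference chain ", reference, " not found"))
  ca_at <- function(cr) {
    chains[chains$chain_ref == cr, , drop = FALSE] %>%
      left_join(pos_map[pos_map$chain_ref == cr,
                        c("resnum", "icode", "aligned_pos")],
                by = c("resnum", "icode")) %>%
      filter(is.finite(.data$x))
  }
  ref_ca <- ca_at(reference)
  lig_src <- structures$ligands
  transforms <- purrr::map(refs, function(cr) {
    mob <- ca_at(cr)
    shared <- intersect(mob$aligned_pos, ref_ca$aligned_pos)
    if (length(shared) < 3) {
      abort(paste0("chain ", cr, ": fewer than 3 aligned Calpha shared with reference"))
    }
    m <- as.matrix(mob[match(shared, mob$aligned_pos), c("x", "y", "z")])
    r <- as.matrix(ref_ca[match(shared, ref_ca$aligned_pos), c("x", "y", "z")])
    tf <- kabsch_superpose(m, r)
    tibble(chain_ref = cr, rmsd = tf$rmsd, n_paired = length(shared),
           transform = list(tf))
  }) %>% bind_rows()

  apply_tf <- function(df, ref_col) {
    for (cr in unique(df[[ref_col]])) {
      tf <- transforms$transform[[match(cr, transforms$chain_ref)]]
      idx <- which(df[[ref_col]] == cr & is.finite(df$x))
      if (length(idx)) {
        df[idx, c("x", "y", "z")] <- transform_coords(df[idx, c("x", "y", "z")], tf)
      }
    }
    df
  }
  structures$chains <- apply_tf(structures$chains, "chain_ref")
  structures$atoms <- apply_tf(structures$atoms, "chain_ref")
  if (nrow(structures$ligand_atoms)) {
    la <- structures$ligand_atoms %>%
      left_join(lig_src %>% select("ligand_ref", "assigned_chain"),
                by = "ligand_ref")
    unassigned <- unique(la$ligand_ref[is.na(la$assigned_chain) |
                                         !(la$assigned_chain %in% transforms$chain_ref)])
    if (length(unassigned)) {
      abort(paste0("ligand(s) without a superposition transform: ",
                   paste(unassigned, collapse = ", ")))
    }
    la <- apply_tf(la, "assigned_chain")
    structures$ligand_atoms <- la %>% select(-"assigned_chain")
  }
  list(structures = structures, transforms = transforms)
}

#' Merge all superimposed ligands into a superligand
#'
#' Concatenates the heavy atoms of every ligand, already mapped to the
#' reference frame, into one composite atom cloud. No deduplication: the
#' superligand atom count is the sum of the contributing ligands' heavy-atom
#' counts, and per-atom provenance (ligand, source complex) is retained.
#'
#' @param ligand_atoms Ligand-atom tibble in the reference frame (as produced
#'   by [superpose_ensemble()]).
#' @param ligands Ligand table (`ligand_ref`, `assigned_chain`, `ltype`).
#' @return Tibble of superligand atoms: `atom_id`, `ligand_ref`, `complex`
#'   (source chain), `ltype`, `x`, `y`, `z`.
#' @export
build_superligand <- function(ligand_atoms, ligands) {
  if (nrow(ligand_atoms) == 0) abort("no ligand atoms to merge")
  missing <- setdiff(unique(ligand_atoms$ligand_ref), ligands$ligand_ref)
  if (length(missing)) {
    abort(paste0("ligand atoms without a ligand record: ",
                 paste(missing, collapse = ", ")))
  }
  ligand_atoms %>%
    left_join(ligands %>% select("ligand_ref", complex = "assigned_chain",
                                 "ltype"),
              by = "ligand_ref") %>%
    mutate(atom_id = row_number()) %>%
    select("atom_id", "ligand_ref", "complex", "ltype", "x", "y", "z")
}

#' Extract a chain's binding pocket against the superligand
#'
#' The pocket is the set of protein heavy atoms of the chain lying within
#' `cutoff` (inclusive) of any superligand atom; pocket residues are the
#' aligned positions owning at least one such atom. The same rule applies to
#' apo and holo chains alike. An empty pocket is allowed (with a warning).
#'
#' @param atoms Protein atom tibble of one chain, in the reference frame.
#' @param superligand Superligand tibble from [build_superligand()].
#' @param pos_map Position map, to translate residue numbers into aligned
#'   positions.
#' @param cutoff Distance threshold in Angstrom (default 4.5, inclusive).
#' @return List of class `pocket`: `chain_ref`, `atoms` (pocket-member atom
#'   rows with `min_dist`), `residues` (tibble `position`, `min_dist`).
#' @export
extract_pocket <- function(atoms, superligand, pos_map, cutoff = 4.5) {
  cr <- atoms$chain_ref[1]
  d <- min_dist_to_set(as.matrix(atoms[, c("x", "y", "z")]),
                       as.matrix(superligand[, c("x", "y", "z")]))
  atoms$min_dist <- d
  member <- atoms[d <= cutoff, , drop = FALSE]
  if (nrow(member) == 0) warn(paste0("chain ", cr, ": empty pocket"))
  res <- member %>%
    left_join(pos_map[pos_map$chain_ref == cr,
                      c("resnum", "icode", "aligned_pos")],
              by = c("resnum", "icode")) %>%
    group_by(position = .data$aligned_pos) %>%
    summarise(min_dist = min(.data$min_dist), n_atoms = n(), .groups = "drop") %>%
    filter(!is.na(.data$position)) %>%
    arrange(.data$position)
  structure(list(chain_ref = cr, atoms = member, residues = res),
            class = "pocket")
}

#' Extract pockets for every chain of a superposed ensemble
#'
#' @param structures `structure_set` in the reference frame.
#' @param superligand From [build_superligand()].
#' @param pos_map Position map.
#' @param cutoff Angstrom threshold (inclusive).
#' @return Tibble with one row per (chain, pocket residue): `chain_ref`,
#'   `position`, `min_dist`, `n_atoms`.
#' @export
extract_pockets <- function(structures, superligand, pos_map, cutoff = 4.5) {
  purrr::map(unique(structures$atoms$chain_ref), function(cr) {
    p <- extract_pocket(structures$atoms[structures$atoms$chain_ref == cr, ,
                                         drop = FALSE],
                        superligand, pos_map, cutoff)
    if (nrow(p$residues) == 0) return(NULL)
    tibble(chain_ref = cr, p$residues)
  }) %>% bind_rows()
}

#' Consensus binding pocket
#'
#' The union over all chains of every aligned position present in at least
#' one pocket.
#'
#' @param pockets Pocket-residue tibble from [extract_pockets()] (or a list
#'   of `pocket` objects).
#' @return Sorted integer vector of aligned positions.
#' @export
consensus_pocket <- function(pockets) {
  if (inherits(pockets, "pocket")) pockets <- list(pockets)
  pos <- if (is.data.frame(pockets)) {
    pockets$position
  } else {
    unlist(purrr::map(pockets, function(p) p$residues$position))
  }
  if (length(pos) == 0) abort("no pockets supplied")
  sort(unique(pos))
}

#' Write a superligand as a PDB file for visual inspection
#'
#' @param superligand From [build_superligand()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_superligand <- function(superligand, path) {
  n <- nrow(superligand)
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = c(t(as.matrix(superligand[, c("x", "y", "z")]))),
    type = rep("HETATM", n),
    resno = rep(1L, n), resid = rep("SLG", n),
    eleno = seq_len(n), elety = rep("C", n),
    chain = rep("S", n), o = rep(1, n), b = rep(0, n),
    elesy = rep("C", n)
  ))
  invisible(path)
}
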