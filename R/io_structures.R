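#' Curation configuration for structure parsing
#'
#' Bundles the rule-based part of dataset curation: the minimum chain length
#' that separates the target protein from co-crystallized peptide ligands, an
#' optional allow-list and a deny-list of chain identifiers (`"pdb_chain"`
#' form), and the set of chemical component ids that are never treated as
#' ligands (water plus common crystallization additives). Exclusions that
#' require visual inspection in the original workflow (fused-helix
#' conformers, groove-occupied binding partners) are expressed as deny-list
#' entries.
#'
#' @param min_length Minimum residue count for a chain to be retained as the
#'   target protein; shorter all-ATOM chains are recorded as peptide ligands.
#' @param deny_chains Character vector of `"pdb_chain"` identifiers to drop.
#' @param allow_chains Optional character vector; when given, only these chain
#'   identifiers survive curation.
#' @param solvent Component ids excluded from ligand extraction.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(min_length = 50,
                            deny_chains = character(),
                            allow_chains = NULL,
                            solvent = c("HOH", "WAT", "DOD", "SO4", "GOL",
                                        "EDO", "PEG", "PO4", "ACT", "DMS",
                                        "FMT", "CL", "NA", "K", "MG", "ZN",
                                        "CA", "IOD", "BR", "NO3", "TRS",
                                        "MES", "EPE", "IMD", "BME", "MPD")) {
  structure(list(min_length = min_length, deny_chains = deny_chains,
                 allow_chains = allow_chains, solvent = solvent),
            class = "curation_config")
}

CANONICAL_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")

aa_one <- function(aa3) {
  one <- suppressWarnings(bio3d::aa321(aa3))
  one[!aa3 %in% CANONICAL_AA3] <- "X"
  one
}

# highest-occupancy altloc conformer per atom; ties broken by altloc label order
resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  at$._alt <- alt
  at %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$resid, .data$elety) %>%
    arrange(dplyr::desc(.data$o), .data$._alt, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(-"._alt") %>%
    arrange(.data$eleno)
}

#' Parse multi-chain PDB files into chains and ligands
#'
#' Reads one or more PDB files (first MODEL only), resolves alternate
#' locations to the highest-occupancy conformer (ties broken by altloc label),
#' and splits the contents into protein chains and ligand records. Every ATOM
#' chain becomes a chain; chains shorter than `config$min_length` are
#' additionally recorded as peptide (or pseudo-peptide, when they contain
#' non-canonical monomers) ligands. Non-solvent HETATM groups become
#' small-molecule ligands. Hydrogens are dropped throughout. Each ligand is
#' assigned to the protein chain whose Calpha trace it approaches most
#' closely; chains with no assigned ligand are flagged `is_apo`.
#'
#' @param paths Character vector of PDB file paths.
#' @param config A [curation_config()].
#' @param pdb_ids Optional identifiers, one per path; defaults to file base
#'   names without extension.
#' @return A `structure_set`: list with tibbles `chains` (one row per residue,
#'   Calpha coordinates and B-factor), `atoms` (all protein heavy atoms),
#'   `ligands` (one row per ligand record) and `ligand_atoms` (heavy atoms of
#'   every ligand).
#' @export
read_structures <- function(paths, config = curation_config(), pdb_ids = NULL) {
  if (is.null(pdb_ids)) {
    pdb_ids <- sub("\\.(pdb|ent)$", "", basename(paths), ignore.case = TRUE)
  }
  sets <- purrr::map2(paths, pdb_ids, parse_structure_file, config = config)
  structure(
    list(chains = bind_rows(purrr::map(sets, "chains")),
         atoms = bind_rows(purrr::map(sets, "atoms")),
         ligands = bind_rows(purrr::map(sets, "ligands")),
         ligand_atoms = bind_rows(purrr::map(sets, "ligand_atoms"))),
    class = "structure_set"
  )
}

parse_structure_file <- function(path, pdb_id, config) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("cannot parse PDB file ", path, ": ",
                                     conditionMessage(e)))
  )
  at <- as_tibble(pdb$atom)
  at$insert[is.na(at$insert)] <- ""
  at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  at <- resolve_altloc(at)

  prot <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type == "HETATM" & !(at$resid %in% config$solvent), , drop = FALSE]

  chains_list <- list(); atoms_list <- list()
  ligands <- list(); ligand_atoms <- list()

  for (ch in unique(prot$chain)) {
    pc <- prot[prot$chain == ch, , drop = FALSE]
    chain_ref <- paste0(pdb_id, "_", ch)
    res <- pc %>%
      distinct(.data$resno, .data$insert, .data$resid) %>%
      arrange(.data$resno, .data$insert)
    ca <- pc[pc$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) {
      warn(paste0("chain ", chain_ref, " has no Calpha atoms; excluded"))
      next
    }
    res <- res %>%
      left_join(ca %>% select("resno", "insert", "x", "y", "z", "b"),
                by = c("resno", "insert"))
    chains_list[[ch]] <- tibble(
      pdb_id = pdb_id, chain_id = ch, chain_ref = chain_ref,
      resnum = res$resno, icode = res$insert, aa = aa_one(res$resid),
      resname = res$resid, x = res$x, y = res$y, z = res$z, bfactor = res$b
    )
    atoms_list[[ch]] <- tibble(
      pdb_id = pdb_id, chain_id = ch, chain_ref = chain_ref,
      resnum = pc$resno, icode = pc$insert, resname = pc$resid,
      atom = pc$elety, elem = pc$elesy,
      x = pc$x, y = pc$y, z = pc$z, occupancy = pc$o, bfactor = pc$b
    )
    # short ATOM chains double as peptide-type ligand records
    if (nrow(res) < config$min_length) {
      aa1 <- aa_one(res$resid)
      ligands[[length(ligands) + 1L]] <- tibble(
        ligand_ref = paste0(pdb_id, "_", ch, "_pep"),
        ligand_id = ch, pdb_id = pdb_id, lig_chain = ch,
        ltype = if (any(aa1 == "X")) "pseudo_peptide" else "peptide",
        n_atoms = nrow(pc)
      )
      ligand_atoms[[length(ligand_atoms) + 1L]] <- tibble(
        ligand_ref = paste0(pdb_id, "_", ch, "_pep"),
        atom = pc$elety, elem = pc$elesy,
        x = pc$x, y = pc$y, z = pc$z, bfactor = pc$b
      )
    }
  }

  if (nrow(het)) {
    het_groups <- het %>%
      group_by(.data$chain) %>%
      mutate(het_only = !(.data$chain[1] %in% prot$chain)) %>%
      ungroup()
    key <- ifelse(het_groups$het_only,
                  paste0(het_groups$chain, "_het"),
                  paste0(het_groups$chain, "_", het_groups$resid, "_",
                         het_groups$resno))
    for (k in unique(key)) {
      hg <- het_groups[key == k, , drop = FALSE]
      lref <- paste0(pdb_id, "_", k)
      multi_res <- dplyr::n_distinct(hg$resno, hg$insert) > 1
      ltype <- if (!multi_res) "small_molecule"
               else if (all(hg$resid %in% CANONICAL_AA3)) "peptide"
               else "pseudo_peptide"
      ligands[[length(ligands) + 1L]] <- tibble(
        ligand_ref = lref,
        ligand_id = paste(unique(hg$resid), collapse = "+"),
        pdb_id = pdb_id, lig_chain = hg$chain[1],
        ltype = ltype, n_atoms = nrow(hg)
      )
      ligand_atoms[[length(ligand_atoms) + 1L]] <- tibble(
        ligand_ref = lref, atom = hg$elety, elem = hg$elesy,
        x = hg$x, y = hg$y, z = hg$z, bfactor = hg$b
      )
    }
  }

  chains <- bind_rows(chains_list)
  ligands <- bind_rows(ligands)
  ligand_atoms <- bind_rows(ligand_atoms)
  ligands <- assign_ligands(chains, ligands, ligand_atoms, config)
  chains <- chains %>%
    mutate(is_apo = !(.data$chain_ref %in% ligands$assigned_chain))
  list(chains = chains, atoms = bind_rows(atoms_list),
       ligands = ligands, ligand_atoms = ligand_atoms)
}

# a ligand belongs to the groove of the target chain whose Calpha trace it
# approaches most closely (the automatable proxy for groove occupancy)
assign_ligands <- function(chains, ligands, ligand_atoms, config) {
  if (nrow(ligands) == 0) {
    return(tibble(ligand_ref = character(), ligand_id = character(),
                  pdb_id = character(), lig_chain = character(),
                  ltype = character(), n_atoms = integer(),
                  assigned_chain = character()))
  }
  lens <- chains %>% count(.data$chain_ref, name = "len")
  targets <- lens$chain_ref[lens$len >= config$min_length]
  assigned <- purrr::map_chr(ligands$ligand_ref, function(lr) {
    la <- ligand_atoms[ligand_atoms$ligand_ref == lr, c("x", "y", "z")]
    best <- NA_character_; bestd <- Inf
    for (tc in targets) {
      ca <- chains[chains$chain_ref == tc, c("x", "y", "z")]
      ca <- ca[stats::complete.cases(ca), , drop = FALSE]
      if (nrow(ca) == 0) next
      d <- min_dist_to_set(as.matrix(la), as.matrix(ca))
      if (min(d) < bestd) { bestd <- min(d); best <- tc }
    }
    best
  })
  ligands$assigned_chain <- assigned
  ligands
}

#' Apply rule-based curation to parsed chains
#'
#' Removes chains shorter than `config$min_length`, chains containing
#' non-canonical (`"X"`) residues, and chains on the deny-list; when an
#' allow-list is configured only listed chains survive. The operation is
#' idempotent and preserves input order. Applied to a full `structure_set` it
#' also drops the excluded chains' atoms and re-derives `is_apo`.
#'
#' @param x A `structure_set` from [read_structures()], or its `$chains`
#'   residue tibble.
#' @param config A [curation_config()].
#' @return Same type as `x`, with non-surviving chains removed.
#' @export
curate_chains <- function(x, config = curation_config()) {
  if (inherits(x, "structure_set")) {
    kept <- curate_chains(x$chains, config)
    keep_refs <- unique(kept$chain_ref)
    x$chains <- kept
    x$atoms <- x$atoms[x$atoms$chain_ref %in% keep_refs, , drop = FALSE]
    x$ligands <- x$ligands[!is.na(x$ligands$assigned_chain) &
                             x$ligands$assigned_chain %in% keep_refs, , drop = FALSE]
    x$ligand_atoms <- x$ligand_atoms[x$ligand_atoms$ligand_ref %in%
                                       x$ligands$ligand_ref, , drop = FALSE]
    x$chains <- x$chains %>%
      mutate(is_apo = !(.data$chain_ref %in% x$ligands$assigned_chain))
    return(x)
  }
  stats_tbl <- x %>%
    group_by(.data$chain_ref) %>%
    summarise(len = n(), has_x = any(.data$aa == "X"), .groups = "drop")
  keep <- stats_tbl$chain_ref[stats_tbl$len >= config$min_length & !stats_tbl$has_x]
  keep <- setdiff(keep, config$deny_chains)
  if (!is.null(config$allow_chains)) keep <- intersect(keep, config$allow_chains)
  out <- x[x$chain_ref %in% keep, , drop = FALSE]
  if (nrow(out) == 0) abort("no chains survive curation")
  out
}

#' Classify a ligand record by type
#'
#' Polymer records of canonical residues are peptides; polymers containing a
#' non-canonical monomer are pseudo-peptides; non-polymer HETATM groups are
#' small molecules.
#'
#' @param resnames Character vector of three-letter component ids, one per
#'   monomer (length 1 for a non-polymer group).
#' @param is_polymer Logical: does the record span more than one monomer /
#'   come from a polymer chain?
#' @param n_heavy_atoms Heavy-atom count; must be positive.
#' @return One of `"small_molecule"`, `"peptide"`, `"pseudo_peptide"`.
#' @export
classify_ligand <- function(resnames, is_polymer, n_heavy_atoms) {
  if (n_heavy_atoms <= 0) abort("ligand with zero heavy atoms")
  if (!is_polymer) return("small_molecule")
  if (all(resnames %in% CANONICAL_AA3)) "peptide" else "pseudo_peptide"
}

#' Chain manifest of a structure set
#'
#' One row per chain: identifiers, length, assigned ligand count and types,
#' apo flag. Optionally written as TSV.
#'
#' @param structures A `structure_set`.
#' @param path Optional output path for a TSV copy.
#' @return The manifest tibble.
#' @export
chain_manifest <- function(structures, path = NULL) {
  lig_by_chain <- structures$ligands %>%
    filter(!is.na(.data$assigned_chain)) %>%
    group_by(chain_ref = .data$assigned_chain) %>%
    summarise(n_ligands = n(),
              ltypes = paste(sort(.data$ltype), collapse = ","),
              .groups = "drop")
  manifest <- structures$chains %>%
    group_by(.data$pdb_id, .data$chain_id, .data$chain_ref) %>%
    summarise(length = n(), is_apo = .data$is_apo[1], .groups = "drop") %>%
    left_join(lig_by_chain, by = "chain_ref") %>%
    mutate(n_ligands = tidyr::replace_na(.data$n_ligands, 0L),
           ltypes = tidyr::replace_na(.data$ltypes, ""))
  if (!is.null(path)) {
    write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest
}

#' Write chains (and optionally their ligands) back to PDB files
#'
#' One file per `pdb_id`, fixed-width PDB precision (3 decimals on
#' coordinates, 2 on B-factors).
#'
#' @param structures A `structure_set`.
#' @param dir Output directory (created if needed).
#' @return Tibble of `pdb_id`, `path` written.
#' @export
write_structures <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(structures$atoms$pdb_id)
  paths <- purrr::map_chr(ids, function(id) {
    at <- structures$atoms[structures$atoms$pdb_id == id, , drop = FALSE]
    at <- arrange(at, .data$chain_id, .data$resnum, .data$icode)
    path <- file.path(dir, paste0(id, ".pdb"))
    lig <- structures$ligands[structures$ligands$pdb_id == id &
                                structures$ligands$ltype == "small_molecule", ,
                              drop = FALSE]
    la <- structures$ligand_atoms[structures$ligand_atoms$ligand_ref %in%
                                    lig$ligand_ref, , drop = FALSE]
    n_p <- nrow(at); n_l <- nrow(la)
    lig_meta <- if (n_l) {
      la %>% left_join(lig %>% select("ligand_ref", "lig_chain"), by = "ligand_ref")
    } else NULL
    xyz <- c(t(as.matrix(rbind(at[, c("x", "y", "z")],
                               if (n_l) la[, c("x", "y", "z")]))))
    suppressWarnings(bio3d::write.pdb(
      pdb = NULL, file = path, xyz = xyz,
      type = c(rep("ATOM", n_p), rep("HETATM", n_l)),
      resno = c(at$resnum, if (n_l) rep(900L, n_l)),
      resid = c(at$resname, if (n_l) rep("LIG", n_l)),
      eleno = seq_len(n_p + n_l),
      elety = c(at$atom, if (n_l) la$atom),
      chain = c(at$chain_id, if (n_l) lig_meta$lig_chain),
      insert = c(at$icode, if (n_l) rep("", n_l)),
      o = c(at$occupancy, if (n_l) rep(1, n_l)),
      b = c(at$bfactor, if (n_l) la$bfactor),
      elesy = c(at$elem, if (n_l) la$elem)
    ))
    path
  })
  tibble(pdb_id = ids, path = paths)
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> ", n_distinct(x$chains$chain_ref), " chains, ",
      nrow(x$ligands), " ligands (",
      sum(x$chains %>% distinct(.data$chain_ref, .data$is_apo) %>% pull("is_apo")),
      " apo chains)\n", sep = "")
  invisible(x)
}
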