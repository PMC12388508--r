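#' Load an amino-acid multiple sequence alignment
#'
#' Reads an aligned FASTA whose record names are chain identifiers
#' (`pdb_chain`) and validates it against the structure-derived sequences:
#' every chain must have exactly one record, and ungapping a record must
#' reproduce the chain's extracted sequence exactly. Alignment computation
#' itself is delegated to external aligners; this package only consumes the
#' result.
#'
#' @param path Path to an aligned FASTA file.
#' @param chains Residue-level chains tibble (from [read_structures()]).
#' @return An object of class `msa`: list with `chain_refs`, `rows` (named
#'   aligned strings), `n_positions`, and `pos_map`, a tibble
#'   (`chain_ref`, `aligned_pos`, `resnum`, `icode`, `aa`) linking 1-based
#'   aligned positions to author residue numbers.
#' @export
read_alignment <- function(path, chains) {
  aln <- Biostrings::readAAStringSet(path)
  rows <- setNames(as.character(aln), names(aln))
  if (length(rows) == 0 || any(nchar(rows) == 0)) abort("length-0 alignment")
  if (length(unique(nchar(rows))) != 1) abort("alignment rows differ in length")
  refs <- unique(chains$chain_ref)
  missing <- setdiff(refs, names(rows))
  if (length(missing)) {
    abort(paste0("alignment is missing chain record(s): ",
                 paste(missing, collapse = ", ")))
  }
  rows <- rows[refs]
  pos_map <- purrr::map(refs, function(cr) {
    res <- chains[chains$chain_ref == cr, , drop = FALSE] %>%
      arrange(.data$resnum, .data$icode)
    cells <- strsplit(rows[[cr]], "")[[1]]
    non_gap <- which(cells != "-")
    if (length(non_gap) != nrow(res)) {
      abort(paste0("chain ", cr, ": alignment row has ", length(non_gap),
                   " residues but the structure has ", nrow(res)))
    }
    mism <- which(cells[non_gap] != res$aa)
    if (length(mism)) {
      abort(paste0("chain ", cr, ": sequence mismatch at aligned position ",
                   non_gap[mism[1]], " ('", cells[non_gap[mism[1]]],
                   "' in alignment vs '", res$aa[mism[1]], "' in structure)"))
    }
    tibble(chain_ref = cr, aligned_pos = non_gap,
           resnum = res$resnum, icode = res$icode, aa = res$aa)
  }) %>% bind_rows()
  structure(list(chain_refs = refs, rows = rows,
                 n_positions = nchar(rows[[1]]), pos_map = pos_map),
            class = "msa")
}

#' Build the multiple structural-letter alignment (MSLA)
#'
#' Projects each chain's structural letters through the amino-acid MSA:
#' every non-gap MSA cell is replaced by the letter anchored at that residue,
#' or by the reserved missing symbol when the residue carries no letter (the
#' first two and last residue of every encodable run, unresolved residues,
#' residues in runs shorter than four). Gap cells are always missing. The
#' result is the aligned-position by chain letter matrix on which all
#' variability statistics are computed.
#'
#' @param msa An `msa` from [read_alignment()].
#' @param sl Structural-letter tibble from [encode_chains()]
#'   (`chain_ref`, `resnum`, `letter`).
#' @return An object of class `msla`: list with `letters` (chains x positions
#'   character matrix, `NA` for missing), `chain_refs`, `n_positions`,
#'   `pos_map` (as in the MSA).
#' @export
build_msla <- function(msa, sl) {
  bad <- setdiff(unique(sl$chain_ref), msa$chain_refs)
  if (length(bad)) {
    abort(paste0("structural letters reference chains absent from the MSA: ",
                 paste(bad, collapse = ", ")))
  }
  mat <- matrix(NA_character_, length(msa$chain_refs), msa$n_positions,
                dimnames = list(msa$chain_refs, NULL))
  key_map <- paste(msa$pos_map$chain_ref, msa$pos_map$resnum, msa$pos_map$icode,
                   sep = "\r")
  sl_icode <- if ("icode" %in% names(sl)) sl$icode else ""
  key_sl <- paste(sl$chain_ref, sl$resnum, sl_icode, sep = "\r")
  hit <- match(key_sl, key_map)
  if (anyNA(hit)) {
    abort(paste0("internal consistency error: letter anchor ",
                 sl$chain_ref[which(is.na(hit))[1]], " resnum ",
                 sl$resnum[which(is.na(hit))[1]], " not found in alignment"))
  }
  mat[cbind(match(msa$pos_map$chain_ref[hit], msa$chain_refs),
            msa$pos_map$aligned_pos[hit])] <- sl$letter
  structure(list(letters = mat, chain_refs = msa$chain_refs,
                 n_positions = msa$n_positions, pos_map = msa$pos_map),
            class = "msla")
}

#' @export
print.msla <- function(x, ...) {
  cat("<msla> ", length(x$chain_refs), " chains x ", x$n_positions,
      " aligned positions\n", sep = "")
  invisible(x)
}

#' Tidy an MSLA into a long tibble
#'
#' @param x An `msla`.
#' @param ... Unused.
#' @return Tibble with `chain_ref`, `aligned_pos`, `letter` (`NA` where the
#'   cell carries no structural letter).
#' @method tidy msla
#' @export
tidy.msla <- function(x, ...) {
  tibble(chain_ref = rep(x$chain_refs, times = x$n_positions),
         aligned_pos = rep(seq_len(x$n_positions), each = length(x$chain_refs)),
         letter = as.vector(x$letters)) %>%
    arrange(.data$chain_ref, .data$aligned_pos)
}

#' Write an MSLA as aligned FASTA-like text plus a position-map TSV
#'
#' Letters are written one symbol per aligned position with `.` as the
#' missing symbol and the sidecar TSV maps (chain, aligned position) to
#' author residue numbers.
#'
#' @param msla An `msla`.
#' @param path Output path for the FASTA-like file; the position map goes to
#'   `paste0(path, ".posmap.tsv")`.
#' @return `path`, invisibly.
#' @export
write_msla <- function(msla, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cr in msla$chain_refs) {
    row <- msla$letters[cr, ]
    row[is.na(row)] <- NA_LETTER
    writeLines(c(paste0(">", cr), paste(row, collapse = "")), con)
  }
  write.table(msla$pos_map, paste0(path, ".posmap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop chains from an MSLA
#'
#' Removes rows (and their pos_map entries) leaving all other rows untouched;
#' used to form apo-only or per-ligand-cluster subsets.
#'
#' @param msla An `msla`.
#' @param chain_refs Chains to keep.
#' @return A new `msla` restricted to `chain_refs`.
#' @export
subset_msla <- function(msla, chain_refs) {
  missing <- setdiff(chain_refs, msla$chain_refs)
  if (length(missing)) {
    abort(paste0("unknown chains: ", paste(missing, collapse = ", ")))
  }
  structure(list(letters = msla$letters[chain_refs, , drop = FALSE],
                 chain_refs = chain_refs, n_positions = msla$n_positions,
                 pos_map = msla$pos_map[msla$pos_map$chain_ref %in% chain_refs, ,
                                        drop = FALSE]),
            class = "msla")
}
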