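#' Structural-letter logo matrix for a chain group
#'
#' For each requested aligned position, computes the letter frequency vector
#' over a group of chains (missing cells excluded) and the information
#' content in bits, `info_bits = log2(n_letters) - H2`, where `H2` is the
#' Shannon entropy of the frequencies in bits and `n_letters` is the alphabet
#' size (27 canonically, so a fully conserved column scores
#' `log2(27) ~ 4.755` and a uniform column scores 0). No small-sample
#' correction is applied. `info_bits` relates to [neq()] by
#' `info_bits = log2(n_letters) - log2(neq)`.
#'
#' @param msla An `msla`.
#' @param chain_group Chain identifiers to pool (default: all chains).
#' @param positions Aligned positions (default: all; typically the consensus
#'   pocket).
#' @param n_letters Alphabet size used for the information ceiling.
#' @param ss_class Optional named letter-to-secondary-structure map (from an
#'   `alphabet_model`) attached for logo colouring.
#' @return Object of class `logo_matrix`: list with `freq` (positions x
#'   letters matrix, rows summing to 1 over observed letters), `info_bits`
#'   (named vector, `NA` for all-missing columns), `positions`, `ss_class`.
#' @export
logo_matrix <- function(msla, chain_group = msla$chain_refs,
                        positions = seq_len(msla$n_positions),
                        n_letters = 27, ss_class = NULL) {
  if (length(chain_group) == 0) abort("chain_group is empty")
  if (any(positions < 1 | positions > msla$n_positions)) {
    abort("positions outside the alignment")
  }
  sub <- msla$letters[chain_group, , drop = FALSE]
  letters_seen <- sort(unique(as.vector(sub[, positions])))
  letters_seen <- letters_seen[!is.na(letters_seen)]
  freq <- matrix(0, length(positions), length(letters_seen),
                 dimnames = list(positions, letters_seen))
  info <- setNames(rep(NA_real_, length(positions)), positions)
  for (i in seq_along(positions)) {
    col <- sub[, positions[i]]
    obs <- col[!is.na(col)]
    if (length(obs) == 0) next
    p <- table(obs) / length(obs)
    freq[i, names(p)] <- as.numeric(p)
    h2 <- -sum(p * log2(p))
    info[i] <- log2(n_letters) - h2
  }
  structure(list(freq = freq, info_bits = info, positions = positions,
                 n_letters = n_letters, ss_class = ss_class),
            class = "logo_matrix")
}

#' Tidy a logo matrix into a long tibble
#'
#' @param x A `logo_matrix`.
#' @param ... Unused.
#' @return Tibble: `position`, `letter`, `freq`, `info_bits`, `height`
#'   (frequency times column information, the letter's stack height), and
#'   `ss_class` when the model map was supplied.
#' @method tidy logo_matrix
#' @export
tidy.logo_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame.table(x$freq, stringsAsFactors = FALSE)) %>%
    rename(position = "Var1", letter = "Var2", freq = "Freq") %>%
    mutate(position = as.integer(.data$position),
           info_bits = unname(x$info_bits[as.character(.data$position)]),
           height = .data$freq * .data$info_bits) %>%
    filter(.data$freq > 0)
  if (!is.null(x$ss_class)) {
    out$ss_class <- unname(x$ss_class[out$letter])
  }
  arrange(out, .data$position, dplyr::desc(.data$freq))
}

#' Write a logo matrix as TSV
#'
#' @param x A `logo_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(x, path) {
  df <- data.frame(position = x$positions, info_bits = unname(x$info_bits),
                   x$freq, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a structural-letter logo
#'
#' Stacked-letter logo: letter height is frequency scaled by the column's
#' information content, coloured by secondary-structure class when available.
#'
#' @param x A `logo_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_logo <- function(x, ...) {
  df <- tidy(x) %>%
    group_by(.data$position) %>%
    arrange(.data$freq, .by_group = TRUE) %>%
    mutate(ymax = cumsum(.data$height), ymin = .data$ymax - .data$height,
           ymid = (.data$ymin + .data$ymax) / 2) %>%
    ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid,
                                        label = .data$letter)) +
    ggplot2::geom_text(ggplot2::aes(size = .data$height,
                                    colour = if (is.null(x$ss_class)) NULL
                                             else .data$ss_class),
                       show.legend = c(size = FALSE)) +
    ggplot2::scale_size_continuous(range = c(1, 8)) +
    ggplot2::labs(x = "aligned position", y = "information (bits)",
                  colour = "secondary structure") +
    ggplot2::theme_minimal()
  p
}

#' Assemble the per-position master table
#'
#' Joins variability profiles, flexibility, ligand-induced deltas and pocket
#' membership into one row per aligned position (the run's master output).
#' The join is validated to be lossless: every input position appears exactly
#' once.
#'
#' @param profiles From [position_profiles()].
#' @param flexibility From [position_flexibility()] (optional).
#' @param deltas From [compare_subsets()] (optional).
#' @param pocket_positions Integer vector from [consensus_pocket()]
#'   (optional).
#' @param helix_positions Optional integer vector flagging helical positions.
#' @param path Optional TSV output path (letter counts serialized as JSON in
#'   the `counts` cell).
#' @return One tibble row per position with `neq`, `category`, `mean_bnorm`,
#'   `flex_class`, `delta`, `delta_band`, `in_pocket`, `in_helix`.
#' @export
export_position_table <- function(profiles, flexibility = NULL, deltas = NULL,
                                  pocket_positions = NULL,
                                  helix_positions = NULL, path = NULL) {
  out <- profiles
  if (anyDuplicated(out$position)) abort("duplicated positions in profiles")
  if (!is.null(flexibility)) {
    if (anyDuplicated(flexibility$position)) {
      abort("duplicated positions in flexibility table")
    }
    out <- left_join(out, flexibility, by = "position")
  }
  if (!is.null(deltas)) {
    if (anyDuplicated(deltas$position)) abort("duplicated positions in deltas")
    out <- left_join(out,
                     deltas %>% select("position", "neq_subset", "delta",
                                       "delta_band"),
                     by = "position")
  }
  out <- out %>%
    mutate(in_pocket = if (is.null(pocket_positions)) NA
                       else .data$position %in% pocket_positions,
           in_helix = if (is.null(helix_positions)) NA
                      else .data$position %in% helix_positions)
  if (nrow(out) != nrow(profiles)) abort("position table join is not lossless")
  if (!is.null(path)) {
    flat <- out %>%
      mutate(counts = purrr::map_chr(.data$counts, function(x) {
        as.character(jsonlite::toJSON(as.list(x), auto_unbox = TRUE))
      }))
    write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write a per-residue scalar into the B-factor column of a PDB file
#'
#' Exports a chain with a chosen per-position scalar (neqSL, mean Bnorm,
#' delta, ...) in the B-factor column so any molecular viewer can colour the
#' structure by it. Positions without a value get the sentinel -1.00. Values
#' are clamped to the fixed-width column; round-tripping recovers them to
#' 2 decimal places.
#'
#' @param chain Residue tibble of one chain (Calpha rows with coordinates).
#' @param values Tibble `position`, `value` of the scalar, in aligned
#'   positions.
#' @param pos_map Position map for the chain.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
export_viewer_annotation <- function(chain, values, pos_map, path) {
  cr <- chain$chain_ref[1]
  pm <- pos_map[pos_map$chain_ref == cr, , drop = FALSE]
  chain <- chain %>%
    left_join(pm[, c("resnum", "icode", "aligned_pos")],
              by = c("resnum", "icode")) %>%
    left_join(values, by = c(aligned_pos = "position")) %>%
    filter(is.finite(.data$x))
  b <- ifelse(is.na(chain$value), -1, pmin(pmax(chain$value, -99.99), 999.99))
  n <- nrow(chain)
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = c(t(as.matrix(chain[, c("x", "y", "z")]))),
    type = rep("ATOM", n),
    resno = chain$resnum, resid = rep("ALA", n),
    eleno = seq_len(n), elety = rep("CA", n),
    chain = rep(chain$chain_id[1] %||% "A", n),
    insert = chain$icode, o = rep(1, n), b = round(b, 2),
    elesy = rep("C", n)
  ))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot per-position variability and flexibility tracks
#'
#' neqSL profile along aligned positions (optionally with the subset curve
#' from [compare_subsets()]) over category and flexibility annotation bars.
#'
#' @param profiles From [position_profiles()].
#' @param deltas Optional tibble from [compare_subsets()]; adds the subset
#'   curve.
#' @param flexibility Optional from [position_flexibility()]; adds a
#'   mean-Bnorm track.
#' @return A ggplot object.
#' @export
plot_variability <- function(profiles, deltas = NULL, flexibility = NULL) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$position, y = .data$neq)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category),
                        size = 1, na.rm = TRUE) +
    ggplot2::labs(x = "aligned position", y = "neqSL (effective letters)",
                  colour = "category") +
    ggplot2::theme_minimal()
  if (!is.null(deltas)) {
    p <- p + ggplot2::geom_line(data = deltas,
                                ggplot2::aes(y = .data$neq_subset),
                                colour = "darkgreen", linetype = 2,
                                na.rm = TRUE)
  }
  if (!is.null(flexibility)) {
    p <- p + ggplot2::geom_col(data = flexibility,
                               mapping = ggplot2::aes(x = .data$position,
                                                      y = .data$mean_bnorm,
                                                      fill = .data$flex_class),
                               alpha = 0.3, inherit.aes = FALSE, na.rm = TRUE)
  }
  p
}
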