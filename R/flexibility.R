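#' Within-structure B-factor normalization (Bnorm)
#'
#' Z-scores the Calpha B-factors of each chain against that chain's own mean
#' and standard deviation: `Bnorm(i,j) = (B(i,j) - mean_j) / sd_j`. Raw
#' B-factors are not comparable across structures (resolution, temperature
#' and refinement protocol shift and scale them); the z-score removes any
#' affine per-structure effect, which is the normalization's purpose. The
#' sample (n - 1) standard deviation is used (switchable).
#'
#' @param chains Residue-level chains tibble with a `bfactor` column
#'   (Calpha B-factors; `NA` rows are ignored).
#' @param sample_sd Use the n-1 denominator (default) or the population n
#'   denominator.
#' @return `chains` with an added `bnorm` column; per chain the non-`NA`
#'   `bnorm` values have mean 0 and sd 1 (within 1e-9).
#' @export
normalize_bfactors <- function(chains, sample_sd = TRUE) {
  zfun <- function(b, ref) {
    obs <- b[!is.na(b)]
    if (length(obs) < 2) {
      abort(paste0("chain ", ref, ": need at least 2 Calpha B-factors"))
    }
    s <- if (sample_sd) sd(obs) else sqrt(mean((obs - mean(obs))^2))
    if (!is.finite(s) || s == 0) {
      abort(paste0("degenerate B-factor column in chain ", ref,
                   " (all values equal)"))
    }
    (b - mean(obs)) / s
  }
  chains %>%
    group_by(.data$chain_ref) %>%
    mutate(bnorm = zfun(.data$bfactor, .data$chain_ref[1])) %>%
    ungroup()
}

#' Per-position flexibility from normalized B-factors
#'
#' Averages Bnorm over every chain contributing a Calpha at each aligned
#' position (one vote per chain, homo-oligomer copies included) and applies
#' the sign rule: positions with mean Bnorm strictly greater than zero are
#' `flexible`, all others `rigid`. Positions with no contributor are `NA`.
#'
#' @param chains Chains tibble carrying a `bnorm` column (see
#'   [normalize_bfactors()]).
#' @param pos_map Position map tibble (`chain_ref`, `aligned_pos`, `resnum`,
#'   `icode`) from [read_alignment()] / an `msla`.
#' @return Tibble: `position`, `mean_bnorm`, `n_chains`, `flex_class`.
#' @export
position_flexibility <- function(chains, pos_map) {
  if (!"bnorm" %in% names(chains)) {
    abort("`chains` must carry a `bnorm` column; run normalize_bfactors() first")
  }
  joined <- pos_map %>%
    left_join(chains %>% select("chain_ref", "resnum", "icode", "bnorm"),
              by = c("chain_ref", "resnum", "icode"))
  all_pos <- tibble(position = seq_len(max(pos_map$aligned_pos)))
  joined %>%
    filter(!is.na(.data$bnorm)) %>%
    group_by(position = .data$aligned_pos) %>%
    summarise(mean_bnorm = mean(.data$bnorm), n_chains = n(),
              .groups = "drop") %>%
    dplyr::right_join(all_pos, by = "position") %>%
    arrange(.data$position) %>%
    mutate(n_chains = tidyr::replace_na(.data$n_chains, 0L),
           flex_class = dplyr::case_when(
             is.na(.data$mean_bnorm) ~ NA_character_,
             .data$mean_bnorm > 0 ~ "flexible",
             TRUE ~ "rigid"
           ))
}
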