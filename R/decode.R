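# Per-letter Gaussian log-densities for an n x 4 descriptor matrix.
# Floored at LOGP_FLOOR so numerical underflow can never propagate -Inf/NaN
# through the Viterbi recursion.
LOGP_FLOOR <- -1e12

log_emissions <- function(obs, model) {
  obs <- as.matrix(obs)
  n <- nrow(obs)
  L <- length(model$letters)
  out <- matrix(LOGP_FLOOR, n, L)
  for (j in seq_len(L)) {
    S <- model$covariances[, , j]
    ch <- chol(S)
    logdet <- 2 * sum(log(diag(ch)))
    centered <- sweep(obs, 2, model$means[j, ])
    z <- backsolve(ch, t(centered), transpose = TRUE)
    maha <- colSums(z^2)
    lp <- -0.5 * (4 * log(2 * pi) + logdet + maha)
    out[, j] <- pmax(lp, LOGP_FLOOR)
  }
  if (anyNA(out)) abort("emission density evaluation produced NaN")
  out
}

#' Viterbi decoding of descriptor sequences
#'
#' Computes the maximum-probability structural-letter path for a sequence of
#' four-Calpha fragment descriptors under an [alphabet_model()]: Gaussian
#' emissions, first-order Markov transitions, all arithmetic in log space with
#' a floor of -1e12 on log densities so underflow never yields NaN. Ties are
#' broken toward the lower letter index.
#'
#' @param obs An n x 4 matrix of fragment descriptors (rows in chain order),
#'   or anything coercible to one.
#' @param model An `alphabet_model`.
#' @return Character vector of n letters (the decoded path).
#' @export
#' @examples
#' m <- alphabet_model(c("A", "B"),
#'   means = rbind(c(5.1, 5.0, 5.1, 2.2), c(6.5, 9.8, 6.5, 0.4)),
#'   covariances = diag(0.09, 4))
#' viterbi_decode(rbind(c(5.1, 5.0, 5.1, 2.2)), m)
viterbi_decode <- function(obs, model) {
  obs <- as.matrix(obs)
  if (nrow(obs) == 0) abort("empty observation sequence")
  validate_alphabet_model(model)
  le <- log_emissions(obs, model)
  n <- nrow(le)
  L <- ncol(le)
  logA <- log(model$transitions)
  logA[logA < LOGP_FLOOR] <- LOGP_FLOOR
  logpi <- log(model$initial)
  logpi[logpi < LOGP_FLOOR] <- LOGP_FLOOR
  delta <- matrix(NA_real_, n, L)
  psi <- matrix(NA_integer_, n, L)
  delta[1, ] <- logpi + le[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in seq_len(L)) {
        cand <- delta[t - 1, ] + logA[, j]
        k <- which.max(cand)  # first max -> lower-index tie-break
        psi[t, j] <- k
        delta[t, j] <- cand[k] + le[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  model$letters[path]
}

# nearest emission mean by Mahalanobis distance (per-letter covariance);
# explicit fallback when no transition matrix is trusted
nearest_centroid_decode <- function(obs, model) {
  obs <- as.matrix(obs)
  L <- length(model$letters)
  d2 <- matrix(NA_real_, nrow(obs), L)
  for (j in seq_len(L)) {
    ch <- chol(model$covariances[, , j])
    z <- backsolve(ch, t(sweep(obs, 2, model$means[j, ])), transpose = TRUE)
    d2[, j] <- colSums(z^2)
  }
  model$letters[apply(d2, 1, which.min)]
}

#' Encode protein chains as structural-letter sequences
#'
#' Slides a four-Calpha window along every maximal run of consecutive residues
#' (author numbering step of exactly 1 with a Calpha present) and decodes each
#' run's descriptor sequence into structural letters. A gap-free run of q
#' residues contributes q - 3 letters; each letter is anchored to the third
#' residue of its fragment. Chain breaks split runs: no letter ever spans a
#' break, and no geometry is interpolated across one.
#'
#' @param chains A residue-level tibble as returned by [read_structures()]
#'   (`$chains`): columns `chain_ref`, `resnum`, `x`, `y`, `z` at minimum.
#' @param model An `alphabet_model`.
#' @param mode `"viterbi"` (default) or `"nearest_centroid"`.
#' @return A tibble with columns `chain_ref`, `resnum` (the anchor residue of
#'   the fragment) and `letter`.
#' @export
encode_chains <- function(chains, model, mode = c("viterbi", "nearest_centroid")) {
  mode <- match.arg(mode)
  validate_alphabet_model(model)
  chains %>%
    dplyr::group_split(.data$chain_ref) %>%
    purrr::map(encode_one_chain, model = model, mode = mode) %>%
    bind_rows()
}

encode_one_chain <- function(res, model, mode) {
  res <- arrange(res, .data$resnum)
  ok <- is.finite(res$x) & is.finite(res$y) & is.finite(res$z)
  res <- res[ok, , drop = FALSE]
  if (nrow(res) < 4) {
    abort(paste0("chain ", res$chain_ref[1], " too fragmented to encode"))
  }
  run_id <- cumsum(c(1L, as.integer(diff(res$resnum) != 1L)))
  runs <- split(seq_len(nrow(res)), run_id)
  if (!any(lengths(runs) >= 4)) {
    abort(paste0("chain ", res$chain_ref[1], " too fragmented to encode"))
  }
  out <- purrr::map(runs[lengths(runs) >= 4], function(idx) {
    coords <- as.matrix(res[idx, c("x", "y", "z")])
    obs <- sliding_descriptors(coords)
    letters <- if (mode == "viterbi") viterbi_decode(obs, model)
               else nearest_centroid_decode(obs, model)
    tibble(chain_ref = res$chain_ref[idx[1]],
           resnum = res$resnum[idx][3:(length(idx) - 1L)],
           letter = letters)
  })
  bind_rows(out)
}
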