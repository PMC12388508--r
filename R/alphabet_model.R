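#' Construct a structural-alphabet model
#'
#' A structural alphabet classifies the geometry of overlapping four-Calpha
#' backbone fragments into a small set of symbolic states ("structural
#' letters"). Each letter carries a Gaussian emission density over the
#' four-dimensional fragment descriptor (three inter-Calpha distances plus a
#' signed chirality projection, see [fragment_descriptors()]), and letters are
#' chained by a first-order Markov transition matrix so that a chain's letter
#' sequence can be decoded by the Viterbi algorithm. The canonical published
#' alphabet has 27 letters labelled `a, A..Z`; its fitted parameters are not
#' part of this package and are loaded from a JSON model file
#' ([read_alphabet_model()]). Reduced synthetic models are valid and are what
#' the test-suite and generator use.
#'
#' @param letters Character vector of distinct single-character letter symbols.
#' @param means Numeric matrix, one row per letter, 4 columns
#'   (`d13`, `d14`, `d24`, `chi`), in Angstrom.
#' @param covariances Either a 4 x 4 x n_letters array of per-letter emission
#'   covariances, or a single 4 x 4 matrix recycled to every letter. Each must
#'   be symmetric positive-definite.
#' @param transitions Row-stochastic n x n transition matrix. Defaults to the
#'   uniform matrix.
#' @param initial Stochastic initial-state vector. Defaults to uniform.
#' @param ss_class Character vector mapping each letter to a secondary
#'   structure class (`"helix"`, `"strand"`, `"loop"`); used for logo
#'   colouring. Defaults to `"loop"`.
#'
#' @return An object of class `alphabet_model`.
#' @export
#' @examples
#' m <- alphabet_model(
#'   letters = c("A", "B"),
#'   means = rbind(A = c(5.1, 5.0, 5.1, 2.2), B = c(6.5, 9.8, 6.5, 0.4)),
#'   covariances = diag(0.09, 4)
#' )
#' m$letters
alphabet_model <- function(letters, means, covariances,
                           transitions = NULL, initial = NULL,
                           ss_class = NULL) {
  letters <- as.character(letters)
  n <- length(letters)
  means <- as.matrix(means)
  if (is.matrix(covariances) && length(dim(covariances)) == 2L) {
    covariances <- array(rep(covariances, n), dim = c(4, 4, n))
  }
  if (is.null(transitions)) {
    transitions <- matrix(1 / n, n, n)
  }
  if (is.null(initial)) initial <- rep(1 / n, n)
  if (is.null(ss_class)) ss_class <- rep("loop", n)
  dimnames(means) <- list(letters, c("d13", "d14", "d24", "chi"))
  dimnames(transitions) <- list(letters, letters)
  names(initial) <- letters
  names(ss_class) <- letters
  model <- structure(
    list(letters = letters, means = means, covariances = covariances,
         transitions = transitions, initial = initial, ss_class = ss_class),
    class = "alphabet_model"
  )
  validate_alphabet_model(model)
  model
}

#' Validate an alphabet model
#'
#' Checks the structural-alphabet invariants: distinct letters, 4-column
#' emission means, symmetric positive-definite covariances, row-stochastic
#' transitions (rows sum to 1 within 1e-9) and a stochastic initial vector.
#'
#' @param model An `alphabet_model`.
#' @return `model`, invisibly, if valid; otherwise an error.
#' @export
validate_alphabet_model <- function(model) {
  n <- length(model$letters)
  if (n < 2) abort("alphabet model needs at least 2 letters")
  if (anyDuplicated(model$letters)) abort("duplicate letter symbols")
  if (!is.matrix(model$means) || nrow(model$means) != n || ncol(model$means) != 4) {
    abort("emission means must be an n_letters x 4 matrix")
  }
  if (!all(dim(model$covariances) == c(4, 4, n))) {
    abort("covariances must be a 4 x 4 x n_letters array")
  }
  for (i in seq_len(n)) {
    S <- model$covariances[, , i]
    if (max(abs(S - t(S))) > 1e-8) abort("covariance not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort("covariance not positive-definite")
  }
  if (!all(dim(model$transitions) == c(n, n))) abort("transition matrix shape")
  if (max(abs(rowSums(model$transitions) - 1)) > 1e-9) {
    abort("transition rows must sum to 1 (within 1e-9)")
  }
  if (any(model$transitions < 0)) abort("negative transition probability")
  if (abs(sum(model$initial) - 1) > 1e-9 || any(model$initial < 0)) {
    abort("initial vector must be stochastic")
  }
  if (length(model$ss_class) != n ||
      !all(model$ss_class %in% c("helix", "strand", "loop"))) {
    abort("ss_class must map every letter to helix/strand/loop")
  }
  invisible(model)
}

#' Read an alphabet model from a JSON file
#'
#' The model file schema has keys `letters`, `means` (n x 4), `covariances`
#' (list of 4 x 4), `transitions` (n x n), `initial` (n) and `ss_class` (n).
#' The schema is validated on load.
#'
#' @param path Path to the JSON model file.
#' @return An `alphabet_model`.
#' @export
read_alphabet_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("letters", "means", "covariances", "transitions", "initial", "ss_class")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("alphabet model file missing keys: ",
                 paste(missing, collapse = ", ")))
  }
  n <- length(x$letters)
  covs <- x$covariances
  if (is.list(covs)) {
    covs <- array(unlist(covs), dim = c(4, 4, n))
  } else if (length(dim(covs)) == 3L) {
    # jsonlite simplifies a list of 4x4 matrices to an n x 4 x 4 array
    covs <- aperm(covs, c(2, 3, 1))
  }
  alphabet_model(
    letters = x$letters,
    means = matrix(unlist(x$means), nrow = n, ncol = 4, byrow = is.list(x$means)),
    covariances = covs,
    transitions = matrix(unlist(x$transitions), n, n, byrow = is.list(x$transitions)),
    initial = as.numeric(x$initial),
    ss_class = as.character(x$ss_class)
  )
}

#' Write an alphabet model to a JSON file
#'
#' @param model An `alphabet_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alphabet_model <- function(model, path) {
  validate_alphabet_model(model)
  n <- length(model$letters)
  out <- list(
    letters = model$letters,
    means = lapply(seq_len(n), function(i) unname(model$means[i, ])),
    covariances = lapply(seq_len(n), function(i) unname(model$covariances[, , i])),
    transitions = lapply(seq_len(n), function(i) unname(model$transitions[i, ])),
    initial = unname(model$initial),
    ss_class = unname(model$ss_class)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.alphabet_model <- function(x, ...) {
  cat("<alphabet_model> ", length(x$letters), " letters: ",
      paste(x$letters, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Tidy an alphabet model into a per-letter tibble
#'
#' @param x An `alphabet_model`.
#' @param ... Unused.
#' @return A tibble with one row per letter: the four emission means, the
#'   self-transition probability and the secondary-structure class.
#' @method tidy alphabet_model
#' @export
tidy.alphabet_model <- function(x, ...) {
  tibble(
    letter = x$letters,
    d13 = x$means[, "d13"], d14 = x$means[, "d14"],
    d24 = x$means[, "d24"], chi = x$means[, "chi"],
    self_transition = diag(x$transitions),
    ss_class = unname(x$ss_class)
  )
}
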