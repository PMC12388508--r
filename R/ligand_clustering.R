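#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over the set bits of two equal-length binary
#' fingerprints (166 bits for the MACCS structural-key scheme, but any fixed
#' length works).
#'
#' @param a,b Binary (0/1 or logical) vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 2/4
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) abort("fingerprints differ in length")
  u <- sum(a | b)
  if (u == 0) abort("undefined similarity for empty fingerprints")
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' All pairwise scores, rounded to three decimal places before storage (so
#' downstream clustering sees exactly the stored values), in a symmetric
#' matrix with unit diagonal.
#'
#' @param fingerprints Binary matrix, one row per ligand (rownames are ligand
#'   identifiers), or a tibble with columns `ligand_ref` and `bits` (list of
#'   equal-length 0/1 vectors).
#' @return Symmetric numeric matrix in `[0, 1]`.
#' @export
tanimoto_matrix <- function(fingerprints) {
  if (is.data.frame(fingerprints)) {
    m <- do.call(rbind, fingerprints$bits)
    rownames(m) <- fingerprints$ligand_ref
    fingerprints <- m
  }
  M <- (as.matrix(fingerprints) != 0) * 1L
  nbits <- rowSums(M)
  if (any(nbits == 0)) {
    abort(paste0("undefined similarity for empty fingerprints: ",
                 paste(rownames(M)[nbits == 0], collapse = ", ")))
  }
  inter <- M %*% t(M)
  uni <- outer(nbits, nbits, "+") - inter
  sim <- round(inter / uni, 3)
  diag(sim) <- 1
  sim
}

#' Hierarchical ligand clustering with singleton removal
#'
#' Clusters ligands on the dissimilarity `1 - Tanimoto` with Ward's
#' minimum-variance linkage in the variant that squares the input
#' dissimilarities internally (`stats::hclust(method = "ward.D2")`), cuts the
#' tree into `k` groups, drops groups of size 1, and relabels the survivors
#' `1..m` in order of their first member in the input ordering. With the
#' published protocol's `k = 7` and one outlier ligand this yields six
#' retained clusters.
#'
#' @param sim Symmetric similarity matrix from [tanimoto_matrix()].
#' @param k Number of tree cuts (default 7).
#' @return An object of class `ligand_clusters`: list with `assignments`
#'   (tibble `ligand_ref`, `cluster`; singletons excluded), `dropped`
#'   (singleton ligand ids), `tree` (the `hclust` object), `k`.
#' @export
cluster_ligands <- function(sim, k = 7) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (k > n) abort(paste0("k = ", k, " exceeds the number of ligands (", n, ")"))
  if (is.null(rownames(sim))) rownames(sim) <- colnames(sim) <- paste0("L", seq_len(n))
  d <- as.dist(1 - sim)
  tree <- hclust(d, method = "ward.D2")
  raw <- cutree(tree, k = k)
  sizes <- table(raw)
  keep_labels <- as.integer(names(sizes)[sizes > 1])
  dropped <- names(raw)[!(raw %in% keep_labels)]
  kept <- raw[raw %in% keep_labels]
  first_seen <- unique(unname(kept))  # order of first member in input order
  relabel <- setNames(seq_along(first_seen), first_seen)
  assignments <- tibble(ligand_ref = names(kept),
                        cluster = unname(relabel[as.character(kept)]))
  structure(list(assignments = assignments, dropped = dropped,
                 tree = tree, k = k),
            class = "ligand_clusters")
}

#' @export
print.ligand_clusters <- function(x, ...) {
  cat("<ligand_clusters> k = ", x$k, ": ",
      n_distinct(x$assignments$cluster), " clusters retained, ",
      length(x$dropped), " singleton(s) dropped\n", sep = "")
  invisible(x)
}

#' Tidy ligand cluster assignments
#'
#' @param x A `ligand_clusters` object.
#' @param ... Unused.
#' @return The assignments tibble (`ligand_ref`, `cluster`).
#' @method tidy ligand_clusters
#' @export
tidy.ligand_clusters <- function(x, ...) x$assignments

#' One-line summary of a ligand clustering
#'
#' @param x A `ligand_clusters` object.
#' @param ... Unused.
#' @return Tibble: `k`, `n_clusters`, `n_ligands`, `n_dropped`.
#' @method glance ligand_clusters
#' @export
glance.ligand_clusters <- function(x, ...) {
  tibble(k = x$k,
         n_clusters = n_distinct(x$assignments$cluster),
         n_ligands = nrow(x$assignments),
         n_dropped = length(x$dropped))
}
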