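test_that("fragment descriptors are rigid-motion invariant and mirror-antisymmetric", {
  set.seed(1)
  for (i in 1:20) {
    frag <- matrix(rnorm(12, sd = 3), 4, 3)
    base <- tryCatch(fragment_descriptors(frag), error = function(e) NULL)
    if (is.null(base)) next
    # translation
    expect_equal(fragment_descriptors(sweep(frag, 2, c(10, 0, 0), "+")), base)
    # random proper rotation + translation
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    moved <- sweep(frag %*% t(q), 2, rnorm(3, sd = 5), "+")
    expect_equal(fragment_descriptors(moved), base, tolerance = 1e-9)
    # mirror image: distances equal, chi negated
    mirror <- frag %*% diag(c(1, 1, -1))
    md <- fragment_descriptors(mirror)
    expect_equal(md[c("d13", "d14", "d24")], base[c("d13", "d14", "d24")])
    expect_equal(md[["chi"]], -base[["chi"]], tolerance = 1e-9)
  }
})

test_that("ideal-helix descriptors match the closed-form chord lengths", {
  r <- 2.3; rise <- 1.5; tw <- 100 * pi / 180
  helix <- ideal_helix_coords(4, radius = r, rise = rise, twist_deg = 100)
  d <- fragment_descriptors(helix)
  chord <- function(k) sqrt((2 * r * sin(k * tw / 2))^2 + (rise * k)^2)
  expect_equal(d[["d13"]], chord(2), tolerance = 1e-12)
  expect_equal(d[["d14"]], chord(3), tolerance = 1e-12)
  expect_equal(d[["d24"]], chord(2), tolerance = 1e-12)
  expect_gt(d[["chi"]], 0)  # right-handed helix
  # left-handed mirror helix flips the chirality sign only
  left <- ideal_helix_coords(4) %*% diag(c(1, -1, 1))
  expect_equal(fragment_descriptors(left)[["chi"]], -d[["chi"]], tolerance = 1e-12)
})

test_that("degenerate fragments raise the chirality error", {
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(fragment_descriptors(collinear), "chirality")
})

test_that("alphabet model invariants are enforced and JSON round-trips", {
  m <- make_alphabet(5, seed = 3)
  expect_silent(validate_alphabet_model(m))
  expect_equal(rowSums(m$transitions), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  path <- tempfile(fileext = ".json")
  write_alphabet_model(m, path)
  m2 <- read_alphabet_model(path)
  expect_equal(m2$means, m$means, tolerance = 1e-12)
  expect_equal(m2$transitions, m$transitions, tolerance = 1e-12)
  expect_equal(m2$covariances, m$covariances, tolerance = 1e-12)
  expect_identical(m2$letters, m$letters)
  # schema errors
  bad <- jsonlite::read_json(path)
  bad$transitions <- NULL
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_alphabet_model(path2), "missing keys")
  m_bad <- m
  m_bad$transitions[1, 1] <- m_bad$transitions[1, 1] + 0.1
  expect_error(validate_alphabet_model(m_bad), "sum to 1")
})

test_that("a single observation decodes to the initial-times-emission argmax", {
  m <- alphabet_model(c("A", "B"),
                      means = rbind(c(5, 5, 5, 2), c(7, 9, 7, -1)),
                      covariances = diag(0.25, 4),
                      initial = c(0.5, 0.5))
  expect_equal(viterbi_decode(rbind(c(5, 5, 5, 2)), m), "A")
  expect_equal(viterbi_decode(rbind(c(7, 9, 7, -1)), m), "B")
  # a lopsided prior can flip a near-tie observation
  m_sk <- alphabet_model(c("A", "B"),
                         means = rbind(c(5, 5, 5, 2), c(5.2, 5.2, 5.2, 2)),
                         covariances = diag(1, 4),
                         initial = c(0.999, 0.001))
  expect_equal(viterbi_decode(rbind(c(5.19, 5.19, 5.19, 2)), m_sk), "A")
})

test_that("Viterbi equals exhaustive path enumeration on small models", {
  set.seed(7)
  for (rep in 1:5) {
    n_states <- sample(2:3, 1)
    m <- make_alphabet(n_states, mean_separation = 2, seed = rep, sigma = 0.8)
    n_obs <- sample(3:4, 1)
    obs <- m$means[sample(n_states, n_obs, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(4 * n_obs, sd = 0.6), n_obs, 4)
    expect_identical(viterbi_decode(obs, m), unname(brute_viterbi(obs, m)))
  }
})

test_that("with near-identity transitions and separated emissions, Viterbi matches nearest-mean assignment", {
  m <- make_alphabet(4, mean_separation = 10, seed = 2, sigma = 0.3,
                     self_bias = 0)
  m$transitions <- 0.99 * diag(4) + 0.01 / 4 +
    matrix(0, 4, 4)
  m$transitions <- m$transitions / rowSums(m$transitions)
  set.seed(9)
  truth <- sample(4, 30, replace = TRUE)
  obs <- m$means[truth, ] + matrix(rnorm(120, sd = 0.2), 30, 4)
  nearest <- m$letters[apply(obs, 1, function(x) {
    which.min(colSums((t(m$means) - x)^2))
  })]
  expect_identical(viterbi_decode(obs, m), nearest)
})

test_that("the decoded path beats 1000 random alternative paths in log-probability", {
  m <- make_alphabet(3, mean_separation = 4, seed = 5, sigma = 0.5)
  set.seed(11)
  obs <- m$means[sample(3, 6, replace = TRUE), ] + matrix(rnorm(24, sd = 0.4), 6, 4)
  path_logp <- function(path_idx) {
    lp <- log(m$initial[path_idx[1]])
    for (t in seq_along(path_idx)) {
      S <- m$covariances[, , path_idx[t]]
      x <- obs[t, ] - m$means[path_idx[t], ]
      lp <- lp - 0.5 * (4 * log(2 * pi) + determinant(S)$modulus[1] +
                          t(x) %*% solve(S) %*% x)
      if (t > 1) lp <- lp + log(m$transitions[path_idx[t - 1], path_idx[t]])
    }
    as.numeric(lp)
  }
  best <- path_logp(match(viterbi_decode(obs, m), m$letters))
  for (i in 1:1000) {
    expect_gte(best, path_logp(sample(3, 6, replace = TRUE)))
  }
})

test_that("chain encoding yields p - 3 letters anchored at third residues, split at breaks", {
  m <- make_alphabet(3, seed = 1)
  helix <- ideal_helix_coords(10)
  chain <- tibble::tibble(chain_ref = "X_A", resnum = 1:10,
                          x = helix[, 1], y = helix[, 2], z = helix[, 3])
  sl <- encode_chains(chain, m)
  expect_equal(nrow(sl), 7)           # p - 3
  expect_equal(sl$resnum, 3:9)        # third residue of each window
  # numbering gap -> runs of 6 and 5 -> 3 + 2 letters, none spanning the break
  helix11 <- ideal_helix_coords(11)
  chain_gap <- tibble::tibble(chain_ref = "X_A", resnum = c(1:6, 10:14),
                              x = helix11[, 1], y = helix11[, 2],
                              z = helix11[, 3])
  sl_gap <- encode_chains(chain_gap, m)
  expect_equal(nrow(sl_gap), 5)
  expect_equal(sl_gap$resnum, c(3, 4, 5, 12, 13))
  # too fragmented
  expect_error(encode_chains(chain[1:3, ], m), "too fragmented")
})

test_that("a 30-residue ideal helix encodes as 27 copies of the helix letter", {
  ens_model <- make_ensemble(n_chains = 2, n_residues = 10,
                             variable_positions = integer(),
                             flexible_positions = integer(),
                             seed = 3, n_blobs = 0, jitter = 0)$model
  helix <- ideal_helix_coords(30)
  chain <- tibble::tibble(chain_ref = "H_A", resnum = 1:30,
                          x = helix[, 1], y = helix[, 2], z = helix[, 3])
  for (mode in c("viterbi", "nearest_centroid")) {
    sl <- encode_chains(chain, ens_model, mode = mode)
    expect_equal(nrow(sl), 27)
    expect_true(all(sl$letter == "A"))
  }
})

test_that("encoding is invariant under a rigid-body transform of the whole chain", {
  m <- make_ensemble(n_chains = 2, n_residues = 12, variable_positions = 6,
                     flexible_positions = integer(), seed = 8, n_blobs = 0)$model
  helix <- ideal_helix_coords(12)
  chain <- tibble::tibble(chain_ref = "R_A", resnum = 1:12,
                          x = helix[, 1], y = helix[, 2], z = helix[, 3])
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- sweep(helix %*% t(q), 2, c(11, -4, 60), "+")
  chain2 <- chain
  chain2[, c("x", "y", "z")] <- moved
  expect_identical(encode_chains(chain, m)$letter, encode_chains(chain2, m)$letter)
})

test_that("decoding recovers planted letters exactly on well-separated synthetic ensembles", {
  ens <- make_ensemble(n_chains = 12, n_residues = 40,
                       variable_positions = c(10, 20, 30),
                       flexible_positions = integer(), seed = 17, n_blobs = 0)
  st <- read_structures(ens$pdb_files, curation_config(min_length = 20))
  sl <- encode_chains(st$chains, ens$model)
  msla <- build_msla(read_alignment(ens$fasta, st$chains), sl)
  planted <- ens$truth$planted_letters
  got <- tidy(msla) %>%
    dplyr::inner_join(planted, by = c("chain_ref", aligned_pos = "position"))
  expect_equal(mean(got$letter.x == got$letter.y), 1)
})
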