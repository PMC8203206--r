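# Toy-model builders and brute-force oracles shared across the suite.
# The oracles deliberately use naive scalar loops / third-party routines so
# they stay independent of the package's vectorised implementations.

# Build a complex_model from a compact atom spec:
# a data.frame (or list of rows) with chain, resno, elety, x, y, z and
# optional resid/elesy/insert/o.
toy_model <- function(atoms, model_id = "toy") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$resid)) atoms$resid <- "GLY"
  if (is.null(atoms$elesy)) atoms$elesy <- substr(atoms$elety, 1, 1)
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  complex_model(atoms, model_id = model_id, source = "synthetic")
}

# Two chains, one single-atom residue each, at given coordinates.
two_point_model <- function(xyz_a, xyz_b, model_id = "pts") {
  toy_model(data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), elety = "CA",
    x = c(xyz_a[1], xyz_b[1]), y = c(xyz_a[2], xyz_b[2]),
    z = c(xyz_a[3], xyz_b[3])), model_id = model_id)
}

# Random two-chain model: n_res residues of 4 heavy atoms per chain,
# chains occupying overlapping boxes so some contacts exist.
random_two_chain_model <- function(seed, n_res = 25L, model_id = NULL) {
  set.seed(seed)
  if (is.null(model_id)) model_id <- sprintf("rand_%d", seed)
  one_chain <- function(chain, x0) {
    centers <- cbind(runif(n_res, x0, x0 + 15), runif(n_res, 0, 15),
                     runif(n_res, 0, 15))
    do.call(rbind, lapply(seq_len(n_res), function(i) {
      data.frame(chain = chain, resno = i,
                 elety = c("N", "CA", "C", "O"),
                 x = centers[i, 1] + rnorm(4, sd = 0.8),
                 y = centers[i, 2] + rnorm(4, sd = 0.8),
                 z = centers[i, 3] + rnorm(4, sd = 0.8),
                 stringsAsFactors = FALSE)
    }))
  }
  toy_model(rbind(one_chain("A", 0), one_chain("B", 10)),
            model_id = model_id)
}

# O(N^2) scalar-loop oracle for per-residue minimum inter-chain distance.
brute_dmin <- function(model) {
  at <- model$atoms
  keys <- unique(at$key)
  out <- setNames(rep(Inf, length(keys)), keys)
  n <- nrow(at)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (at$chain[i] == at$chain[j]) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
      if (d < out[[at$key[i]]]) out[[at$key[i]]] <- d
    }
  }
  out
}

# Brute-force inter-chain residue contact list at a cutoff.
brute_contacts <- function(model, cutoff) {
  at <- model$atoms
  keys <- unique(at$key)
  chains <- vapply(keys, function(k) at$chain[at$key == k][1], character(1))
  hits <- character(0)
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (chains[i] >= chains[j]) next
      d <- residue_min_distance(at[at$key == keys[i], ],
                                at[at$key == keys[j], ])
      if (d <= cutoff) hits <- c(hits, paste(keys[i], keys[j], sep = "--"))
    }
  }
  sort(hits)
}

# Apply a rigid transform (rotation about z by `deg`, then translation)
# to every atom of a model.
rigid_transform_model <- function(model, deg = 30, shift = c(1, 2, 3)) {
  th <- deg * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  at[, c("x", "y", "z")] <- xyz
  complex_model(at, model_id = model$model_id, source = "synthetic")
}

# Relabel a model (same structure, new id) so pools of "identical" models
# can be formed.
relabel <- function(model, id) {
  complex_model(model$atoms, model_id = id, source = model$source)
}

# The worked 2-model pool: one single-atom residue per chain; the scored
# model has the chains in contact (Dmin 0), the other has them 20 A apart.
worked_example_pool <- function() {
  m1 <- two_point_model(c(0, 0, 0), c(0, 0, 0), "contact")
  m2 <- two_point_model(c(0, 0, 0), c(20, 0, 0), "apart")
  build_pool(list(m1, m2), target_id = "worked")
}
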