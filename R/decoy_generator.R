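#' @title Synthetic decoy-pool generator
#' @description Seeded generation of reference two-chain complexes
#'   (idealised antiparallel helix dimers, the shape of coiled-coil
#'   interfaces) and rigid-body-perturbed decoy pools with known
#'   ground-truth quality, so every scoring stage can be exercised
#'   end-to-end without external inputs.
#' @name decoy_generator
NULL

# Ideal alpha-helix constants: 1.5 A rise and 100 degrees twist per
# residue; each backbone atom type sits on its own coaxial helix with a
# fixed radius, phase and axial offset relative to CA. The constants give
# plausible (not refined) bond geometry -- the generator needs a
# realistic-looking 5 A interface, not biophysical accuracy.
HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180
HELIX_ATOMS <- data.frame(
  elety = c("N", "CA", "C", "O", "CB"),
  elesy = c("N", "C", "C", "O", "C"),
  radius = c(1.56, 2.28, 1.64, 1.97, 3.29),
  dphase = c(-28.9, 0, 29.9, 44.0, -33.0) * pi / 180,
  dz = c(-0.95, 0, 1.06, 2.00, -0.77),
  stringsAsFactors = FALSE)

# Evaluate code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# Counter-based per-decoy seed: decoys are independent of pool size, so
# growing a pool never reshuffles earlier members. Kept within 32-bit
# signed range.
decoy_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 16807) %% 2147483647)
}

helix_chain <- function(n_res, chain, phase0 = 0) {
  rows <- lapply(seq_len(n_res), function(i) {
    theta <- phase0 + (i - 1L) * HELIX_TWIST + HELIX_ATOMS$dphase
    data.frame(chain = chain, resno = i, insert = "", resid = "ALA",
               elety = HELIX_ATOMS$elety, elesy = HELIX_ATOMS$elesy,
               x = HELIX_ATOMS$radius * cos(theta),
               y = HELIX_ATOMS$radius * sin(theta),
               z = (i - 1L) * HELIX_RISE + HELIX_ATOMS$dz,
               o = 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate an idealised two-helix reference dimer
#'
#' Two ideal alpha-helical poly-alanine chains (backbone N, CA, C, O plus
#' CB), chain A along the z axis and chain B antiparallel with its axis
#' 9 A away, guaranteeing a non-empty interface at the 5 A heavy-atom
#' cutoff. The helix phases are drawn from the seed, so different seeds
#' give different (but always contacting) interfaces; the same seed gives
#' bit-identical coordinates.
#'
#' @param n_res_per_chain residues per chain (>= 5).
#' @param seed integer seed.
#' @return A [complex_model()] with chains A and B.
#' @export
make_reference_dimer <- function(n_res_per_chain, seed = 1L) {
  if (n_res_per_chain < 5L)
    stop_input("a helix dimer needs >= 5 residues per chain (got %d)",
               n_res_per_chain)
  phases <- with_seed(seed, runif(2, 0, 2 * pi))
  a <- helix_chain(n_res_per_chain, "A", phases[1L])
  b <- helix_chain(n_res_per_chain, "B", phases[2L])
  # antiparallel: flip about the x axis, then separate axes along x
  b$y <- -b$y
  b$z <- -b$z + (n_res_per_chain - 1L) * HELIX_RISE  # re-span the same z range
  b$x <- b$x + 9
  complex_model(rbind(a, b),
                model_id = sprintf("ref_dimer_n%d_s%d", n_res_per_chain, seed),
                source = "synthetic")
}

rotation_about_axis <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle_rad)
  s_ <- sin(angle_rad)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Rigid-body perturbation of the ligand chain
#'
#' Rotates chain B of the reference about its own centroid by
#' `rotation` degrees around a seeded random axis, translates it by
#' `translation` Angstrom along a seeded random direction (or a fixed
#' `direction` if given), and optionally adds per-atom Gaussian jitter of
#' standard deviation `jitter_sd` to chain B. Chain A and all residue
#' keys are untouched, so the decoy stays comparable to the reference.
#'
#' @param reference a [complex_model()] (chains A and B).
#' @param rotation rotation magnitude, degrees (>= 0).
#' @param translation translation magnitude, Angstrom (>= 0).
#' @param jitter_sd per-atom Gaussian noise sd, Angstrom (>= 0).
#' @param seed integer seed.
#' @param direction optional length-3 translation direction (normalised
#'   internally); default: seeded random direction.
#' @param model_id id for the perturbed model.
#' @return A [complex_model()].
#' @export
perturb_model <- function(reference, rotation = 0, translation = 0,
                          jitter_sd = 0, seed = 1L, direction = NULL,
                          model_id = paste0(reference$model_id, "_pert")) {
  if (rotation < 0 || translation < 0 || jitter_sd < 0)
    stop_input("perturbation magnitudes must be non-negative")
  at <- reference$atoms
  moving <- at$chain == "B"
  if (!any(moving))
    stop_input("reference has no chain B to perturb")
  xyz <- as.matrix(at[moving, c("x", "y", "z")])
  with_seed(seed, {
    axis <- random_unit_vector()
    dirv <- if (is.null(direction)) random_unit_vector() else {
      stopifnot(length(direction) == 3L)
      direction / sqrt(sum(direction^2))
    }
    centroid <- colMeans(xyz)
    rot <- rotation_about_axis(axis, rotation * pi / 180)
    xyz <- sweep(sweep(xyz, 2L, centroid) %*% t(rot), 2L, centroid, "+")
    xyz <- sweep(xyz, 2L, dirv * translation, "+")
    if (jitter_sd > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), sd = jitter_sd), ncol = 3L)
  })
  at[moving, c("x", "y", "z")] <- xyz
  complex_model(at, model_id = model_id, source = "synthetic")
}

#' Specification of a synthetic decoy pool
#'
#' @param n_decoys number of decoys (>= 2).
#' @param rotation_max maximum rotation for far-from-native decoys,
#'   degrees.
#' @param translation_max maximum translation for far decoys, Angstrom.
#' @param jitter_sd per-atom Gaussian noise applied to every decoy's
#'   ligand chain, Angstrom.
#' @param seed integer seed; the pool is fully reproducible from it.
#' @param fraction_near_native fraction of decoys drawn with small
#'   perturbations (<= 5 degrees, <= 1 A).
#' @param n_res_per_chain residues per chain of the underlying reference
#'   dimer.
#' @return List of class `decoy_spec`.
#' @export
decoy_spec <- function(n_decoys = 30L, rotation_max = 30, translation_max = 15,
                       jitter_sd = 0.1, seed = 1L,
                       fraction_near_native = 0.4, n_res_per_chain = 20L) {
  if (n_decoys < 2L) stop_input("a decoy pool must allow a jury: n_decoys >= 2")
  if (rotation_max < 0 || translation_max < 0 || jitter_sd < 0)
    stop_input("decoy_spec magnitudes must be non-negative")
  if (fraction_near_native < 0 || fraction_near_native > 1)
    stop_input("fraction_near_native must lie in [0, 1]")
  structure(list(n_decoys = as.integer(n_decoys), rotation_max = rotation_max,
                 translation_max = translation_max, jitter_sd = jitter_sd,
                 seed = as.integer(seed),
                 fraction_near_native = fraction_near_native,
                 n_res_per_chain = as.integer(n_res_per_chain)),
            class = "decoy_spec")
}

#' Generate a decoy pool with known ground truth
#'
#' Builds the reference dimer for the spec's seed, then draws
#' `n_decoys` rigid-body decoys. Near-native decoys are striped evenly
#' through the counter sequence (decoy i is near-native when
#' `floor(i * f)` exceeds `floor((i - 1) * f)`), which yields
#' `floor(fraction_near_native * n_decoys)` of them while keeping the
#' assignment of each counter position independent of the pool size.
#' Near-native decoys draw rotation uniform on \[0, 5\] degrees and
#' translation uniform on \[0, 1\] A; the rest are far from native
#' (rotation uniform on
#' \[rotation_max/3, rotation_max\], translation uniform on
#' \[translation_max/3, translation_max\], random directions). Every
#' decoy's ligand chain also receives the spec's Gaussian jitter.
#' Ground-truth quality is the DockQ of each decoy against the
#' unperturbed reference. Each decoy draws from its own counter-derived
#' seed, so the pool is reproducible and earlier decoys are unchanged
#' when `n_decoys` grows.
#'
#' @param spec a [decoy_spec()].
#' @return List of class `decoy_pool`: `pool` (a [build_pool()] of the
#'   decoys), `ground_truth` (named DockQ-vs-reference values),
#'   `reference` (the unperturbed [complex_model()]), `manifest`
#'   (data.frame: model_id, kind, rotation, translation, jitter_sd,
#'   dockq_ref) and `spec`.
#' @export
generate_pool <- function(spec) {
  if (!inherits(spec, "decoy_spec")) stop_input("expected a decoy_spec")
  ref <- make_reference_dimer(spec$n_res_per_chain, spec$seed)
  f <- spec$fraction_near_native
  models <- vector("list", spec$n_decoys)
  manifest <- data.frame(model_id = character(spec$n_decoys),
                         kind = character(spec$n_decoys),
                         rotation = numeric(spec$n_decoys),
                         translation = numeric(spec$n_decoys),
                         jitter_sd = spec$jitter_sd,
                         dockq_ref = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_decoys)) {
    s_i <- decoy_seed(spec$seed, i)
    near <- floor(i * f) > floor((i - 1) * f)
    draw <- with_seed(s_i, runif(2))
    rot <- if (near) draw[1L] * 5 else
      spec$rotation_max / 3 + draw[1L] * spec$rotation_max * 2 / 3
    trans <- if (near) draw[2L] * 1 else
      spec$translation_max / 3 + draw[2L] * spec$translation_max * 2 / 3
    id <- sprintf("decoy_%03d", i)
    models[[i]] <- perturb_model(ref, rotation = rot, translation = trans,
                                 jitter_sd = spec$jitter_sd,
                                 seed = decoy_seed(s_i, 1L), model_id = id)
    manifest$model_id[i] <- id
    manifest$kind[i] <- if (near) "near_native" else "far"
    manifest$rotation[i] <- rot
    manifest$translation[i] <- trans
  }
  pool <- build_pool(models, target_id = ref$model_id)
  gt <- vapply(models, function(m) dockq(m, reference = ref)$dockq, numeric(1))
  names(gt) <- manifest$model_id
  manifest$dockq_ref <- unname(gt)
  structure(list(pool = pool, ground_truth = gt, reference = ref,
                 manifest = manifest, spec = spec),
            class = "decoy_pool")
}

#' @export
print.decoy_pool <- function(x, ...) {
  cat(sprintf("<decoy_pool> %d decoys of %s (%d near-native), ground-truth DockQ %.3f - %.3f\n",
              length(x$ground_truth), x$reference$model_id,
              sum(x$manifest$kind == "near_native"),
              min(x$ground_truth), max(x$ground_truth)))
  invisible(x)
}

#' Write a generated decoy pool to disk
#'
#' One numbered PDB file per decoy plus `manifest.tsv` (model id,
#' perturbation parameters, ground-truth DockQ).
#'
#' @param decoys a [generate_pool()] result.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_pool <- function(decoys, outdir) {
  if (!inherits(decoys, "decoy_pool")) stop_input("expected a decoy_pool")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (id in pool_ids(decoys$pool))
    write_pdb(decoys$pool$models[[id]], file.path(outdir, paste0(id, ".pdb")))
  write_pdb(decoys$reference, file.path(outdir, "reference.pdb"))
  manifest <- file.path(outdir, "manifest.tsv")
  write.table(decoys$manifest, manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}
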