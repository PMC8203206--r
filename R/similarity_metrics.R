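#' @title Pairwise model-vs-model similarity metrics
#' @description The kernels consumed by the jury scores: least-squares
#'   (Kabsch) superposition, the DockQ composite (fnat, interface RMSD,
#'   ligand RMSD) and the symmetric QS-score contact-overlap measure.
#'
#'   The DockQ constants are the published ones: ligand-RMSD scaling
#'   d1 = 8.5 A, interface-RMSD scaling d2 = 1.5 A, native-contact cutoff
#'   5 A, interface definition for the RMSD term at 10 A. QS-score uses
#'   C-beta contacts (C-alpha for glycine) at 12 A with weight 1 up to
#'   5 A and a Gaussian decay of width 4.28 A beyond.
#' @name similarity_metrics
NULL

DOCKQ_D1 <- 8.5   # A, ligand RMSD scaling
DOCKQ_D2 <- 1.5   # A, interface RMSD scaling
DOCKQ_FNAT_CUTOFF <- 5.0   # A, heavy-atom native contacts
DOCKQ_IFACE_CUTOFF <- 10.0 # A, interface residues for iRMS
QS_CONTACT_CUTOFF <- 12.0  # A, C-beta contact horizon
QS_FULL_WEIGHT <- 5.0      # A, below this weight = 1
QS_SIGMA <- 4.28           # A, Gaussian decay width
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mov_coords` onto `ref_coords` (rows paired). Reflections are rejected
#' by the determinant-sign correction of the SVD solution, so the rotation
#' always has determinant +1.
#'
#' @param ref_coords,mov_coords N x 3 matrices (N >= 3), Angstrom.
#' @return List of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd`. The fitted coordinates are
#'   `mov %*% t(rotation)` plus the translation, row-wise.
#' @export
kabsch_superpose <- function(ref_coords, mov_coords) {
  ref <- as.matrix(ref_coords)
  mov <- as.matrix(mov_coords)
  if (!identical(dim(ref), dim(mov)))
    stop_input("coordinate sets differ in shape (%d x %d vs %d x %d)",
               nrow(ref), ncol(ref), nrow(mov), ncol(mov))
  if (nrow(ref) < 3L)
    stop_input("superposition needs >= 3 atom pairs (got %d)", nrow(ref))
  c_ref <- colMeans(ref)
  c_mov <- colMeans(mov)
  a <- sweep(mov, 2L, c_mov)
  b <- sweep(ref, 2L, c_ref)
  s <- svd(crossprod(a, b))          # H = t(a) %*% b
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- c_ref - as.vector(rot %*% c_mov)
  fitted <- sweep(mov %*% t(rot), 2L, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

# Apply a superposition to an N x 3 coordinate matrix.
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2L, sup$translation, "+")
}

rmsd_plain <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

# Inter-chain residue contacts of a model at a heavy-atom cutoff:
# data.frame(key_a, key_b, dist) over all unordered chain pairs, with the
# chain pair oriented by sort order so contact identities are comparable
# across models.
model_contacts <- function(model, cutoff) {
  chains <- sort(chain_ids(model))
  out <- list()
  for (i in seq_len(length(chains) - 1L)) {
    for (j in seq((i + 1L), length(chains))) {
      d <- chain_residue_dmat(model, chains[i], chains[j])
      hit <- which(d <= cutoff, arr.ind = TRUE)
      if (nrow(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          key_a = rownames(d)[hit[, 1L]],
          key_b = colnames(d)[hit[, 2L]],
          dist = d[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(key_a = character(0), key_b = character(0),
                      dist = numeric(0)))
  do.call(rbind, out)
}

#' Fraction of native contacts (fnat)
#'
#' The fraction of the reference model's inter-chain residue contacts
#' (minimum heavy-atom distance at or below `contact_cutoff`) that are
#' also present in `model`. Native contacts involving residues absent
#' from `model` are dropped pairwise before the fraction is formed.
#'
#' @param model,reference [complex_model()]s with shared residue keys.
#' @param contact_cutoff contact distance in Angstrom (default 5.0).
#' @return Fraction in \[0, 1\].
#' @export
fnat <- function(model, reference, contact_cutoff = DOCKQ_FNAT_CUTOFF) {
  ref_ct <- model_contacts(reference, contact_cutoff)
  if (nrow(ref_ct) == 0L)
    stop_compute("no native interface: reference '%s' has no inter-chain contacts at %.1f A",
                 reference$model_id, contact_cutoff)
  shared <- residue_keys(model)
  ref_ct <- ref_ct[ref_ct$key_a %in% shared & ref_ct$key_b %in% shared, ,
                   drop = FALSE]
  if (nrow(ref_ct) == 0L)
    stop_compute("no native contacts remain after dropping residues absent from '%s'",
                 model$model_id)
  mod_ct <- model_contacts(model, contact_cutoff)
  ref_id <- paste(ref_ct$key_a, ref_ct$key_b, sep = "--")
  mod_id <- paste(mod_ct$key_a, mod_ct$key_b, sep = "--")
  mean(ref_id %in% mod_id)
}

# Matched backbone coordinates for a set of residue keys: atoms N, CA, C, O
# present in BOTH models, paired by (residue key, atom name).
matched_backbone <- function(model, reference, keys) {
  pick <- function(m) {
    at <- m$atoms
    at <- at[at$key %in% keys & at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    at
  }
  a <- pick(model)
  b <- pick(reference)
  ida <- paste(a$key, a$elety, sep = "\r")
  idb <- paste(b$key, b$elety, sep = "\r")
  common <- intersect(ida, idb)
  list(mov = as.matrix(a[match(common, ida), c("x", "y", "z")]),
       ref = as.matrix(b[match(common, idb), c("x", "y", "z")]))
}

# Receptor = larger chain by residue count in the reference; ties broken
# by chain id sort order.
assign_roles <- function(reference) {
  chains <- sort(chain_ids(reference))
  if (length(chains) != 2L)
    stop_input("DockQ is defined here for two-chain models (got %d chains)",
               length(chains))
  n_res <- vapply(chains, function(ch)
    length(unique(reference$atoms$key[reference$atoms$chain == ch])),
    integer(1))
  ord <- order(-n_res, chains)
  list(receptor = chains[ord[1L]], ligand = chains[ord[2L]])
}

#' DockQ similarity of a model against a reference model
#'
#' The composite docking-quality score
#' \deqn{DockQ = (fnat + 1/(1+(iRMS/1.5)^2) + 1/(1+(LRMS/8.5)^2)) / 3}
#' where iRMS is the backbone RMSD over the reference's interface residues
#' (defined at a 10 A heavy-atom cutoff) after superposing on those
#' residues, and LRMS is the ligand backbone RMSD after superposing the
#' receptor chains. Backbone = N, CA, C, O. Residues missing from either
#' model are dropped pairwise.
#'
#' @param model a [complex_model()] to score.
#' @param reference the [complex_model()] acting as reference.
#' @param allow_empty_reference if `TRUE` (the jury-scoring mode used by
#'   [pairwise_matrix()]), a reference with no inter-chain contacts does
#'   not raise an error: the fnat term is 0 and, when the reference has
#'   no 10 A interface either, the iRMS term is 0 (`irms = Inf`). The
#'   default `FALSE` keeps the strict behaviour expected when the
#'   reference is a trusted native-like structure.
#' @return List of class `pairwise_similarity`: `model_a` (scored model),
#'   `model_b` (reference), `dockq`, `fnat`, `irms`, `lrms` (`qs` is NA
#'   here; see [pairwise_similarity()]).
#' @export
dockq <- function(model, reference, allow_empty_reference = FALSE) {
  roles <- assign_roles(reference)
  fn <- if (allow_empty_reference) {
    tryCatch(fnat(model, reference),
             dockjury_compute_error = function(e) 0)
  } else {
    fnat(model, reference)
  }
  # interface residues of the reference at the 10 A heavy-atom cutoff
  iface_ct <- model_contacts(reference, DOCKQ_IFACE_CUTOFF)
  iface_keys <- unique(c(iface_ct$key_a, iface_ct$key_b))
  bb_i <- matched_backbone(model, reference, iface_keys)
  if (nrow(bb_i$ref) < 3L && !allow_empty_reference)
    stop_compute("fewer than 3 shared interface backbone atoms between '%s' and '%s'",
                 model$model_id, reference$model_id)
  irms <- if (nrow(bb_i$ref) < 3L) Inf else
    kabsch_superpose(bb_i$ref, bb_i$mov)$rmsd
  # ligand RMSD after superposing on the receptor chain
  rec_keys <- unique(reference$atoms$key[reference$atoms$chain == roles$receptor])
  lig_keys <- unique(reference$atoms$key[reference$atoms$chain == roles$ligand])
  bb_r <- matched_backbone(model, reference, rec_keys)
  bb_l <- matched_backbone(model, reference, lig_keys)
  if (nrow(bb_r$ref) < 3L || nrow(bb_l$ref) < 1L)
    stop_compute("too few shared backbone atoms for ligand RMSD between '%s' and '%s'",
                 model$model_id, reference$model_id)
  sup <- kabsch_superpose(bb_r$ref, bb_r$mov)
  lrms <- rmsd_plain(apply_superposition(sup, bb_l$mov), bb_l$ref)
  dq <- (fn + 1 / (1 + (irms / DOCKQ_D2)^2) + 1 / (1 + (lrms / DOCKQ_D1)^2)) / 3
  structure(list(model_a = model$model_id, model_b = reference$model_id,
                 qs = NA_real_, dockq = dq, fnat = fn,
                 irms = irms, lrms = lrms),
            class = "pairwise_similarity")
}

#' @export
print.pairwise_similarity <- function(x, ...) {
  cat(sprintf("<pairwise_similarity> %s vs %s\n", x$model_a, x$model_b))
  cat(sprintf("  qs    %s\n", ifelse(is.na(x$qs), "-", sprintf("%.4f", x$qs))))
  cat(sprintf("  dockq %.4f  (fnat %.4f, irms %.3f A, lrms %.3f A)\n",
              x$dockq, x$fnat, x$irms, x$lrms))
  invisible(x)
}

# Per-residue contact coordinates for QS-score: C-beta, or C-alpha for
# glycine. Residues providing neither are skipped with a warning.
qs_contact_coords <- function(model) {
  at <- model$atoms
  keys <- residue_keys(model)
  cb <- at[at$elety == "CB", , drop = FALSE]
  ca <- at[at$elety == "CA", , drop = FALSE]
  rows <- lapply(keys, function(k) {
    i <- which(cb$key == k)
    if (length(i)) return(cb[i[1L], , drop = FALSE])
    j <- which(ca$key == k & ca$resid == "GLY")
    if (length(j)) return(ca[j[1L], , drop = FALSE])
    NULL
  })
  skipped <- keys[vapply(rows, is.null, logical(1))]
  if (length(skipped))
    warning(sprintf("qs_score: %d residue(s) without CB (or GLY CA) skipped in '%s'",
                    length(skipped), model$model_id), call. = FALSE)
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Weighted inter-chain contact list on QS coordinates: named weight vector,
# names "key_a--key_b" with the chain pair in sort order.
qs_weighted_contacts <- function(model) {
  at <- qs_contact_coords(model)
  chains <- sort(unique(at$chain))
  w <- numeric(0)
  for (i in seq_len(length(chains) - 1L)) {
    for (j in seq((i + 1L), length(chains))) {
      a <- at[at$chain == chains[i], , drop = FALSE]
      b <- at[at$chain == chains[j], , drop = FALSE]
      d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                      as.matrix(b[, c("x", "y", "z")]))
      hit <- which(d <= QS_CONTACT_CUTOFF, arr.ind = TRUE)
      if (nrow(hit)) {
        dd <- d[hit]
        wt <- ifelse(dd <= QS_FULL_WEIGHT, 1,
                     exp(-(dd - QS_FULL_WEIGHT)^2 / (2 * QS_SIGMA^2)))
        names(wt) <- paste(a$key[hit[, 1L]], b$key[hit[, 2L]], sep = "--")
        w <- c(w, wt)
      }
    }
  }
  w
}

#' QS-score between two models
#'
#' Symmetric contact-overlap score on C-beta contacts (C-alpha for
#' glycine) at a 12 A horizon: each inter-chain residue contact carries
#' weight 1 up to 5 A and a Gaussian decay beyond. The score is the sum of
#' the smaller weight over contacts shared by both models divided by the
#' sum of the larger weight over the union of contacts. Identical models
#' score 1; models with disjoint contact sets score 0. Two models that
#' both have no contacts at all are vacuously identical and score 1.
#'
#' @param model_a,model_b [complex_model()]s with shared chain set.
#' @return Value in \[0, 1\].
#' @export
qs_score <- function(model_a, model_b) {
  wa <- qs_weighted_contacts(model_a)
  wb <- qs_weighted_contacts(model_b)
  keys <- union(names(wa), names(wb))
  if (!length(keys)) return(1)
  va <- setNames(rep(0, length(keys)), keys)
  vb <- va
  va[names(wa)] <- wa
  vb[names(wb)] <- wb
  sum(pmin(va, vb)) / sum(pmax(va, vb))
}

#' Full pairwise similarity of two models
#'
#' Convenience wrapper computing both the QS-score and DockQ (with its
#' fnat / iRMS / LRMS components, `model_b` acting as reference).
#'
#' @param model_a,model_b [complex_model()]s.
#' @return A `pairwise_similarity` (see [dockq()]) with `qs` filled in.
#' @export
pairwise_similarity <- function(model_a, model_b) {
  out <- dockq(model_a, model_b)
  out$qs <- qs_score(model_a, model_b)
  out
}
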