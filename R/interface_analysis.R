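#' @title Interface detection and minimum inter-chain distances
#' @description Stage 1 of the ModFOLDIA method: for every residue the
#'   minimum heavy-atom distance to any residue in a *different* chain
#'   (Dmin), and the interface set at an inclusive cutoff (default 5 A).
#' @name interface_analysis
NULL

#' Minimum heavy-atom distance between two residues
#'
#' The minimum Euclidean distance over all heavy-atom pairs; symmetric in
#' its arguments. Used as the contact kernel throughout the package.
#'
#' @param res_a,res_b data.frames of atoms (columns `x`, `y`, `z`), e.g.
#'   subsets of a model's `atoms` table.
#' @return Distance in Angstrom.
#' @export
residue_min_distance <- function(res_a, res_b) {
  if (nrow(res_a) == 0L || nrow(res_b) == 0L)
    stop_input("residue with zero heavy atoms")
  min(cross_dist(as.matrix(res_a[, c("x", "y", "z")]),
                 as.matrix(res_b[, c("x", "y", "z")])))
}

# All-pairs Euclidean distances between two coordinate sets, computed as
# sqrt((dx)^2 + (dy)^2 + (dz)^2) term by term -- the same arithmetic as a
# scalar loop over pairs, so the vectorised path is bit-identical to a
# brute-force oracle (no expanded-square shortcut, which differs in
# floating point).
cross_dist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 +
       outer(a[, 2], b[, 2], "-")^2 +
       outer(a[, 3], b[, 3], "-")^2)
}

# Row-group minimum: collapse rows of `m` to one row per group by pmin.
group_min_rows <- function(m, groups, levels_) {
  idx <- split(seq_len(nrow(m)), factor(groups, levels = levels_))
  rows <- lapply(idx, function(i) {
    if (length(i) == 1L) m[i, ] else
      do.call(pmin, lapply(i, function(r) m[r, ]))
  })
  matrix(unlist(rows, use.names = FALSE), nrow = length(idx), byrow = TRUE,
         dimnames = list(levels_, colnames(m)))
}

# Residue-level min-distance matrix between two chains of a model:
# rows/cols named by residue key. The workhorse behind interface profiles,
# fnat contacts and DockQ interface definitions.
chain_residue_dmat <- function(model, chain_a, chain_b) {
  at <- model$atoms
  a <- at[at$chain == chain_a, , drop = FALSE]
  b <- at[at$chain == chain_b, , drop = FALSE]
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  ka <- unique(a$key)
  kb <- unique(b$key)
  rmin <- group_min_rows(d, a$key, ka)
  rmin <- t(group_min_rows(t(rmin), b$key, kb))
  rmin
}

#' Interface profile of a model
#'
#' For every residue, the minimum heavy-atom distance to any residue of a
#' different chain (Dmin, uncapped), and the interface set: residues with
#' Dmin at or below the cutoff (inclusive, per the <= 5 A heavy-atom
#' interface definition). With more than two chains the minimum over all
#' foreign chains is used. Intra-chain pairs never contribute.
#'
#' @param model a [complex_model()] with >= 2 chains.
#' @param cutoff interface cutoff in Angstrom (default 5.0).
#' @return An object of class `interface_profile`: list with `model_id`,
#'   `dmin` (named numeric, every residue key), `interface_set` (character)
#'   and `cutoff`.
#' @export
interface_profile <- function(model, cutoff = 5.0) {
  chains <- chain_ids(model)
  if (length(chains) < 2L)
    stop_input("interface_profile() needs >= 2 chains")
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop_input("cutoff must be positive")
  at <- model$atoms
  keys <- residue_keys(model)
  dmin <- setNames(rep(Inf, length(keys)), keys)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  for (ch in chains) {
    own <- at$chain == ch
    if (!any(!own)) next
    d <- cross_dist(xyz[own, , drop = FALSE], xyz[!own, , drop = FALSE])
    per_atom <- apply(d, 1L, min)
    per_res <- vapply(split(per_atom, factor(at$key[own],
                                             levels = unique(at$key[own]))),
                      min, numeric(1))
    dmin[names(per_res)] <- per_res
  }
  structure(list(model_id = model$model_id, dmin = dmin,
                 interface_set = names(dmin)[dmin <= cutoff],
                 cutoff = cutoff),
            class = "interface_profile")
}

#' @export
print.interface_profile <- function(x, ...) {
  cat(sprintf("<interface_profile> %s: %d/%d residues within %.1f A of another chain\n",
              x$model_id, length(x$interface_set), length(x$dmin), x$cutoff))
  invisible(x)
}

#' Interface profiles for every model in a pool
#'
#' Dmin is recorded for *every* residue of every model (not only interface
#' residues) so that cross-model means (MeanDmin) can be formed for
#' residues that are interface in one model but not in another.
#'
#' @param pool a [build_pool()] result.
#' @param cutoff interface cutoff in Angstrom.
#' @return Named list of [interface_profile()]s, one per model.
#' @export
pool_dmin_table <- function(pool, cutoff = 5.0) {
  lapply(pool$models, interface_profile, cutoff = cutoff)
}

#' Export an interface profile (or several) as a data.frame
#'
#' @param profiles a single `interface_profile` or a list of them.
#' @return data.frame with columns model_id, chain, seq_num, icode, dmin,
#'   is_interface.
#' @export
interface_table <- function(profiles) {
  if (inherits(profiles, "interface_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    parts <- strsplit(names(p$dmin), "|", fixed = TRUE)
    data.frame(model_id = p$model_id,
               chain = vapply(parts, `[`, character(1), 1L),
               seq_num = as.integer(vapply(parts, `[`, character(1), 2L)),
               icode = vapply(parts, function(x)
                 if (length(x) >= 3L) x[3L] else "", character(1)),
               dmin = unname(p$dmin),
               is_interface = names(p$dmin) %in% p$interface_set,
               stringsAsFactors = FALSE)
  }))
}
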