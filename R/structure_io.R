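#' @title Multi-chain structural models and model pools
#' @description Readers, writers and validators for the package's core
#'   containers: a `complex_model` (one multi-chain model, heavy atoms only)
#'   and a `model_pool` (>= 2 models of one target with an equivalent-residue
#'   correspondence keyed by author numbering).
#' @name structure_io
NULL

# Residue key: chain | author seq number | insertion code ("" when blank).
# All cross-model residue equivalence in the package goes through this key;
# the pool is assumed to derive from a single target sequence, so author
# numbering is trusted and no alignment fallback is attempted.
residue_key <- function(chain, resno, insert) {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = "|")
}

#' Construct a complex model from an atom table
#'
#' Low-level constructor used by [read_pdb()] and the decoy generator.
#' Atoms must already be heavy atoms (no H/D); one row per atom.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z`
#'   (coordinates, Angstrom) and optionally `o` (occupancy, default 1).
#' @param model_id character scalar identifying the model.
#' @param source provenance string (file path or `"synthetic"`).
#' @return An object of class `complex_model`: a list with elements
#'   `model_id`, `atoms` (the validated table, plus a `key` column) and
#'   `source`.
#' @export
complex_model <- function(atoms, model_id, source = "constructed") {
  req <- c("chain", "resno", "insert", "resid", "elety", "elesy",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop_input("atom table lacks columns: %s",
               paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop_input("model '%s' has no atoms", model_id)
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop_input("model '%s' contains non-finite coordinates", model_id)
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  chains <- unique(atoms$chain)
  if (length(chains) < 2L)
    stop_input("model '%s' is not a complex: %d chain(s) after filtering",
               model_id, length(chains))
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, atoms = atoms, source = source),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model> %s: %d chains (%s), %d residues, %d heavy atoms\n",
              x$model_id, length(chain_ids(x)),
              paste(chain_ids(x), collapse = ","),
              length(residue_keys(x)), nrow(x$atoms)))
  invisible(x)
}

#' Chain identifiers of a model
#' @param model a `complex_model`.
#' @return Character vector of chain ids in order of first appearance.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Residue keys of a model
#' @param model a `complex_model`.
#' @return Character vector `chain|resno|icode`, file order.
#' @export
residue_keys <- function(model) unique(model$atoms$key)

# Element inference when columns 77-78 are blank: strip digits/apostrophes
# from the atom name, take the leading letter; names like "1HG2" are
# hydrogens, "CA" is carbon (calcium never appears in ATOM records of
# protein chains).
infer_element <- function(elety) {
  nm <- gsub("[0-9']", "", trimws(elety))
  substr(nm, 1L, 1L)
}

#' Read a multi-chain model from a PDB file
#'
#' Parses ATOM records of the first MODEL block (via bio3d), then filters to
#' heavy atoms: hydrogens/deuterium are dropped by element (inferred from
#' the atom name when the element column is blank), HETATM records and
#' waters are excluded, and for alternate-location duplicates only the
#' highest-occupancy conformer is kept (ties: first encountered).
#' Gzip-compressed files are accepted by `.gz` extension.
#'
#' @param path path to a PDB (or PDB.gz) file.
#' @param model_id identifier for the model; defaults to the file name
#'   without extension.
#' @return A [complex_model()].
#' @export
read_pdb <- function(path, model_id = NULL) {
  if (!file.exists(path))
    stop_input("file not found: %s", path)
  if (is.null(model_id))
    model_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path),
                    ignore.case = TRUE)
  src <- path
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(readLines(gzfile(path)), tmp)
    path <- tmp
  }
  validate_pdb_lines(path)
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "DOD", "WAT")), ,
           drop = FALSE]
  if (nrow(at) == 0L)
    stop_input("no ATOM records in %s", src)
  elesy <- trimws(ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                         infer_element(at$elety), at$elesy))
  at <- at[!(toupper(elesy) %in% c("H", "D")), , drop = FALSE]
  elesy <- elesy[!(toupper(elesy) %in% c("H", "D"))]
  if (nrow(at) == 0L)
    stop_input("no heavy atoms in %s", src)
  at$elesy <- elesy
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # altloc resolution: within (residue, atom name) keep highest occupancy;
  # order() is stable so ties fall to the first conformer encountered
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- !duplicated(akey[order(-occ)])[order(order(-occ))]
  at <- at[keep, , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                       unique(paste(at$chain, at$resno, at$insert,
                                    sep = "\r")))), , drop = FALSE]
  complex_model(
    data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
               resid = at$resid, elety = at$elety, elesy = at$elesy,
               x = at$x, y = at$y, z = at$z,
               o = ifelse(is.na(at$o), 1, at$o),
               stringsAsFactors = FALSE),
    model_id = model_id, source = src)
}

# Cheap structural validation so a malformed record is reported with its
# line number instead of surfacing as a cryptic parser failure.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  # only the first MODEL block is validated (only it is read)
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) is_atom[seq_along(lines) > endmdl[1]] <- FALSE
  idx <- which(is_atom)
  if (!length(idx)) return(invisible(TRUE))
  bad_len <- idx[nchar(lines[idx]) < 54]
  if (length(bad_len))
    stop_input("unparsable ATOM record at line %d of %s (record too short)",
               bad_len[1], path)
  coords <- suppressWarnings(cbind(
    as.numeric(substr(lines[idx], 31, 38)),
    as.numeric(substr(lines[idx], 39, 46)),
    as.numeric(substr(lines[idx], 47, 54))))
  bad <- idx[!stats::complete.cases(coords)]
  if (length(bad))
    stop_input("unparsable ATOM record at line %d of %s (bad coordinates)",
               bad[1], path)
  invisible(TRUE)
}

#' Write a model to a PDB file
#'
#' Fixed-width wwPDB v3.3 ATOM records via bio3d. Coordinates are written
#' to 3 decimals, so a read/write round trip preserves them to 0.001 A.
#' Residue numbers above 9999 do not fit the fixed-width field and raise
#' an error (no hybrid-36 fallback).
#'
#' @param model a [complex_model()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  if (!inherits(model, "complex_model"))
    stop_input("write_pdb() needs a complex_model")
  at <- model$atoms
  if (nrow(at) == 0L || length(chain_ids(model)) == 0L)
    stop_input("model '%s' has no chains to write", model$model_id)
  if (any(at$resno > 9999L))
    stop_input("residue number exceeds 9999; PDB fixed-width cannot represent it")
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(at)),
      resno = at$resno, resid = at$resid, chain = at$chain,
      insert = ifelse(at$insert == "", NA, at$insert),
      elety = at$elety, eleno = seq_len(nrow(at)),
      o = at$o, b = rep(0, nrow(at)), elesy = at$elesy)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_input("cannot write PDB to %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Assemble a pool of models of one target
#'
#' Builds the equivalent-residue correspondence across models: each residue
#' key (chain, author number, insertion code) is mapped to the models that
#' contain it. All models must share the same chain set. Keys absent from
#' some model are recorded as warnings in the returned object; downstream
#' scoring skips them when averaging across models.
#'
#' @param models list of [complex_model()]s (length >= 2, unique ids).
#' @param target_id identifier for the target complex.
#' @return An object of class `model_pool`: list with `target_id`, `models`
#'   (named by model id), `correspondence` (logical matrix, residue keys x
#'   models) and `warnings` (character).
#' @export
build_pool <- function(models, target_id = "target") {
  if (!is.list(models) || length(models) < 2L)
    stop_input("a pool requires >= 2 models (got %d)", length(models))
  ok <- vapply(models, inherits, logical(1), what = "complex_model")
  if (!all(ok))
    stop_input("all pool members must be complex_model objects")
  ids <- vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(ids))
    stop_input("duplicate model ids in pool: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chain_sets <- lapply(models, function(m) sort(chain_ids(m)))
  ref_chains <- chain_sets[[1]]
  for (i in seq_along(models)) {
    if (!identical(chain_sets[[i]], ref_chains)) {
      stop_input(
        "chain set mismatch: model '%s' has {%s}, model '%s' has {%s}",
        ids[1], paste(ref_chains, collapse = ","),
        ids[i], paste(chain_sets[[i]], collapse = ","))
    }
  }
  key_lists <- lapply(models, residue_keys)
  all_keys <- unique(unlist(key_lists))
  corr <- vapply(key_lists, function(k) all_keys %in% k,
                 logical(length(all_keys)))
  dimnames(corr) <- list(all_keys, ids)
  warn <- character(0)
  incomplete <- which(rowSums(corr) < length(models))
  if (length(incomplete)) {
    warn <- vapply(incomplete, function(i) {
      sprintf("residue %s absent from model(s): %s", all_keys[i],
              paste(ids[!corr[i, ]], collapse = ", "))
    }, character(1))
  }
  names(models) <- ids
  structure(list(target_id = target_id, models = models,
                 correspondence = corr, warnings = unname(warn)),
            class = "model_pool")
}

#' @export
print.model_pool <- function(x, ...) {
  cat(sprintf("<model_pool> target %s: %d models, %d residue keys (%d shared by all)\n",
              x$target_id, length(x$models), nrow(x$correspondence),
              sum(rowSums(x$correspondence) == length(x$models))))
  if (length(x$warnings))
    cat(sprintf("  %d residue key(s) missing from some model\n",
                length(x$warnings)))
  invisible(x)
}

#' Model identifiers of a pool
#' @param pool a `model_pool`.
#' @return Character vector of model ids.
#' @export
pool_ids <- function(pool) names(pool$models)
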