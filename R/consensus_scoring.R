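#' @title Consensus (jury) scoring of a model pool
#' @description The full reference-free protocol: ModFOLDIA per-residue and
#'   global interface-accuracy scores, QSscoreJury and DockQJury pairwise
#'   consensus scores, external-score ingestion, and the aggregated global
#'   score used to rank the pool.
#' @name consensus_scoring
NULL

SI_HALF_DISTANCE <- 20  # A: Dmin at which the sigmoid contact score is 0.5

#' Sigmoid contact score of a minimum distance
#'
#' `Si = 1 / (1 + (Dmin/20)^2)`: 1 at contact distance zero, 0.5 at 20 A.
#'
#' @param dmin minimum inter-chain heavy-atom distance(s), Angstrom, >= 0.
#' @return Value(s) in (0, 1].
#' @export
si_score <- function(dmin) {
  if (any(!is.finite(dmin)) || any(dmin < 0))
    stop_input("si_score() needs finite non-negative distances")
  1 / (1 + (dmin / SI_HALF_DISTANCE)^2)
}

#' Per-residue interface accuracy score
#'
#' `IA = 1 - |Si - MeanSi|`: 1 when a residue's contact score agrees
#' exactly with the pool mean, decreasing linearly with the discrepancy.
#'
#' @param si,mean_si contact scores in (0, 1] (see [si_score()]).
#' @return Value(s) in \[0, 1\].
#' @export
ia_score <- function(si, mean_si) {
  if (any(si <= 0 | si > 1) || any(mean_si <= 0 | mean_si > 1))
    stop_input("ia_score() inputs must lie in (0, 1]")
  1 - abs(si - mean_si)
}

#' Per-residue ModFOLDIA scores for one model of a pool
#'
#' For each interface residue of the scored model (minimum inter-chain
#' heavy-atom distance Dmin at or below `cutoff`), the equivalent residue
#' is located in every *other* model of the pool and MeanDmin is the
#' arithmetic mean of its Dmin there (uncapped distances included, whether
#' or not the residue is interface in the other model). Then
#' Si = si(Dmin), MeanSi = si(MeanDmin), IA = 1 - |Si - MeanSi|.
#' Residues absent from every other model cannot be averaged: their IA is
#' recorded as NA with `missing = TRUE` (they contribute 0 to the global
#' numerator).
#'
#' @param pool a [build_pool()] result (>= 2 models).
#' @param model_id id of the model to score.
#' @param cutoff interface cutoff, Angstrom (default 5.0).
#' @param profiles optional precomputed [pool_dmin_table()] result (reused
#'   by [score_pool()] to avoid recomputation).
#' @return data.frame with one row per interface residue: `key`, `chain`,
#'   `seq_num`, `icode`, `dmin`, `si`, `n_other` (models contributing to
#'   the mean), `mean_dmin`, `mean_si`, `ia`, `missing`.
#' @export
modfoldia_local <- function(pool, model_id, cutoff = 5.0, profiles = NULL) {
  check_pool_model(pool, model_id)
  if (is.null(profiles)) profiles <- pool_dmin_table(pool, cutoff)
  prof <- profiles[[model_id]]
  others <- profiles[setdiff(pool_ids(pool), model_id)]
  keys <- prof$interface_set
  if (!length(keys)) {
    return(data.frame(key = character(0), chain = character(0),
                      seq_num = integer(0), icode = character(0),
                      dmin = numeric(0), si = numeric(0),
                      n_other = integer(0), mean_dmin = numeric(0),
                      mean_si = numeric(0), ia = numeric(0),
                      missing = logical(0)))
  }
  other_d <- vapply(others, function(p) unname(p$dmin[keys]),
                    numeric(length(keys)))
  other_d <- matrix(other_d, nrow = length(keys))
  n_other <- rowSums(!is.na(other_d))
  mean_dmin <- ifelse(n_other > 0L, rowMeans(other_d, na.rm = TRUE), NA_real_)
  dmin <- unname(prof$dmin[keys])
  si <- si_score(dmin)
  mean_si <- ifelse(is.na(mean_dmin), NA_real_,
                    1 / (1 + (mean_dmin / SI_HALF_DISTANCE)^2))
  ia <- 1 - abs(si - mean_si)
  miss <- n_other == 0L
  if (any(miss))
    warning(sprintf("modfoldia_local('%s'): %d interface residue(s) absent from every other model",
                    model_id, sum(miss)), call. = FALSE)
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(key = keys,
             chain = vapply(parts, `[`, character(1), 1L),
             seq_num = as.integer(vapply(parts, `[`, character(1), 2L)),
             icode = vapply(parts, function(x)
               if (length(x) >= 3L) x[3L] else "", character(1)),
             dmin = dmin, si = si, n_other = as.integer(n_other),
             mean_dmin = mean_dmin, mean_si = mean_si, ia = ia,
             missing = miss, stringsAsFactors = FALSE)
}

#' Global ModFOLDIA score of one model
#'
#' The sum of the model's per-residue IA scores over its interface,
#' normalised by the larger of (a) the model's own interface size and
#' (b) the mean interface size across all models of the pool. Residues
#' whose IA could not be formed (absent from every other model)
#' contribute 0 to the numerator. An empty interface scores 0.
#'
#' @inheritParams modfoldia_local
#' @return Value in \[0, 1\].
#' @export
modfoldia_global <- function(pool, model_id, cutoff = 5.0, profiles = NULL) {
  check_pool_model(pool, model_id)
  if (is.null(profiles)) profiles <- pool_dmin_table(pool, cutoff)
  local <- modfoldia_local(pool, model_id, cutoff, profiles)
  n_iface <- vapply(profiles, function(p) length(p$interface_set), integer(1))
  denom <- max(n_iface[[model_id]], mean(n_iface))
  if (nrow(local) == 0L || denom == 0) return(0)
  sum(local$ia, na.rm = TRUE) / denom
}

check_pool_model <- function(pool, model_id) {
  if (!inherits(pool, "model_pool"))
    stop_input("expected a model_pool")
  if (length(pool$models) < 2L)
    stop_input("jury requires >= 2 models")
  if (!model_id %in% pool_ids(pool))
    stop_input("model '%s' not in pool", model_id)
  invisible(TRUE)
}

#' Pairwise similarity table for a whole pool
#'
#' QS-score for each unordered model pair (it is symmetric) and DockQ for
#' each ordered pair (the second model of the pair acts as reference; the
#' score is not symmetric in general).
#'
#' @param pool a [build_pool()] result.
#' @return List with matrices `qs` and `dockq` (rows = scored model,
#'   columns = reference model, diagonal NA) and a long-format data.frame
#'   `table` (model_a, model_b, qs, dockq, fnat, irms, lrms).
#' @export
pairwise_matrix <- function(pool) {
  ids <- pool_ids(pool)
  n <- length(ids)
  qs <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  dq <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (j > i) {
        q <- qs_score(pool$models[[i]], pool$models[[j]])
        qs[i, j] <- q
        qs[j, i] <- q
      }
      ps <- dockq(pool$models[[i]], reference = pool$models[[j]],
                  allow_empty_reference = TRUE)
      dq[i, j] <- ps$dockq
      rows[[length(rows) + 1L]] <- data.frame(
        model_a = ids[i], model_b = ids[j], qs = qs[i, j],
        dockq = ps$dockq, fnat = ps$fnat, irms = ps$irms, lrms = ps$lrms,
        stringsAsFactors = FALSE)
    }
  }
  list(qs = qs, dockq = dq, table = do.call(rbind, rows))
}

#' Jury (consensus) score of one model
#'
#' The arithmetic mean of a pairwise similarity metric between the model
#' and every *other* model of the pool (self-comparison excluded). With
#' `metric = "qs"` this is QSscoreJury; with `metric = "dockq"` it is
#' DockQJury (each other model in turn acts as the DockQ reference).
#'
#' @param pool a [build_pool()] result (>= 2 models).
#' @param model_id id of the model to score.
#' @param metric `"qs"` or `"dockq"`.
#' @param pairwise optional precomputed [pairwise_matrix()] result.
#' @return Value in \[0, 1\].
#' @export
jury_score <- function(pool, model_id, metric = c("qs", "dockq"),
                       pairwise = NULL) {
  metric <- match.arg(metric)
  check_pool_model(pool, model_id)
  if (is.null(pairwise)) pairwise <- pairwise_matrix(pool)
  m <- pairwise[[metric]]
  mean(m[model_id, setdiff(colnames(m), model_id)])
}

#' Average per-chain-pair scores into one assembly score
#'
#' External per-chain-pair scores (ProQDock-style) are averaged over the
#' interacting chain pairs to give a single global score for the assembly.
#'
#' @param per_pair named numeric vector (or list) of per-chain-pair values
#'   in \[0, 1\].
#' @return The arithmetic mean.
#' @export
average_chain_pair_scores <- function(per_pair) {
  v <- unlist(per_pair, use.names = FALSE)
  if (!length(v)) stop_input("no chain-pair scores to average")
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    stop_input("chain-pair scores must lie in [0, 1]")
  mean(v)
}

#' Read external per-model scores from TSV
#'
#' Expected columns: `method`, `model_id`, optionally `chain_a` and
#' `chain_b`, and `score` (in \[0, 1\]). When chain columns are present,
#' per-chain-pair rows of a model are averaged via
#' [average_chain_pair_scores()]; otherwise one row per model is expected.
#'
#' @param path TSV file with a header row.
#' @return Named list: one element per method, each a named numeric vector
#'   of per-model global scores.
#' @export
read_external_scores <- function(path) {
  if (!file.exists(path)) stop_input("external score file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("method", "model_id", "score")
  if (!all(need %in% names(df)))
    stop_input("external score file %s must have columns: %s",
               path, paste(need, collapse = ", "))
  if (any(!is.finite(df$score)) || any(df$score < 0 | df$score > 1))
    stop_input("external scores must lie in [0, 1] (%s)", path)
  out <- lapply(split(df, df$method), function(d) {
    vapply(split(d$score, d$model_id), average_chain_pair_scores, numeric(1))
  })
  out
}

#' Aggregate component scores into the ModFOLDdock global score
#'
#' The global score of a model is the unweighted arithmetic mean of its
#' available component scores. The three internal components (QSscoreJury,
#' DockQJury, ModFOLDIA global) are always required; external components
#' (e.g. ProQDock-style or VoroMQA-style slots) extend the mean to five
#' methods when supplied. Models are ranked by global score, descending;
#' ties are broken by model id sort order for determinism.
#'
#' @param components data.frame with columns `model_id`, `qs_jury`,
#'   `dockq_jury`, `modfoldia` and optionally further numeric columns, one
#'   per external method.
#' @return data.frame of class `consensus_scores`: the input columns plus
#'   `n_components`, `global` and `rank`, ordered by rank.
#' @export
aggregate_modfolddock <- function(components) {
  need <- c("model_id", "qs_jury", "dockq_jury", "modfoldia")
  missing_cols <- setdiff(need, names(components))
  if (length(missing_cols))
    stop_input("missing internal component column(s): %s",
               paste(missing_cols, collapse = ", "))
  score_cols <- setdiff(names(components), "model_id")
  for (cc in c("qs_jury", "dockq_jury", "modfoldia")) {
    if (any(is.na(components[[cc]])))
      stop_input("internal component '%s' is missing for some model", cc)
  }
  sc <- as.matrix(components[, score_cols, drop = FALSE])
  n_comp <- rowSums(!is.na(sc))
  global <- rowMeans(sc, na.rm = TRUE)
  if (any(n_comp < length(score_cols)))
    message(sprintf("aggregate: %d-component aggregate used for %d model(s)",
                    min(n_comp), sum(n_comp < length(score_cols))))
  out <- components
  out$n_components <- as.integer(n_comp)
  out$global <- global
  ord <- order(-out$global, out$model_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("consensus_scores", "data.frame")
  out
}

#' Score and rank a model pool
#'
#' The full protocol in one call: interface profiles, per-residue
#' ModFOLDIA scores, QSscoreJury, DockQJury, ModFOLDIA global, optional
#' external components, and the aggregated global score with ranking.
#'
#' @param pool a [build_pool()] result (>= 2 models).
#' @param cutoff interface cutoff, Angstrom (default 5.0).
#' @param external optional result of [read_external_scores()] (or a list
#'   of named per-model numeric vectors, one per external method).
#' @return List of class `pool_scores`: `scores` (the ranked
#'   [aggregate_modfolddock()] table), `residue_ia` (named list of
#'   per-model [modfoldia_local()] data.frames), `pairwise` (the
#'   [pairwise_matrix()] result) and `profiles`.
#' @export
score_pool <- function(pool, cutoff = 5.0, external = NULL) {
  if (!inherits(pool, "model_pool")) stop_input("expected a model_pool")
  if (length(pool$models) < 2L) stop_input("jury requires >= 2 models")
  ids <- pool_ids(pool)
  profiles <- pool_dmin_table(pool, cutoff)
  pw <- pairwise_matrix(pool)
  comp <- data.frame(
    model_id = ids,
    qs_jury = vapply(ids, jury_score, numeric(1), pool = pool,
                     metric = "qs", pairwise = pw),
    dockq_jury = vapply(ids, jury_score, numeric(1), pool = pool,
                        metric = "dockq", pairwise = pw),
    modfoldia = vapply(ids, modfoldia_global, numeric(1), pool = pool,
                       cutoff = cutoff, profiles = profiles),
    stringsAsFactors = FALSE)
  if (!is.null(external)) {
    for (method in names(external)) {
      v <- external[[method]]
      unknown <- setdiff(names(v), ids)
      if (length(unknown))
        stop_input("external method '%s' scores unknown model(s): %s",
                   method, paste(unknown, collapse = ", "))
      comp[[method]] <- unname(v[match(comp$model_id, names(v))])
    }
  }
  residue_ia <- lapply(setNames(ids, ids), function(id)
    modfoldia_local(pool, id, cutoff, profiles))
  structure(list(scores = aggregate_modfolddock(comp),
                 residue_ia = residue_ia,
                 pairwise = pw, profiles = profiles,
                 target_id = pool$target_id, cutoff = cutoff),
            class = "pool_scores")
}

#' @export
print.pool_scores <- function(x, ...) {
  cat(sprintf("<pool_scores> target %s: %d models ranked (cutoff %.1f A)\n",
              x$target_id, nrow(x$scores), x$cutoff))
  print.data.frame(utils::head(as.data.frame(x$scores), 10L), digits = 4)
  if (nrow(x$scores) > 10L) cat(sprintf("  ... %d more\n", nrow(x$scores) - 10L))
  invisible(x)
}
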