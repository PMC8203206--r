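#' @title Standard-format output writers
#' @description Tabular (TSV) and CASP-QA-style text output for pool
#'   scoring results.
#' @name output_formats
NULL

#' Write the per-model consensus score table as TSV
#'
#' @param result a [score_pool()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_scores_tsv <- function(result, path) {
  write.table(as.data.frame(result$scores), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-residue IA scores for all models as TSV
#'
#' One row per (model, interface residue): model_id, chain, seq_num,
#' icode, dmin, si, mean_dmin, mean_si, ia.
#'
#' @inheritParams write_scores_tsv
#' @return Invisibly, `path`.
#' @export
write_residue_tsv <- function(result, path) {
  rows <- lapply(names(result$residue_ia), function(id) {
    d <- result$residue_ia[[id]]
    if (nrow(d) == 0L) return(NULL)
    cbind(model_id = id, d[, c("chain", "seq_num", "icode", "dmin", "si",
                               "mean_dmin", "mean_si", "ia")])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model_id = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pairwise similarity table as TSV
#'
#' @inheritParams write_scores_tsv
#' @return Invisibly, `path`.
#' @export
write_pairwise_tsv <- function(result, path) {
  write.table(result$pairwise$table, path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Residue keys of a pool ordered by chain, author number, insertion code.
ordered_pool_keys <- function(result) {
  keys <- names(result$profiles[[1L]]$dmin)
  for (p in result$profiles) keys <- union(keys, names(p$dmin))
  parts <- strsplit(keys, "|", fixed = TRUE)
  ch <- vapply(parts, `[`, character(1), 1L)
  no <- as.integer(vapply(parts, `[`, character(1), 2L))
  ic <- vapply(parts, function(x) if (length(x) >= 3L) x[3L] else "",
               character(1))
  keys[order(ch, no, ic)]
}

#' Write scores in CASP-QA-style plain text
#'
#' A header block (PFRMAT QA, TARGET, METHOD, QMODE 2) followed by one
#' line per model: the model name, its global score, then one per-residue
#' score per residue of the target in PDB numbering order ("X" for
#' residues without a score, i.e. outside the model's interface or absent
#' from the model), and a closing END line. Models appear in rank order.
#'
#' @inheritParams write_scores_tsv
#' @return Invisibly, `path`.
#' @export
write_caspqa <- function(result, path) {
  keys <- ordered_pool_keys(result)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PFRMAT QA",
               sprintf("TARGET %s", result$target_id),
               "AUTHOR dockjury",
               "METHOD Consensus jury scoring (QSscoreJury, DockQJury, ModFOLDIA)",
               "QMODE 2"), con)
  for (i in seq_len(nrow(result$scores))) {
    id <- result$scores$model_id[i]
    ia <- result$residue_ia[[id]]
    per_res <- setNames(rep("X", length(keys)), keys)
    if (nrow(ia)) {
      scored <- ia[!ia$missing, , drop = FALSE]
      per_res[scored$key] <- sprintf("%.3f", scored$ia)
    }
    writeLines(sprintf("%s %.4f %s", id, result$scores$global[i],
                       paste(per_res, collapse = " ")), con)
  }
  writeLines("END", con)
  invisible(path)
}
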