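# ModFOLDIA scores, jury scores, aggregation and ranking.

test_that("si_score and ia_score follow their closed forms", {
  expect_equal(si_score(0), 1)
  expect_equal(si_score(20), 0.5)
  expect_equal(si_score(5), 1 / (1 + 0.0625))
  d <- seq(0, 60, length.out = 25)
  expect_equal(si_score(d), 1 / (1 + (d / 20)^2))
  expect_error(si_score(-1), "non-negative", class = "dockjury_input_error")
  expect_equal(ia_score(1, 1), 1)
  expect_equal(ia_score(1, 0.5), 0.5)
  expect_equal(ia_score(0.5, si_score(5)), 1 - abs(0.5 - 1 / 1.0625))
  expect_error(ia_score(1.2, 0.5), "0, 1", class = "dockjury_input_error")
})

test_that("the worked 2-model pool gives IA = 0.5 and global = 0.5", {
  pool <- worked_example_pool()
  local <- modfoldia_local(pool, "contact")
  expect_equal(nrow(local), 2L)               # one residue per chain
  expect_equal(local$dmin, c(0, 0))
  expect_equal(local$si, c(1, 1))
  expect_equal(local$mean_dmin, c(20, 20))
  expect_equal(local$mean_si, c(0.5, 0.5))
  expect_equal(local$ia, c(0.5, 0.5))
  # n_interface: scored model 2, other model 0 -> denom max(2, 1) = 2
  expect_equal(modfoldia_global(pool, "contact"), 0.5)
  # the far model has an empty interface -> 0
  expect_equal(modfoldia_global(pool, "apart"), 0)
})

test_that("pools of identical models score exactly 1 everywhere", {
  base <- make_reference_dimer(10, seed = 2)
  for (k in c(2L, 3L, 5L)) {
    pool <- build_pool(lapply(seq_len(k), function(i)
      relabel(base, sprintf("copy_%d", i))))
    res <- score_pool(pool)
    expect_equal(res$scores$qs_jury, rep(1, k))
    expect_equal(res$scores$dockq_jury, rep(1, k))
    expect_equal(res$scores$modfoldia, rep(1, k))
    expect_equal(res$scores$global, rep(1, k))
    for (ia_tab in res$residue_ia) expect_equal(ia_tab$ia, rep(1, nrow(ia_tab)))
  }
})

test_that("jury scores equal a brute-force pairwise table", {
  dp <- generate_pool(decoy_spec(n_decoys = 6, seed = 21, n_res_per_chain = 12))
  pool <- dp$pool
  ids <- pool_ids(pool)
  pw <- pairwise_matrix(pool)
  for (id in ids) {
    qs_vals <- vapply(setdiff(ids, id), function(o)
      qs_score(pool$models[[id]], pool$models[[o]]), numeric(1))
    dq_vals <- vapply(setdiff(ids, id), function(o)
      dockq(pool$models[[id]], pool$models[[o]],
            allow_empty_reference = TRUE)$dockq, numeric(1))
    expect_equal(jury_score(pool, id, "qs", pw), mean(qs_vals))
    expect_equal(jury_score(pool, id, "dockq", pw), mean(dq_vals))
  }
  expect_error(jury_score(build_pool(list(pool$models[[1]],
                                          pool$models[[2]]))[["x"]],
                          ids[1]), class = "dockjury_input_error")
})

test_that("scores are bounded and invariant to model order", {
  dp <- generate_pool(decoy_spec(n_decoys = 5, seed = 31, n_res_per_chain = 10))
  res <- score_pool(dp$pool)
  sc <- res$scores
  for (col in c("qs_jury", "dockq_jury", "modfoldia", "global")) {
    expect_true(all(sc[[col]] >= 0 & sc[[col]] <= 1))
  }
  for (ia_tab in res$residue_ia)
    expect_true(all(ia_tab$ia >= 0 & ia_tab$ia <= 1, na.rm = TRUE))
  shuffled <- build_pool(rev(dp$pool$models), target_id = "rev")
  res2 <- score_pool(shuffled)
  m <- match(sc$model_id, res2$scores$model_id)
  expect_equal(res2$scores$global[m], sc$global)
  expect_equal(res2$scores$rank[m], sc$rank)
})

test_that("residues absent from every other model are flagged and add 0", {
  # scored model has two interface residues; A|2| is absent from the other
  m1 <- toy_model(data.frame(chain = c("A", "A", "B"), resno = c(1L, 2L, 1L),
                             elety = "CA", x = c(0, 0, 3), y = c(0, 1, 0),
                             z = 0), "full")
  m2 <- two_point_model(c(0, 0, 0), c(3, 0, 0), "lean")
  pool <- build_pool(list(m1, m2))
  expect_warning(local <- modfoldia_local(pool, "full"), "absent from every")
  row <- local[local$key == "A|2|", ]
  expect_true(row$missing)
  expect_true(is.na(row$ia))
  # global: A|2| contributes 0 to the numerator, still counts in n_interface
  shared <- local[local$key != "A|2|", ]
  denom <- max(3, mean(c(3, 2)))
  expect_warning(
    expect_equal(modfoldia_global(pool, "full"), sum(shared$ia) / denom))
})

test_that("chain-pair averaging and external score ingestion work", {
  expect_equal(average_chain_pair_scores(c(AB = 0.7)), 0.7)
  expect_equal(average_chain_pair_scores(c(0.6, 0.8, 1.0)), 0.8)
  expect_error(average_chain_pair_scores(numeric(0)), "no chain-pair",
               class = "dockjury_input_error")
  expect_error(average_chain_pair_scores(c(0.5, 1.2)), "\\[0, 1\\]",
               class = "dockjury_input_error")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("method\tmodel_id\tchain_a\tchain_b\tscore",
               "proqdock\tm1\tA\tB\t0.6",
               "proqdock\tm1\tA\tC\t0.8",
               "proqdock\tm2\tA\tB\t0.4",
               "voromqa\tm1\t\t\t0.9",
               "voromqa\tm2\t\t\t0.3"), tsv)
  ext <- read_external_scores(tsv)
  expect_setequal(names(ext), c("proqdock", "voromqa"))
  expect_equal(ext$proqdock[["m1"]], 0.7)    # mean of the two chain pairs
  expect_equal(ext$proqdock[["m2"]], 0.4)
  expect_equal(ext$voromqa[["m1"]], 0.9)
})

test_that("aggregation averages available components and ranks deterministically", {
  comp <- data.frame(model_id = c("m1", "m2"),
                     qs_jury = c(0.2, 0.3), dockq_jury = c(0.4, 0.5),
                     modfoldia = c(0.6, 0.7),
                     ext1 = c(0.8, NA), ext2 = c(1.0, NA))
  expect_message(agg <- aggregate_modfolddock(comp), "3-component")
  expect_equal(agg$global[agg$model_id == "m1"], mean(c(0.2, 0.4, 0.6, 0.8, 1.0)))
  expect_equal(agg$global[agg$model_id == "m2"], mean(c(0.3, 0.5, 0.7)))
  expect_equal(agg$n_components, c(5L, 3L)[order(-agg$global)][rank(agg$rank)])
  # ties broken by model id sort order
  tie <- data.frame(model_id = c("b", "a"), qs_jury = 0.5,
                    dockq_jury = 0.5, modfoldia = 0.5)
  agg2 <- aggregate_modfolddock(tie)
  expect_equal(agg2$model_id, c("a", "b"))
  expect_equal(agg2$rank, c(1L, 2L))
  expect_error(aggregate_modfolddock(tie[, -2]), "qs_jury",
               class = "dockjury_input_error")
})

test_that("score_pool blends external components into a five-method mean", {
  dp <- generate_pool(decoy_spec(n_decoys = 4, seed = 41, n_res_per_chain = 10))
  ids <- pool_ids(dp$pool)
  ext <- list(proqdock = setNames(rep(0.5, 4), ids),
              voromqa = setNames(rep(0.9, 4), ids))
  res <- score_pool(dp$pool, external = ext)
  expect_equal(res$scores$n_components, rep(5L, 4))
  sc <- res$scores
  expect_equal(sc$global,
               (sc$qs_jury + sc$dockq_jury + sc$modfoldia + 0.5 + 0.9) / 5)
  bad <- list(proqdock = c(nope = 0.5))
  expect_error(score_pool(dp$pool, external = bad), "unknown model",
               class = "dockjury_input_error")
})

test_that("CASP-QA output has the documented layout", {
  base <- make_reference_dimer(8, seed = 3)
  pool <- build_pool(list(relabel(base, "m_b"), relabel(base, "m_a")))
  res <- score_pool(pool)
  out <- tempfile(fileext = ".caspqa")
  write_caspqa(res, out)
  lines <- readLines(out)
  expect_equal(lines[1], "PFRMAT QA")
  expect_match(lines[2], "^TARGET ")
  expect_true("QMODE 2" %in% lines)
  expect_equal(lines[length(lines)], "END")
  body <- lines[6:(length(lines) - 1)]
  expect_length(body, 2L)
  # rank order, ties by id: m_a first; per-residue field per residue key
  fields <- strsplit(body[1], " +")[[1]]
  expect_equal(fields[1], "m_a")
  expect_equal(as.numeric(fields[2]), 1)
  expect_length(fields, 2L + 16L)             # 16 residues in the dimer
  vals <- suppressWarnings(as.numeric(fields[-(1:2)]))
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
})
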