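test_that("expression matrix TSV round-trips bit-exactly and orders columns by the sheet", {
  es <- make_expr(n = 50, m = 10, seed = 42)
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(es, mp, sp)
  back <- read_expression_matrix(mp, sp)
  expect_identical(back$values, es$values)
  expect_identical(back$samples$sample_id, es$samples$sample_id)

  # shuffled matrix columns are reordered to sample-sheet order
  shuffled <- es$values[, rev(seq_len(ncol(es$values)))]
  df <- tibble::as_tibble(shuffled, rownames = "feature_id")
  readr::write_tsv(df, mp)
  back2 <- read_expression_matrix(mp, sp)
  expect_identical(back2$values, es$values)
})

test_that("malformed expression inputs fail with informative errors", {
  es <- make_expr(n = 3, m = 4)
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(es, mp, sp)

  # sheet with an extra sample the matrix lacks
  sheet5 <- dplyr::bind_rows(es$samples[, 1:5], tibble::tibble(
    sample_id = "ghost", subject_id = "s99", timepoint = "pre",
    gender = "male", distance_km = 0
  ))
  sp5 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sheet5, sp5)
  expect_error(read_expression_matrix(mp, sp5), "ghost")

  # non-numeric cell named by coordinates
  lines <- readr::read_lines(mp)
  lines[2] <- sub("^(f001\t)[^\t]+", "\\1oops", lines[2])
  readr::write_lines(lines, mp)
  err <- expect_error(read_expression_matrix(mp, sp), "oops")
  expect_match(conditionMessage(err), "f001")

  # duplicate feature id
  write_expression_matrix(es, mp)
  lines <- readr::read_lines(mp)
  lines[3] <- sub("^f002", "f001", lines[3])
  readr::write_lines(lines, mp)
  expect_error(read_expression_matrix(mp, sp), "[Dd]uplicate")
})

test_that("GMT reading collapses duplicates, skips short lines and round-trips", {
  p <- withr::local_tempfile(fileext = ".gmt")
  readr::write_lines(c("T1\tdesc\tA\tB\tA", "", "short\tonly"), p)
  expect_warning(read_gene_sets(p), "fewer than 3")
  db <- suppressWarnings(read_gene_sets(p))
  expect_equal(nrow(db), 1)
  expect_setequal(db$genes[[1]], c("A", "B"))

  readr::write_lines("short\tonly", p)
  expect_error(expect_warning(read_gene_sets(p)), "No valid")

  # 42-term file keeps all 42 terms
  lines <- vapply(1:42, function(i) {
    paste(c(sprintf("T%02d", i), "d", sprintf("g%d", sample(500, 10))), collapse = "\t")
  }, "")
  readr::write_lines(lines, p)
  expect_equal(nrow(read_gene_sets(p)), 42)

  # larger synthetic database: identical universe after re-serialisation
  set.seed(7)
  big <- gene_set_db(
    term_id = sprintf("S%03d", 1:300),
    genes = lapply(1:300, function(i) sample(sprintf("g%04d", 1:7000), sample(5:80, 1)))
  )
  write_gene_sets(big, p)
  back <- read_gene_sets(p)
  expect_equal(length(db_universe(back)), length(db_universe(big)))
  expect_setequal(db_universe(back), db_universe(big))
})

test_that("regulator-target reading filters by type and collapses duplicate edges", {
  p <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    tr_id = c("R1", "R1", "R2", "R1", "R2"),
    target_gene_id = c("gA", "gB", "gC", "gA", "gD"),
    type = c("tfbs", "tfbs", "tfbs", "other", "other")
  ), p)
  db <- suppressMessages(read_tr_targets(p, type_filter = "tfbs"))
  expect_equal(nrow(db), 2)
  expect_setequal(db$targets[[which(db$tr_id == "R1")]], c("gA", "gB"))
  expect_equal(length(db_universe(db)), 3)
  expect_error(suppressMessages(read_tr_targets(p, type_filter = "nope")), "No rows")

  # duplicated (tr, target) rows collapse to one edge
  readr::write_tsv(tibble::tibble(
    tr_id = c("R1", "R1"), target_gene_id = c("gA", "gA"), type = "tfbs"
  ), p)
  db2 <- suppressMessages(read_tr_targets(p, "tfbs"))
  expect_equal(lengths(db2$targets), 1L, ignore_attr = TRUE)
})

test_that("a 196-regulator layout reports 196 regulators and 23,991 distinct targets", {
  genes <- sprintf("g%05d", 1:23991)
  groups <- split(genes, rep_len(1:196, length(genes)))
  db <- tr_target_db(setNames(groups, sprintf("TR%03d", 1:196)))
  expect_equal(nrow(db), 196)
  expect_equal(length(db_universe(db)), 23991)
})

test_that("feature-gene partition is exhaustive, disjoint and counts distinct genes", {
  ann <- tibble::tibble(
    feature_id = c("f1", "f2", "f2", "f3"),
    gene_id = c("gA", "gA", "gB", NA)
  )
  parts <- map_features_to_genes(c("f1", "f2", "f3"), ann)
  expect_equal(parts$unambiguous$feature_id, "f1")
  expect_equal(parts$unambiguous$gene_id, "gA")
  expect_equal(names(parts$ambiguous), "f2")
  expect_setequal(parts$ambiguous$f2, c("gA", "gB"))
  expect_equal(parts$unannotated, "f3")

  # many-to-one collapse counted once
  ann2 <- tibble::tibble(feature_id = c("f1", "f2"), gene_id = c("gA", "gA"))
  expect_equal(map_features_to_genes(c("f1", "f2"), ann2)$n_distinct_genes, 1)

  # conservation on random fixtures
  set.seed(11)
  for (rep in 1:5) {
    feats <- sprintf("f%03d", 1:60)
    ann3 <- tibble::tibble(
      feature_id = sample(feats, 120, replace = TRUE),
      gene_id = sample(c(sprintf("g%02d", 1:30), NA), 120, replace = TRUE)
    )
    parts <- map_features_to_genes(feats, ann3)
    expect_equal(
      nrow(parts$unambiguous) + length(parts$ambiguous) + length(parts$unannotated),
      length(feats)
    )
    expect_length(
      intersect(parts$unambiguous$feature_id, names(parts$ambiguous)), 0
    )
  }
})
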