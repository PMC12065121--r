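make_raw_table <- function() {
  data.frame(
    CatHC = c("Actinopteri", "Actinopteri", "Reptilia", "Actinopteri",
              "Amphibia", "Actinopteri"),
    CatHO = c("Siluriformes", "Siluriformes", "Squamata", "Characiformes",
              "Anura", "Siluriformes"),
    CatHF = c("Pimelodidae", "Pimelodidae", "Colubridae", "Anostomidae",
              "?", "Pimelodidae"),
    CatHG = c("Pimelodus", "Pseudoplatystoma", "Helicops", "Leporinus",
              "Rana", "Pimelodus"),
    CatHS = c("P. maculatus", "P. corruscans", "H. angulatus",
              "L. friderici", "R. sp", "P. blochii"),
    CatE1 = c("aquatic", "aquatic", "aquatic", "aquatic", "terrestrial",
              "aquatic"),
    CatE2 = c("freshwater", "freshwater", "freshwater", "freshwater",
              "freshwater", "freshwater"),
    CatL1 = c("Neotropical", "Neotropical", "Neotropical", "Neotropical",
              "Palaearctic", "Neotropical"),
    CatL2 = c("South America", "South America", "South America",
              "South America", "Europe", "South America"),
    CatL5 = c("Brazil", "Brazil", "Brazil", "Brazil", "France", "Brazil"),
    host_role = c("definitive", "definitive", "definitive", "definitive",
                  "definitive", "paratenic"),
    row.names = paste0("t", 1:6),
    stringsAsFactors = FALSE)
}

test_that("curate applies the five steps in order and reports counts", {
  raw <- make_raw_table()
  labels <- c(t1 = "CladeA", t2 = "CladeA", t3 = "CladeB", t4 = "CladeB",
              t5 = "CladeB", t6 = "CladeA")
  cur <- curate(raw, labels = labels)
  # t6 dropped as paratenic (step 1), t5 for its missing CatHF (step 4)
  expect_equal(rownames(cur$table), c("t1", "t2", "t3", "t4"))
  expect_equal(cur$report$dropped_role, 1L)
  expect_equal(cur$report$dropped_missing_rows, 1L)
  expect_equal(cur$report$dropped_unlabelled, 0L)
  expect_equal(cur$report$rows_out, 4L)
  expect_equal(unname(cur$labels), c("CladeA", "CladeA", "CladeB", "CladeB"))

  # unlabelled rows go at step 5
  cur2 <- curate(raw, labels = labels[c("t1", "t2", "t3")])
  expect_equal(rownames(cur2$table), c("t1", "t2", "t3"))
  expect_equal(cur2$report$dropped_unlabelled, 1L)

  expect_error(curate(raw[, 1:3], labels = labels), "absent.*CatHG")
  expect_error(curate(raw, labels = setNames(rep(NA, 6), paste0("t", 1:6))),
               "step 5")
})

test_that("curate is idempotent and honours the column threshold", {
  raw <- make_raw_table()
  labels <- setNames(rep(c("X", "Y"), 3), paste0("t", 1:6))
  cur1 <- curate(raw, labels = labels)
  tab2 <- cbind(cur1$table, host_role = "definitive")
  cur2 <- curate(tab2, labels = labels)
  expect_identical(cur1$table, cur2$table)
  expect_identical(cur1$labels, cur2$labels)

  # a fully-missing column is dropped rather than wiping out all rows
  raw$CatL5 <- "?"
  cur3 <- curate(raw, labels = labels)
  expect_equal(cur3$report$dropped_columns, "CatL5")
  expect_false("CatL5" %in% names(cur3$table))

  # a stricter threshold drops the partially-missing CatHF column too
  raw2 <- make_raw_table()
  cur4 <- curate(raw2, labels = labels, col_missing_threshold = 0.1)
  expect_true("CatHF" %in% cur4$report$dropped_columns)
})

test_that("synonym harmonization is applied before curation", {
  raw <- make_raw_table()
  labels <- setNames(rep("X", 6), paste0("t", 1:6))
  cur <- curate(raw, labels = labels,
                synonyms = c("Actinopteri" = "Actinopterygii"))
  expect_true(all(cur$table$CatHC[cur$table$CatHO == "Siluriformes"] ==
                    "Actinopterygii"))
})

test_that("one_hot is lossless and its geometry is right", {
  # 2 features with 3 and 4 observed values -> 7 columns, row sums 2
  tab <- data.frame(f1 = c("a", "b", "c", "a", "b"),
                    f2 = c("w", "x", "y", "z", "w"),
                    row.names = paste0("r", 1:5))
  enc <- one_hot(tab, labels = setNames(rep("K", 5), paste0("r", 1:5)))
  expect_equal(ncol(enc$X), 7L)
  expect_true(all(rowSums(enc$X) == 2L))
  expect_true(all(enc$X %in% 0:1))
  expect_identical(decode_one_hot(enc), tab)

  # single feature, single value -> one column of ones
  tab1 <- data.frame(f = rep("v", 3), row.names = paste0("r", 1:3))
  enc1 <- one_hot(tab1)
  expect_equal(dim(enc1$X), c(3L, 1L))
  expect_true(all(enc1$X == 1L))

  # missing cells are a contract breach
  expect_error(one_hot(data.frame(f = c("a", "?"))), "curated")

  # column order: by feature, then first observation
  expect_equal(colnames(enc$X)[1:3], c("f1=a", "f1=b", "f1=c"))
})

test_that("encoder replays exactly on new rows, unseen values zero out", {
  tab <- data.frame(f1 = c("a", "b"), f2 = c("x", "y"),
                    row.names = c("r1", "r2"))
  enc <- one_hot(tab)
  new <- data.frame(f1 = c("b", "q"), f2 = c("x", "y"),
                    row.names = c("n1", "n2"))
  X2 <- apply_encoder(enc$encoder, new)
  expect_equal(colnames(X2), colnames(enc$X))
  expect_equal(unname(X2["n1", ]), c(0L, 1L, 1L, 0L))
  expect_equal(sum(X2["n2", c("f1=a", "f1=b")]), 0L)  # unseen value

  f <- withr::local_tempfile(fileext = ".json")
  write_encoder(enc$encoder, f)
  expect_equal(read_encoder(f), enc$encoder)
})

test_that("encoding width equals the sum of observed cardinalities", {
  # the study's printed cardinalities: widths sum to 446 over 494 rows
  card <- c(CatHC = 5, CatHO = 28, CatHF = 63, CatHG = 116, CatHS = 170,
            CatE1 = 2, CatE2 = 3, CatL1 = 10, CatL2 = 7, CatL5 = 42)
  n <- 494
  tab <- as.data.frame(
    lapply(card, function(k) paste0("v", (seq_len(n) - 1L) %% k + 1L)),
    row.names = paste0("t", seq_len(n)))
  sm <- summarize_metadata(tab)
  expect_equal(unname(sm$cardinality), unname(card), ignore_attr = TRUE)
  expect_equal(sm$data_points, 4940)
  enc <- one_hot(tab)
  expect_equal(ncol(enc$X), 446L)
  expect_equal(ncol(enc$X), sum(sm$cardinality))
  expect_identical(decode_one_hot(enc), tab)
})

test_that("summarize_metadata counts rows, features and data points", {
  empty <- data.frame()
  sm0 <- summarize_metadata(empty)
  expect_equal(sm0$rows, 0L)
  expect_equal(sm0$data_points, 0L)

  cfg <- small_config(k = 3L, size = 6L, seed = 2)
  sim <- make_tree_with_clades(cfg)
  md <- make_metadata(sim$partition, cfg)
  cur <- curate(md$metadata, labels = md$labels)
  sm <- summarize_metadata(cur)
  expect_equal(sm$rows * sm$features, sm$data_points)
  expect_equal(sm$features, 10L)
})

test_that("metadata CSV io round-trips", {
  raw <- make_raw_table()
  f <- withr::local_tempfile(fileext = ".csv")
  write_metadata(raw, f)
  back <- read_metadata(f)
  expect_equal(back, raw)
  expect_error(read_metadata("does-not-exist.csv"), "not found")
})
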