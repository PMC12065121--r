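test_that("fitch_score matches hand-worked examples", {
  t1 <- parse_newick(text = "((A,B),(C,D));")
  expect_equal(fitch_score(t1, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  t2 <- parse_newick(text = "((A,C),(B,D));")
  expect_equal(fitch_score(t2, c(A = "0", B = "0", C = "1", D = "1")), 2L)
  expect_equal(fitch_score(t1, c(A = "0", B = "?", C = "1", D = "1")), 1L)
})

test_that("fitch_score equals brute-force minimization on random trees", {
  withr::local_seed(101)
  for (i in 1:40) {
    tr <- random_test_tree(sample(4:8, 1), multi = i %% 2 == 0)
    st <- random_states(tr, n_states = sample(2:4, 1),
                        p_missing = if (i %% 3 == 0) 0.25 else 0)
    if (all(st %in% "?")) next
    expect_equal(fitch_score(tr, st), brute_force_fitch(tr, st),
                 info = paste("tree", write_newick(tr),
                              "states", paste(st, collapse = "")))
  }
})

test_that("fitch_score agrees with an independent parsimony engine", {
  skip_if_not_installed("phangorn")
  withr::local_seed(77)
  for (i in 1:10) {
    tr <- random_test_tree(sample(5:10, 1), multi = FALSE)
    st <- random_states(tr, n_states = 3)
    pd <- phangorn::phyDat(matrix(st, ncol = 1,
                                  dimnames = list(names(st), NULL)),
                           type = "USER", levels = sort(unique(st)))
    expect_equal(fitch_score(tr, st), phangorn::parsimony(tr, pd))
  }
})

test_that("fitch_score is invariant under state relabeling", {
  withr::local_seed(31)
  for (i in 1:10) {
    tr <- random_test_tree(8, multi = TRUE)
    st <- random_states(tr, n_states = 3)
    perm <- setNames(sample(c("1", "2", "3")), c("1", "2", "3"))
    st2 <- setNames(perm[st], names(st))
    expect_equal(fitch_score(tr, st), fitch_score(tr, st2))
  }
})

test_that("degenerate characters error or score zero", {
  tr <- parse_newick(text = "((A,B),(C,D));")
  expect_error(fitch_score(tr, c(A = "?", B = "?", C = "?", D = "?")),
               "missing for every terminal")
  expect_error(fitch_score(tr, c(A = "0", B = "0", C = "1")), "without a")
  expect_equal(fitch_score(tr, c(A = "0", B = "0", C = "0", D = "?")), 0L)
  # constant character yields no transformation records
  mat <- data.frame(c1 = rep("0", 4), row.names = c("A", "B", "C", "D"))
  expect_equal(nrow(classify_transformations(tr, mat)), 0L)
})

test_that("both reconstructions realize the Fitch score; flavours differ
           only where a genuine placement choice exists", {
  withr::local_seed(202)
  for (i in 1:15) {
    tr <- random_test_tree(sample(4:9, 1), multi = i %% 2 == 0)
    st <- random_states(tr, n_states = sample(2:3, 1),
                        p_missing = if (i %% 4 == 0) 0.2 else 0)
    if (all(st %in% "?")) next
    rec <- mpr_reconstructions(tr, st)
    n_acc <- nrow(cladeforest:::.assignment_changes(tr, rec$acctran))
    n_del <- nrow(cladeforest:::.assignment_changes(tr, rec$deltran))
    expect_equal(n_acc, rec$score)
    expect_equal(n_del, rec$score)
    expect_equal(rec$score, fitch_score(tr, st))
  }

  # single unambiguous origin: the flavours coincide
  tr <- parse_newick(text = "((A,B),(C,D));")
  rec <- mpr_reconstructions(tr, c(A = "1", B = "1", C = "0", D = "0"))
  expect_identical(rec$acctran, rec$deltran)

  # internal-vs-terminal alternative: ACCTRAN pushes the change rootward
  tr2 <- parse_newick(text = "((A,(B,C)),D);")
  rec2 <- mpr_reconstructions(tr2, c(A = "1", B = "1", C = "0", D = "0"))
  expect_false(identical(rec2$acctran, rec2$deltran))
  nt <- length(tr2$tip.label)
  # ACCTRAN: change on the deep branch into {A,B,C}; DELTRAN: on terminals
  acc_changes <- cladeforest:::.assignment_changes(tr2, rec2$acctran)
  del_changes <- cladeforest:::.assignment_changes(tr2, rec2$deltran)
  expect_true(any(acc_changes$node > nt))
  expect_true(all(del_changes$node <= nt))
})

test_that("wildcards never create state changes", {
  withr::local_seed(404)
  for (i in 1:10) {
    tr <- random_test_tree(8, multi = TRUE)
    st <- random_states(tr, n_states = 2, p_missing = 0.4)
    if (all(st %in% "?")) next
    rec <- mpr_reconstructions(tr, st)
    wild_tips <- which(tr$tip.label %in% names(st)[st == "?"])
    for (a in c("acctran", "deltran")) {
      ch <- cladeforest:::.assignment_changes(tr, rec[[a]])
      expect_false(any(ch$node %in% wild_tips))
    }
  }
})

test_that("transformations are classified unique / private / nonprivate", {
  # unique: x originates once, all bearers in the 3-terminal clade
  tr_u <- parse_newick(text = "((A,B,C),D,E,F);")
  mat_u <- data.frame(
    c1 = c("x", "x", "x", "0", "0", "0"),
    row.names = c("A", "B", "C", "D", "E", "F"))
  rec_u <- classify_transformations(tr_u, mat_u)
  focal <- rec_u[rec_u$clade_size >= 3, ]
  expect_equal(nrow(focal), 1L)
  expect_equal(focal$classification, "unique")
  expect_equal(focal$to, "x")
  expect_false(focal$ambiguous)

  # private: x originates twice (from different ancestral states), every
  # bearer inside the focal clade K = (A1,A2,(W1,W2,W3,(V1,V2)))
  tr_p <- parse_newick(text = "((A1,A2,(W1,W2,W3,(V1,V2))),O1,O2);")
  st_p <- c(A1 = "x", A2 = "x", W1 = "z", W2 = "z", W3 = "z",
            V1 = "x", V2 = "x", O1 = "y", O2 = "y")
  expect_equal(fitch_score(tr_p, st_p), brute_force_fitch(tr_p, st_p))
  rec_p <- classify_transformations(tr_p, data.frame(c1 = st_p,
                                                     row.names = names(st_p)))
  k_row <- rec_p[rec_p$clade_size == 7, ]
  expect_equal(nrow(k_row), 1L)
  expect_false(k_row$ambiguous)
  expect_equal(k_row$to, "x")
  expect_equal(k_row$classification, "private")

  # nonprivate: a bearer of x sits outside the focal clade
  tr_n <- parse_newick(text = "((A,B,C),(D,E),F,G);")
  st_n <- c(A = "x", B = "x", C = "x", D = "x", E = "0", F = "0", G = "0")
  rec_n <- classify_transformations(tr_n,
                                    data.frame(c1 = st_n,
                                               row.names = names(st_n)))
  abc <- rec_n[rec_n$clade_size == 3, ]
  expect_equal(abc$classification, "nonprivate")

  # records below the clade-size threshold stay unclassified
  small <- rec_n[rec_n$clade_size < 3, ]
  expect_true(all(is.na(small$classification)))

  expect_error(classify_transformations(tr_n, data.frame(c1 = st_n),
                                        min_clade_size = 0), "positive")
})

test_that("every nonambiguous qualifying record gets exactly one class", {
  withr::local_seed(505)
  for (i in 1:8) {
    cfg <- small_config(k = 3L, size = 5L, seed = i)
    sim <- make_tree_with_clades(cfg)
    cm <- make_character_matrix(sim$tree, n_chars = 4, changes_per_char = 2,
                                seed = i)
    rec <- classify_transformations(sim$tree, cm$matrix)
    qual <- rec[!rec$ambiguous & rec$clade_size >= 3, ]
    expect_true(all(qual$classification %in%
                      c("unique", "private", "nonprivate")))
    expect_true(all(is.na(rec$classification[rec$ambiguous])))
    expect_true(all(rec$from != rec$to))
  }
})

test_that("collapse_unsupported collapses exactly the unsupported branches", {
  tr <- parse_newick(text = "((((A,B),C),D),E);")  # 3 non-root internal
  # no records at all -> star tree
  empty <- data.frame(node = integer(), ambiguous = logical())
  star <- collapse_unsupported(tr, empty)
  expect_equal(star$Nnode, 1L)
  expect_setequal(star$tip.label, tr$tip.label)

  # a character change on every internal branch -> unchanged topology
  mat_all <- data.frame(
    c1 = c("1", "1", "0", "0", "0"), c2 = c("1", "1", "1", "0", "0"),
    c3 = c("1", "1", "1", "1", "0"),
    row.names = c("A", "B", "C", "D", "E"))
  rec_all <- classify_transformations(tr, mat_all, min_clade_size = 3)
  full <- collapse_unsupported(tr, rec_all)
  expect_true(ape::all.equal.phylo(tr, full, use.edge.length = FALSE))

  # support on one of three internal branches -> exactly two collapsed
  mat_one <- data.frame(c2 = c("1", "1", "1", "0", "0"),
                        row.names = c("A", "B", "C", "D", "E"))
  rec_one <- classify_transformations(tr, mat_one)
  part <- collapse_unsupported(tr, rec_one)
  expect_equal(part$Nnode, tr$Nnode - 2L)
  cl <- extract_clades(part, 1)
  expect_equal(lapply(cl, `[[`, "terminals"), list(c("A", "B", "C")))
})
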