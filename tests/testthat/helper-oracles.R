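# Shared fixtures and independent oracles, built in code.

# Brute-force minimum-change count: enumerate every assignment of states to
# internal nodes; wildcard terminals ("?"/"NA"/NA) cost nothing on their
# branch. Independent of the package's dynamic-programming implementation.
brute_force_fitch <- function(tree, states, alphabet = NULL) {
  labs <- tree$tip.label
  if (is.null(names(states))) names(states) <- labs
  obs <- states[labs]
  wild <- is.na(obs) | obs %in% c("?", "NA", "")
  if (is.null(alphabet)) alphabet <- sort(unique(obs[!wild]))
  nt <- length(labs)
  n_int <- tree$Nnode
  grid <- rep(list(alphabet), n_int)
  combos <- as.matrix(do.call(expand.grid,
                              c(grid, list(stringsAsFactors = FALSE))))
  cost <- integer(nrow(combos))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sp <- combos[, p - nt]
    cost <- cost + if (ch <= nt) {
      if (wild[ch]) 0L else as.integer(obs[ch] != sp)
    } else {
      as.integer(combos[, ch - nt] != sp)
    }
  }
  as.integer(min(cost))
}

# Random rooted tree over n tips, with polytomies when multi = TRUE:
# recursive random partition of the tip labels into 2-4 groups.
random_test_tree <- function(n, multi = FALSE) {
  labs <- paste0("t", seq_len(n))
  build <- function(x) {
    if (length(x) == 1L) return(x)
    kmax <- if (multi) min(length(x), 4L) else 2L
    k <- if (length(x) == 2L || kmax == 2L) 2L else
      sample(seq(2L, kmax), 1L)
    grp <- sample(rep(seq_len(k), length.out = length(x)))
    paste0("(", paste(vapply(split(x, grp), build, character(1)),
                      collapse = ","), ")")
  }
  parse_newick(text = paste0(build(labs), ";"))
}

random_states <- function(tree, n_states = 2L, p_missing = 0) {
  labs <- tree$tip.label
  s <- as.character(sample.int(n_states, length(labs), replace = TRUE))
  if (p_missing > 0) s[runif(length(s)) < p_missing] <- "?"
  setNames(s, labs)
}

# small fast synthetic config for tests
small_config <- function(k = 4L, size = 12L, s = 1, seed = 1L, ...) {
  synthetic_config(k = k, clade_sizes = rep(size, k), s = s,
                   paratenic_rate = 0, seed = seed, ...)
}

# encoded matrix + labels from a small synthetic dataset
small_encoded <- function(k = 4L, size = 12L, s = 1, seed = 1L, ...) {
  cfg <- small_config(k, size, s, seed, ...)
  sim <- make_tree_with_clades(cfg)
  md <- make_metadata(sim$partition, cfg)
  cur <- curate(md$metadata, labels = md$labels)
  one_hot(cur)
}
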