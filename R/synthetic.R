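# Synthetic study-scale data: rooted trees with k planted monophyletic
# clades, clade-correlated hierarchical host/biogeography metadata, and
# character matrices with known parsimony structure. Defaults mirror the
# study conditions: 8 clades over 537 terminals (~8% of rows flagged as
# intermediate/paratenic-host records so that ~494 survive curation), ten
# features with cardinalities (5, 28, 63, 116, 170, 2, 3, 10, 7, 42).

#' Synthetic-data configuration
#'
#' @param k Number of planted clades (>= 2).
#' @param clade_sizes Integer vector of clade sizes (recycled to length `k`
#'   if scalar). Default: 537 terminals split as evenly as possible.
#' @param s Signal strength in \[0, 1\]: per terminal and feature group, the
#'   probability of drawing the clade-characteristic profile rather than a
#'   draw from the global pool.
#' @param missing_rate Per-cell missing-data rate in \[0, 1).
#' @param paratenic_rate Fraction of rows flagged as intermediate/paratenic
#'   host records (dropped by curation).
#' @param cardinality Named integer vector of feature cardinalities; host
#'   taxonomy nests species < genus < family < order < class, and country
#'   (CatL5) nests under continent (CatL2); the zoogeographical region
#'   (CatL1) cuts across continents and is drawn independently.
#' @param disjoint_profiles Require clade profiles to be disjoint for every
#'   feature (needs all cardinalities >= k); default `FALSE` — profiles are
#'   distinct as combinations, as in real data where eight clades share
#'   five host classes.
#' @param seed Base seed; all generator randomness derives from it.
#' @return A list of class `cf_config`.
#' @export
synthetic_config <- function(k = 8L,
                             clade_sizes = NULL,
                             s = 0.9,
                             missing_rate = 0,
                             paratenic_rate = 0.08,
                             cardinality = c(CatHC = 5L, CatHO = 28L,
                                             CatHF = 63L, CatHG = 116L,
                                             CatHS = 170L, CatE1 = 2L,
                                             CatE2 = 3L, CatL1 = 10L,
                                             CatL2 = 7L, CatL5 = 42L),
                             disjoint_profiles = FALSE,
                             seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  if (is.null(clade_sizes)) {
    n <- 537L
    clade_sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  }
  if (length(clade_sizes) == 1L) clade_sizes <- rep(clade_sizes, k)
  clade_sizes <- as.integer(clade_sizes)
  if (length(clade_sizes) != k) stop("`clade_sizes` must have length `k`")
  if (any(clade_sizes < 1L)) stop("clade sizes must be positive")
  if (s < 0 || s > 1) stop("`s` must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must be in [0, 1)")
  if (paratenic_rate < 0 || paratenic_rate >= 1)
    stop("`paratenic_rate` must be in [0, 1)")
  req <- cf_features()
  if (!all(req %in% names(cardinality)))
    stop("`cardinality` must name all of: ", paste(req, collapse = ", "))
  cardinality <- vapply(cardinality[req], as.integer, integer(1))
  # the hierarchy needs children at least as numerous as their parents
  if (cardinality["CatHS"] < cardinality["CatHG"] ||
      cardinality["CatHG"] < cardinality["CatHF"] ||
      cardinality["CatHF"] < cardinality["CatHO"] ||
      cardinality["CatHO"] < cardinality["CatHC"] ||
      cardinality["CatL5"] < cardinality["CatL2"])
    stop("nested features need cardinality >= their parent feature's")
  if (disjoint_profiles && any(cardinality < k))
    stop("disjoint profiles need every cardinality >= k; too small: ",
         paste(names(cardinality)[cardinality < k], collapse = ", "))
  if (!disjoint_profiles &&
      (cardinality["CatHO"] < k || cardinality["CatL5"] < k))
    stop("need CatHO and CatL5 cardinality >= k for distinct clade profiles")
  structure(list(k = k, clade_sizes = clade_sizes, s = s,
                 missing_rate = missing_rate,
                 paratenic_rate = paratenic_rate,
                 cardinality = cardinality,
                 disjoint_profiles = disjoint_profiles,
                 seed = as.integer(seed)),
            class = "cf_config")
}

.cfg_seed <- function(config, stream) {
  # small fixed offsets keep tree / metadata / character streams independent
  as.integer((config$seed %% 100000000L) * 7L + stream)
}

# random rooted binary tree over given labels by sequential random joins
.random_join_newick <- function(labels) {
  parts <- labels
  while (length(parts) > 1L) {
    pick <- sample.int(length(parts), 2L)
    joined <- paste0("(", parts[pick[1L]], ",", parts[pick[2L]], ")")
    parts <- c(parts[-pick], joined)
  }
  parts
}

#' Generate a tree with planted monophyletic clades
#'
#' Builds a rooted binary tree whose terminals are partitioned into `k`
#' monophyletic clades of the configured sizes: random coalescent-style
#' joins within each clade, then among the clade roots. Deterministic given
#' the config seed.
#'
#' @param config A `cf_config` from [synthetic_config()].
#' @return List: `tree` (a `phylo`) and `partition` (a `cf_partition`,
#'   clades named `CladeI`, `CladeII`, ...).
#' @export
make_tree_with_clades <- function(config) {
  stopifnot(inherits(config, "cf_config"))
  set.seed(.cfg_seed(config, 1L))
  n <- sum(config$clade_sizes)
  tips <- sprintf("t%04d", seq_len(n))
  clade_names <- paste0("Clade", as.character(utils::as.roman(
    seq_len(config$k))))
  idx <- rep(seq_len(config$k), config$clade_sizes)
  partition <- clade_partition(split(tips, clade_names[idx]))
  roots <- vapply(seq_len(config$k), function(i)
    .random_join_newick(tips[idx == i]), character(1))
  txt <- if (length(roots) > 1L) .random_join_newick(roots) else
    paste0("(", roots, ")")
  tree <- parse_newick(text = paste0(txt, ";"))
  list(tree = tree, partition = partition)
}

# global hierarchical pools: child value index determines its parents
.hier_parent <- function(child_idx, n_parent) ((child_idx - 1L) %% n_parent) + 1L

.value_label <- function(feature, i) {
  sprintf("%s_%03d", sub("^Cat", "", feature), i)
}

# a full host chain (species..class) or geo chain (country, continent)
.host_chain <- function(sp, card) {
  g <- .hier_parent(sp, card["CatHG"])
  f <- .hier_parent(g, card["CatHF"])
  o <- .hier_parent(f, card["CatHO"])
  cl <- .hier_parent(o, card["CatHC"])
  c(CatHC = .value_label("CatHC", cl), CatHO = .value_label("CatHO", o),
    CatHF = .value_label("CatHF", f), CatHG = .value_label("CatHG", g),
    CatHS = .value_label("CatHS", sp))
}

.geo_chain <- function(country, card) {
  cont <- .hier_parent(country, card["CatL2"])
  c(CatL2 = .value_label("CatL2", cont),
    CatL5 = .value_label("CatL5", country))
}

# clade-characteristic profiles; distinct combinations are guaranteed by
# giving each clade its own host order lineage and its own country
.clade_profiles <- function(config) {
  card <- config$cardinality
  k <- config$k
  if (config$disjoint_profiles) {
    sp_idx <- seq_len(k)           # species i -> genus i -> ... class i
    co_idx <- seq_len(k)
  } else {
    # pick species whose order ancestors differ across clades
    orders <- seq_len(k)
    fams <- vapply(orders, function(o)
      which(.hier_parent(seq_len(card["CatHF"]), card["CatHO"]) == o)[1L],
      integer(1))
    gens <- vapply(fams, function(f)
      which(.hier_parent(seq_len(card["CatHG"]), card["CatHF"]) == f)[1L],
      integer(1))
    sp_idx <- vapply(gens, function(g)
      which(.hier_parent(seq_len(card["CatHS"]), card["CatHG"]) == g)[1L],
      integer(1))
    co_idx <- seq_len(k)
  }
  lapply(seq_len(k), function(i) {
    c(.host_chain(sp_idx[i], card),
      CatE1 = .value_label("CatE1", ((i - 1L) %% card["CatE1"]) + 1L),
      CatE2 = .value_label("CatE2", ((i - 1L) %% card["CatE2"]) + 1L),
      CatL1 = .value_label("CatL1", ((i - 1L) %% card["CatL1"]) + 1L),
      .geo_chain(co_idx[i], card))
  })
}

#' Generate clade-correlated metadata
#'
#' Each clade carries a characteristic profile (one full host-taxonomy
#' chain, habitat, aquatic-ecosystem type, zoogeographical region, and one
#' continent/country chain). Per terminal and per feature group, the clade
#' profile is used with probability `s` and an independent draw from the
#' global pool with probability `1 - s`; draws respect the declared
#' hierarchy (a drawn species implies its genus, family, order and class; a
#' drawn country implies its continent). Missing cells are inserted at the
#' configured rate, and a configured fraction of rows is flagged as
#' intermediate/paratenic-host records.
#'
#' @param partition A `cf_partition` (e.g. from [make_tree_with_clades()]).
#' @param config A `cf_config`.
#' @return List: `metadata` (data frame, terminal rownames, the ten feature
#'   columns plus `host_role`) and `labels` (terminal -> clade).
#' @export
make_metadata <- function(partition, config) {
  stopifnot(inherits(config, "cf_config"))
  partition <- clade_partition(unclass(partition))
  set.seed(.cfg_seed(config, 2L))
  card <- config$cardinality
  profiles <- .clade_profiles(config)
  terminals <- unlist(partition, use.names = FALSE)
  clade_of <- rep(names(partition), lengths(partition))
  clade_index <- match(clade_of, names(partition))
  n <- length(terminals)
  feats <- cf_features()
  tab <- matrix(NA_character_, n, length(feats),
                dimnames = list(terminals, feats))
  for (i in seq_len(n)) {
    prof <- profiles[[clade_index[i]]]
    row <- prof
    use_prof <- stats::runif(5L) < config$s  # host, E1, E2, L1, geo groups
    if (!use_prof[1L])
      row[c("CatHC", "CatHO", "CatHF", "CatHG", "CatHS")] <-
        .host_chain(sample.int(card["CatHS"], 1L), card)
    if (!use_prof[2L])
      row["CatE1"] <- .value_label("CatE1", sample.int(card["CatE1"], 1L))
    if (!use_prof[3L])
      row["CatE2"] <- .value_label("CatE2", sample.int(card["CatE2"], 1L))
    if (!use_prof[4L])
      row["CatL1"] <- .value_label("CatL1", sample.int(card["CatL1"], 1L))
    if (!use_prof[5L])
      row[c("CatL2", "CatL5")] <-
        .geo_chain(sample.int(card["CatL5"], 1L), card)
    tab[i, ] <- row[feats]
  }
  if (config$missing_rate > 0) {
    hit <- matrix(stats::runif(length(tab)) < config$missing_rate,
                  nrow = n)
    tab[hit] <- NA_character_
  }
  role <- rep("definitive", n)
  n_par <- round(config$paratenic_rate * n)
  if (n_par > 0) {
    rows <- sample.int(n, n_par)
    role[rows] <- sample(c("paratenic", "intermediate"), n_par,
                         replace = TRUE)
  }
  metadata <- data.frame(tab, host_role = role, stringsAsFactors = FALSE)
  list(metadata = metadata,
       labels = setNames(clade_of, terminals))
}

#' Plant a character on specific branches
#'
#' Low-level helper: evolves one categorical character on the tree by
#' assigning `base` everywhere and overwriting the terminals under each
#' given branch (child node) with the corresponding derived state. Later
#' branches in the list overwrite earlier, nested ones.
#'
#' @param tree A `phylo`.
#' @param nodes Child node ids of the branches carrying a change.
#' @param derived Derived state per branch (recycled).
#' @param base Ancestral state (default "0").
#' @return Named character vector of terminal states.
#' @export
plant_character <- function(tree, nodes, derived = "1", base = "0") {
  validate_tree(tree)
  sets <- .node_terminal_sets(tree)
  derived <- rep_len(as.character(derived), length(nodes))
  states <- setNames(rep(base, length(tree$tip.label)), tree$tip.label)
  for (i in seq_along(nodes)) states[sets[[nodes[i]]]] <- derived[i]
  states
}

#' Generate a character matrix with known parsimony structure
#'
#' Evolves `n_chars` characters by planting a known number of state changes
#' on randomly chosen branches. With `clean = TRUE` the chosen branches are
#' non-nested and each change introduces a distinct derived state, so the
#' Fitch score of each character equals the planted change count; otherwise
#' nested placements may make the true minimum smaller than the number of
#' planted events, and the planted count is an upper bound.
#'
#' @param tree A `phylo`.
#' @param n_chars Number of characters.
#' @param changes_per_char Planted changes per character.
#' @param clean Use non-nested branches and distinct derived states.
#' @param seed Integer seed.
#' @return List: `matrix` (data frame, terminals x characters) and `truth`
#'   (data frame: character, planted change count, branch nodes).
#' @export
make_character_matrix <- function(tree, n_chars = 6L, changes_per_char = 2L,
                                  clean = TRUE, seed = 1L) {
  validate_tree(tree)
  set.seed(seed)
  nt <- length(tree$tip.label)
  root <- .tree_root(tree)
  sets <- .node_terminal_sets(tree)
  candidates <- setdiff(seq_len(nt + tree$Nnode), root)
  cols <- list(); truth <- list()
  for (j in seq_len(n_chars)) {
    picked <- integer(0)
    pool <- sample(candidates)
    for (v in pool) {
      if (length(picked) == changes_per_char) break
      if (clean) {
        overlap <- any(vapply(picked, function(u)
          length(intersect(sets[[u]], sets[[v]])) > 0L, TRUE))
        if (overlap) next
      }
      picked <- c(picked, v)
    }
    if (length(picked) < changes_per_char)
      stop("more changes requested than available branches for character ",
           j)
    derived <- if (clean) as.character(seq_along(picked)) else
      as.character(sample.int(max(2L, changes_per_char), length(picked),
                              replace = TRUE))
    cols[[paste0("char", j)]] <- plant_character(tree, picked, derived,
                                                 base = "0")
    truth[[j]] <- data.frame(character = paste0("char", j),
                             planted_changes = length(picked),
                             nodes = I(list(picked)))
  }
  list(matrix = as.data.frame(cols, stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}
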