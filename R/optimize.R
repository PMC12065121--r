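# Parsimony optimization of unordered categorical characters on rooted
# trees with hard polytomies. Missing ("?") and inapplicable ("NA") cells
# are optimized as full-alphabet wildcards; because a wildcard terminal can
# always adopt its parent's state at zero cost, wildcards never create
# state changes on their own.

MISSING_CODES <- c("?", "NA", "", NA_character_)

.is_missing_state <- function(x) is.na(x) | x %in% c("?", "NA", "")

# normalize a character column into a named vector over the tree's terminals
.prep_states <- function(tree, states) {
  labs <- tree$tip.label
  if (is.null(names(states))) {
    if (length(states) != length(labs))
      stop("unnamed state vector must match the number of terminals")
    names(states) <- labs
  }
  absent <- setdiff(labs, names(states))
  if (length(absent))
    stop("terminal(s) without a character cell: ",
         paste(sort(absent), collapse = ", "))
  states <- as.character(states[labs])
  names(states) <- labs
  states
}

.char_alphabet <- function(states, alphabet = NULL) {
  observed <- sort(unique(states[!.is_missing_state(states)]))
  if (!length(observed)) stop("character is missing for every terminal")
  if (is.null(alphabet)) return(observed)
  alphabet <- as.character(alphabet)
  if (!all(observed %in% alphabet))
    stop("observed state(s) outside the declared alphabet: ",
         paste(setdiff(observed, alphabet), collapse = ", "))
  alphabet
}

# unit-cost Sankoff cost vectors for every node (exact for polytomies and
# set-valued terminals); rows = nodes, cols = alphabet states
.cost_vectors <- function(tree, states, alphabet) {
  nt <- length(tree$tip.label)
  ns <- length(alphabet)
  cost <- matrix(Inf, nrow = nt + tree$Nnode, ncol = ns)
  for (i in seq_len(nt)) {
    s <- states[tree$tip.label[i]]
    if (.is_missing_state(s)) cost[i, ] <- 0 else cost[i, match(s, alphabet)] <- 0
  }
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  internal <- unique(ed[, 1L])
  for (v in internal) cost[v, ] <- 0
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1L]; ch <- ed[i, 2L]
    # min over child states t of cost(t) + [t != s]
    contrib <- pmin(cost[ch, ], min(cost[ch, ]) + 1)
    cost[p, ] <- cost[p, ] + contrib
  }
  cost
}

#' Fitch parsimony score of a categorical character
#'
#' Minimum number of unordered state changes needed to explain the terminal
#' states on a rooted tree, generalized to hard polytomies (Hartigan-style
#' optimization via unit-cost dynamic programming). Missing ("?") and
#' inapplicable ("NA") cells are wildcards over the character's alphabet.
#'
#' @param tree A `phylo` object.
#' @param states Character vector of terminal states, named by terminal (or
#'   unnamed in `tree$tip.label` order).
#' @param alphabet Optional declared state alphabet; defaults to the observed
#'   states, sorted.
#' @return Nonnegative integer: the parsimony score.
#' @export
fitch_score <- function(tree, states, alphabet = NULL) {
  validate_tree(tree)
  states <- .prep_states(tree, states)
  alphabet <- .char_alphabet(states, alphabet)
  cost <- .cost_vectors(tree, states, alphabet)
  as.integer(min(cost[.tree_root(tree), ]))
}

#' ACCTRAN and DELTRAN most-parsimonious reconstructions
#'
#' Computes two full single-state assignments over all nodes, each realizing
#' the Fitch score. Both are deterministic: the root takes the first
#' minimum-cost state in alphabet order; descending the tree, DELTRAN keeps
#' the parent's state whenever it is among the child's minimizers (delaying
#' changes toward the terminals), while ACCTRAN adopts a non-parent minimizer
#' whenever one exists (accelerating changes toward the root). Residual ties
#' are broken by alphabet order.
#'
#' @inheritParams fitch_score
#' @return List with `acctran` and `deltran` (named state vectors over node
#'   ids `1..n_tips+n_nodes`), the `score`, and the `alphabet`.
#' @export
mpr_reconstructions <- function(tree, states, alphabet = NULL) {
  validate_tree(tree)
  states <- .prep_states(tree, states)
  alphabet <- .char_alphabet(states, alphabet)
  cost <- .cost_vectors(tree, states, alphabet)
  root <- .tree_root(tree)
  score <- min(cost[root, ])

  assign_one <- function(flavour) {
    out <- character(nrow(cost))
    out[root] <- alphabet[which.min(cost[root, ])]
    # cladewise order = preorder: parents assigned before their children
    ed <- ape::reorder.phylo(tree, "cladewise")$edge
    for (i in seq_len(nrow(ed))) {
      p <- ed[i, 1L]; ch <- ed[i, 2L]
      f <- out[p]
      m <- cost[ch, ] + as.numeric(alphabet != f)
      minimizers <- alphabet[m == min(m)]
      if (flavour == "deltran") {
        out[ch] <- if (f %in% minimizers) f else minimizers[1L]
      } else {
        non_parent <- setdiff(minimizers, f)
        out[ch] <- if (length(non_parent)) non_parent[1L] else f
      }
    }
    out
  }

  list(acctran = assign_one("acctran"),
       deltran = assign_one("deltran"),
       score = as.integer(score),
       alphabet = alphabet)
}

# data.frame of state changes implied by a full node-state assignment
.assignment_changes <- function(tree, assignment) {
  ed <- tree$edge
  from <- assignment[ed[, 1L]]
  to <- assignment[ed[, 2L]]
  keep <- from != to
  data.frame(node = ed[keep, 2L], from = from[keep], to = to[keep],
             stringsAsFactors = FALSE)
}

#' Classify nonambiguous character transformations
#'
#' Optimizes every character of a matrix on the tree and records the state
#' changes. A transformation on a branch is nonambiguous iff the ACCTRAN and
#' DELTRAN reconstructions agree on its (from, to) pair. Nonambiguous
#' transformations on branches subtending clades of at least `min_clade_size`
#' terminals are classified:
#' \describe{
#'   \item{unique}{the derived state originates exactly once on the tree
#'     (in both reconstructions) and every terminal exhibiting it lies in
#'     the clade — a unique, nonhomoplastic synapomorphy;}
#'   \item{private}{the derived state originates more than once but every
#'     terminal exhibiting it lies in the clade;}
#'   \item{nonprivate}{terminals outside the clade also exhibit the derived
#'     state.}
#' }
#' Transformations on smaller clades (or terminal branches) are kept with
#' classification `NA`; ambiguous transformations are flagged.
#'
#' @param tree A `phylo` object.
#' @param matrix Data frame of characters: rows = terminals (rownames),
#'   columns = characters; cells are state codes, `"?"` (missing) or `"NA"`
#'   (inapplicable).
#' @param min_clade_size Minimum clade size for classification (default 3).
#' @param alphabets Optional named list of declared alphabets per character.
#' @return Data frame with columns `character`, `node` (branch identified by
#'   its child node id), `clade_size`, `from`, `to`, `ambiguous`,
#'   `classification`.
#' @export
classify_transformations <- function(tree, matrix, min_clade_size = 3L,
                                     alphabets = NULL) {
  validate_tree(tree)
  if (!is.numeric(min_clade_size) || min_clade_size < 1)
    stop("`min_clade_size` must be a positive integer")
  matrix <- as.data.frame(matrix, stringsAsFactors = FALSE)
  sets <- .node_terminal_sets(tree)
  out <- list()
  for (char in colnames(matrix)) {
    states <- setNames(as.character(matrix[[char]]), rownames(matrix))
    rec <- mpr_reconstructions(tree, states,
                               alphabet = alphabets[[char]])
    ch_a <- .assignment_changes(tree, rec$acctran)
    ch_d <- .assignment_changes(tree, rec$deltran)
    key_a <- paste(ch_a$node, ch_a$from, ch_a$to, sep = "\x1f")
    key_d <- paste(ch_d$node, ch_d$from, ch_d$to, sep = "\x1f")
    nodes <- sort(union(ch_a$node, ch_d$node))
    if (!length(nodes)) next
    obs <- states[!.is_missing_state(states)]
    rows <- lapply(nodes, function(v) {
      ia <- match(v, ch_a$node); id <- match(v, ch_d$node)
      nonamb <- !is.na(ia) && !is.na(id) && key_a[ia] == key_d[id]
      src <- if (!is.na(ia)) ch_a[ia, ] else ch_d[id, ]
      clade <- sets[[v]]
      cls <- NA_character_
      if (nonamb && length(clade) >= min_clade_size) {
        derived <- src$to
        origins_a <- sum(ch_a$to == derived)
        origins_d <- sum(ch_d$to == derived)
        bearers <- names(obs)[obs == derived]
        exclusive <- all(bearers %in% clade)
        cls <- if (origins_a == 1L && origins_d == 1L && exclusive) "unique"
               else if (exclusive) "private" else "nonprivate"
      }
      data.frame(character = char, node = v, clade_size = length(clade),
                 from = src$from, to = src$to, ambiguous = !nonamb,
                 classification = cls, stringsAsFactors = FALSE)
    })
    out[[char]] <- do.call(rbind, rows)
  }
  if (!length(out))
    return(data.frame(character = character(), node = integer(),
                      clade_size = integer(), from = character(),
                      to = character(), ambiguous = logical(),
                      classification = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse branches without synapomorphic support
#'
#' Every internal non-root branch carrying no nonambiguous transformation of
#' any character is collapsed (its children are re-attached to the
#' grandparent), typically yielding a highly polytomic cladogram when few
#' characters optimize cleanly. Terminals are never removed.
#'
#' @param tree A `phylo` object.
#' @param records Transformation records from [classify_transformations()]
#'   computed on this tree.
#' @return A valid `phylo` with unsupported internal branches collapsed.
#' @export
collapse_unsupported <- function(tree, records) {
  validate_tree(tree)
  supported <- unique(records$node[!records$ambiguous])
  nt <- length(tree$tip.label)
  root <- .tree_root(tree)
  kids <- .tree_children(tree)
  build <- function(v) {
    if (v <= nt) return(.quote_label(tree$tip.label[v]))
    parts <- unlist(lapply(kids[[v]], function(k) {
      if (k > nt && k != root && !(k %in% supported)) {
        # unsupported internal branch: splice grandchildren upward
        sub <- build(k)
        substr(sub, 2L, nchar(sub) - 1L)  # drop its wrapping parens
      } else build(k)
    }))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  parse_newick(text = paste0(build(root), ";"))
}

.quote_label <- function(x) {
  if (grepl("[ ,();:\\[\\]']", x)) paste0("'", gsub("'", "''", x), "'") else x
}
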