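#' @importFrom ape read.tree write.tree
NULL

#' Parse a rooted Newick tree
#'
#' Reads a single rooted tree from a Newick string or file. Polytomies are
#' allowed, single-quoted labels are supported, square-bracket comments are
#' stripped, and a numeric label at an internal node position is kept as a
#' support annotation (in `tree$node.label`). The tree is validated: terminal
#' labels must be unique, non-empty strings.
#'
#' @param text Newick string (exactly one tree, terminated by `;`).
#' @param file Path to a Newick file; exactly one of `text`/`file`.
#' @return An object of class `phylo` (see \pkg{ape}), rooted.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("Newick file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  stopifnot(is.character(text), length(text) == 1L)
  text <- .strip_newick_comments(text)
  .check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error: ape could not read the string")
  tree$tip.label <- .unquote_label(tree$tip.label)
  if (!is.null(tree$node.label))
    tree$node.label <- .unquote_label(tree$node.label)
  validate_tree(tree)
  tree
}

.unquote_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

# remove [...] comments outside quoted labels
.strip_newick_comments <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- character(0)
  in_quote <- FALSE
  depth <- 0L
  for (ch in chars) {
    if (ch == "'" && depth == 0L) in_quote <- !in_quote
    if (!in_quote && ch == "[") { depth <- depth + 1L; next }
    if (!in_quote && ch == "]" && depth > 0L) { depth <- depth - 1L; next }
    if (depth == 0L) out <- c(out, ch)
  }
  paste(out, collapse = "")
}

# cheap structural validation with 1-based character offsets in messages
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error at offset ", i, ": unmatched ')'")
    }
  }
  if (in_quote) stop("Newick parse error: unterminated quoted label")
  if (depth > 0L)
    stop("Newick parse error at offset ", length(chars),
         ": ", depth, " unclosed '('")
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error at offset ", nchar(text),
         ": missing terminating ';'")
}

#' Validate a phylogenetic tree
#'
#' Checks the invariants assumed throughout the package: unique non-empty
#' terminal labels, a single root, and internal nodes with at least two
#' children.
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly; errors otherwise.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  labs <- tree$tip.label
  if (any(is.na(labs)) || any(!nzchar(labs)))
    stop("terminal labels must be non-empty strings")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    stop("duplicate terminal label(s): ", paste(dup, collapse = ", "))
  if (tree$Nnode < 1L) stop("tree has no internal nodes")
  nt <- length(labs)
  # every internal node needs >= 2 children; the root must be unique
  child_count <- tabulate(tree$edge[, 1L], nbins = nt + tree$Nnode)
  internal <- (nt + 1L):(nt + tree$Nnode)
  if (any(child_count[internal] < 2L))
    stop("internal node with fewer than two children (singleton node)")
  parents <- unique(tree$edge[, 1L])
  roots <- setdiff(parents, tree$edge[, 2L])
  if (length(roots) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional output path; if `NULL`, the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# children lists indexed by node id (tips 1..n, internals n+1..n+Nnode)
.tree_children <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

.tree_root <- function(tree) {
  setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
}

# terminal label sets for every node, postorder-accumulated
.node_terminal_sets <- function(tree) {
  nt <- length(tree$tip.label)
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ed)))  # subtree edges precede the edge to the parent
    sets[[ed[i, 1L]]] <- c(sets[[ed[i, 1L]]], sets[[ed[i, 2L]]])
  sets
}

#' Extract clades from a rooted tree
#'
#' A clade is the full terminal set of a non-root internal node; the root's
#' terminal set and singleton terminals are never counted. Clades are ordered
#' by decreasing size, ties broken by the lexicographically smallest member.
#'
#' @param tree A `phylo` object.
#' @param min_size Minimum number of terminals per reported clade.
#' @return A list of clades; each is a list with `id` and sorted `terminals`.
#' @export
extract_clades <- function(tree, min_size = 1L) {
  validate_tree(tree)
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size < 1)
    stop("`min_size` must be a positive integer")
  nt <- length(tree$tip.label)
  root <- .tree_root(tree)
  sets <- .node_terminal_sets(tree)
  nodes <- setdiff((nt + 1L):(nt + tree$Nnode), root)
  nodes <- nodes[vapply(nodes, function(v) length(sets[[v]]) >= min_size, TRUE)]
  clades <- lapply(nodes, function(v) sort(sets[[v]]))
  ord <- order(-lengths(clades),
               vapply(clades, function(x) x[1L], character(1)))
  clades <- clades[ord]
  lapply(seq_along(clades), function(i)
    list(id = paste0("C", i), node = nodes[ord][i], terminals = clades[[i]]))
}

.clade_keys <- function(tree) {
  vapply(extract_clades(tree, 1L),
         function(cl) paste(cl$terminals, collapse = "\x1f"), character(1))
}

#' Compare the clade sets of two rooted trees
#'
#' Clades are the terminal sets of non-root internal nodes; identity is exact
#' terminal-set equality (rooted-tree semantics, no bipartition
#' complementation). Both trees must be defined on the same terminals.
#'
#' @param tree_a,tree_b `phylo` objects over the same terminal set.
#' @return A list with counts `shared`, `only_a`, `only_b`.
#' @export
compare_clade_sets <- function(tree_a, tree_b) {
  validate_tree(tree_a); validate_tree(tree_b)
  sym <- c(setdiff(tree_a$tip.label, tree_b$tip.label),
           setdiff(tree_b$tip.label, tree_a$tip.label))
  if (length(sym))
    stop("trees are not on the same terminal set; symmetric difference: ",
         paste(sort(sym), collapse = ", "))
  a <- .clade_keys(tree_a)
  b <- .clade_keys(tree_b)
  shared <- length(intersect(a, b))
  list(shared = shared,
       only_a = length(a) - shared,
       only_b = length(b) - shared)
}

#' Construct a clade partition
#'
#' A named list of pairwise-disjoint terminal sets, used as prediction labels.
#'
#' @param x Named list of character vectors (clade name -> terminals).
#' @return Validated partition (class `cf_partition`).
#' @export
clade_partition <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x)))
    stop("partition must be a named list with unique non-empty clade names")
  x <- lapply(x, function(v) sort(unique(as.character(v))))
  if (any(lengths(x) < 1L)) stop("every clade must contain >= 1 terminal")
  all_terms <- unlist(x, use.names = FALSE)
  dup <- unique(all_terms[duplicated(all_terms)])
  if (length(dup))
    stop("overlapping clades; shared terminal(s): ",
         paste(dup, collapse = ", "))
  structure(x, class = "cf_partition")
}

#' Label tree terminals by clade membership
#'
#' Maps every terminal of `tree` to its clade name in `partition`, or to
#' `"UNASSIGNED"` when it belongs to no clade. Monophyly of each clade on the
#' tree is verified; violations are reported as warnings, not errors.
#'
#' @param tree A `phylo` object.
#' @param partition A `cf_partition` (or coercible named list).
#' @return Named character vector, one entry per terminal of `tree`.
#' @export
label_terminals <- function(tree, partition) {
  validate_tree(tree)
  partition <- clade_partition(unclass(partition))
  unknown <- setdiff(unlist(partition), tree$tip.label)
  if (length(unknown))
    stop("partition terminal(s) absent from tree: ",
         paste(sort(unknown), collapse = ", "))
  labels <- setNames(rep("UNASSIGNED", length(tree$tip.label)),
                     tree$tip.label)
  keys <- .clade_keys(tree)
  for (nm in names(partition)) {
    members <- partition[[nm]]
    labels[members] <- nm
    if (length(members) > 1L &&
        !(paste(members, collapse = "\x1f") %in% keys))
      warning("clade '", nm, "' is not monophyletic on the tree")
  }
  labels
}

#' Read / write clade partitions
#'
#' CSV files have two columns, `terminal,clade`; JSON files map clade name to
#' an array of terminals.
#'
#' @param file Path to a `.csv` or `.json` partition file.
#' @return A `cf_partition`.
#' @export
read_partition <- function(file) {
  if (!file.exists(file)) stop("partition file not found: ", file)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    return(clade_partition(as.list(x)))
  }
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("terminal", "clade") %in% names(df)))
    stop("partition CSV needs columns `terminal` and `clade`")
  clade_partition(split(df$terminal, df$clade))
}

#' @rdname read_partition
#' @param partition A `cf_partition`.
#' @export
write_partition <- function(partition, file) {
  partition <- clade_partition(unclass(partition))
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(partition), file, auto_unbox = FALSE)
  } else {
    df <- data.frame(
      terminal = unlist(partition, use.names = FALSE),
      clade = rep(names(partition), lengths(partition)),
      stringsAsFactors = FALSE)
    utils::write.csv(df, file, row.names = FALSE)
  }
  invisible(file)
}
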