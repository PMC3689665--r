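#' Parse a Newick string into a validated phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned object is
#' a standard `"phylo"` tree that every other function in the package
#' consumes. Square-bracket comments are stripped before parsing; quoted
#' labels are unquoted; polytomies are preserved as-is. A root edge, if
#' present, is kept on the object but ignored by all per-species metrics
#' (it subtends every tip and is therefore shared by definition).
#'
#' @param text a single Newick string (must end with `;`).
#' @return An object of class `"phylo"` with at least 2 uniquely labelled
#'   tips and non-negative edge lengths.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' fair_proportion_ed(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # strip [...] comments (the common Newick comment dialect)
  clean <- gsub("\\[[^]]*\\]", "", text)
  if (!grepl(";", clean)) {
    stop("malformed Newick: no terminating ';' found near position ",
         nchar(clean), call. = FALSE)
  }
  tr <- tryCatch(
    ape::read.tree(text = clean),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr)) {
    # locate first structural imbalance for the error message
    op <- cumsum(strsplit(clean, "")[[1]] == "(") -
      cumsum(strsplit(clean, "")[[1]] == ")")
    pos <- if (any(op < 0)) which(op < 0)[1] else nchar(clean)
    stop("malformed Newick string (check position ", pos, ")", call. = FALSE)
  }
  # unquote 'quoted labels'
  tr$tip.label <- gsub("^'(.*)'$", "\\1", tr$tip.label)
  validate_phylo(tr)
}

validate_phylo <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  n <- length(tr$tip.label)
  if (n < 2L) stop("validation error: tree has fewer than 2 tips", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("validation error: duplicate tip labels: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    stop("validation error: tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0)) {
    stop("validation error: edge lengths must be non-negative and non-missing",
         call. = FALSE)
  }
  pend <- tr$edge.length[match(seq_len(n), tr$edge[, 2])]
  if (any(pend == 0)) {
    warning("tree has zero-length pendant edges; species ages of 0 can ",
            "degrade downstream regressions (log offsets are applied there)",
            call. = FALSE)
  }
  tr
}

#' Read / write a single Newick tree file
#'
#' @param path file path holding exactly one Newick tree.
#' @return `read_phylo()` returns a validated `"phylo"`; `write_phylo()`
#'   returns `path` invisibly.
#' @export
read_phylo <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

#' @rdname read_phylo
#' @param tree a `"phylo"` object.
#' @export
write_phylo <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# parent / pendant-length lookup tables, indexed by node id
tree_tables <- function(tree) {
  nnode <- max(tree$edge)
  parent <- integer(nnode)
  elen <- numeric(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  list(parent = parent, elen = elen, root = root, nnode = nnode)
}

# number of tips descending from each node (tips count themselves)
node_tip_counts <- function(tree) {
  tt <- tree_tables(tree)
  n <- length(tree$tip.label)
  cnt <- integer(tt$nnode)
  cnt[seq_len(n)] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    cnt[po[i, 1]] <- cnt[po[i, 1]] + cnt[po[i, 2]]
  }
  cnt
}

# distance from the root to each node (root edge ignored)
node_depths <- function(tree) {
  tt <- tree_tables(tree)
  dep <- numeric(tt$nnode)
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(pre)))) { # reverse postorder = preorder
    dep[pre[i, 2]] <- dep[pre[i, 1]] + tt$elen[pre[i, 2]]
  }
  dep
}

#' Species ages: terminal branch lengths
#'
#' The length of each tip's pendant edge, in the tree's time units (Myr for a
#' dated tree). Used as a proxy for species age / evolutionary uniqueness of
#' the unshared part of a species' history.
#'
#' @param tree a `"phylo"` object.
#' @return Named numeric vector, one entry per tip.
#' @export
terminal_branch_lengths <- function(tree) {
  validate_suppress(tree)
  n <- length(tree$tip.label)
  stats::setNames(tree$edge.length[match(seq_len(n), tree$edge[, 2])],
                  tree$tip.label)
}

# validation without re-raising the zero-pendant warning on every call
validate_suppress <- function(tree) {
  suppressWarnings(validate_phylo(tree))
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Each edge's length is divided equally among the tips that descend from it;
#' a species' ED is the sum of its shares along its root-to-tip path. The
#' scores therefore partition the total tree length exactly:
#' `sum(fair_proportion_ed(tree)) == sum(tree$edge.length)` (minus any root
#' edge, which is shared by all tips and ignored).
#'
#' @param tree a `"phylo"` object.
#' @return Named numeric vector of ED scores (same units as the edge
#'   lengths), one per tip.
#' @export
fair_proportion_ed <- function(tree) {
  validate_suppress(tree)
  n <- length(tree$tip.label)
  tt <- tree_tables(tree)
  cnt <- node_tip_counts(tree)
  share <- tt$elen / pmax(cnt, 1L) # per-edge per-descendant-tip share
  ed <- numeric(n)
  for (i in seq_len(n)) {
    node <- i
    acc <- 0
    while (node != tt$root) {
      acc <- acc + share[node]
      node <- tt$parent[node]
    }
    ed[i] <- acc
  }
  stats::setNames(ed, tree$tip.label)
}

#' Phylogenetic (Brownian) covariance matrix
#'
#' `C[i, j]` is the depth (distance from the root) of the most recent common
#' ancestor of tips `i` and `j`; the diagonal holds root-to-tip depths. This
#' is the expected covariance of a unit-rate Brownian trait and the `V`
#' matrix used by Blomberg's K and PGLS. Any root edge is ignored.
#'
#' @param tree a `"phylo"` object.
#' @return Symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_suppress(tree)
  n <- length(tree$tip.label)
  dep <- node_depths(tree)
  # descendant tip sets per node, accumulated in postorder
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    desc[[po[i, 1]]] <- c(desc[[po[i, 1]]], desc[[po[i, 2]]])
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  internal <- unique(po[, 1])
  for (nd in internal) {
    kids <- po[po[, 1] == nd, 2]
    if (length(kids) < 2L) next
    for (a in seq_len(length(kids) - 1L)) {
      for (b in seq.int(a + 1L, length(kids))) {
        C[desc[[kids[a]]], desc[[kids[b]]]] <- dep[nd]
        C[desc[[kids[b]]], desc[[kids[a]]]] <- dep[nd]
      }
    }
  }
  diag(C) <- dep[seq_len(n)]
  C
}

#' Patristic distance matrix
#'
#' Pairwise sums of edge lengths along the tree path between tips, derived
#' from the tree-metric identity `d(i,j) = C[i,i] + C[j,j] - 2 C[i,j]` with
#' `C` the shared-path covariance of [phylo_vcv()].
#'
#' @param tree a `"phylo"` object.
#' @return Symmetric non-negative matrix with zero diagonal and tip labels
#'   as dimnames.
#' @export
patristic_distances <- function(tree) {
  C <- phylo_vcv(tree)
  d <- diag(C)
  D <- outer(d, d, "+") - 2 * C
  D[D < 0] <- 0 # numerical noise guard
  diag(D) <- 0
  D
}

#' Export per-species ED and BL as CSV
#'
#' Writes a table with columns `species,ed,bl` (units of the tree's edge
#' lengths).
#'
#' @param tree a `"phylo"` object.
#' @param path output CSV path.
#' @return The data frame, invisibly.
#' @export
export_ed_bl <- function(tree, path) {
  ed <- fair_proportion_ed(tree)
  bl <- terminal_branch_lengths(tree)
  df <- data.frame(species = names(ed), ed = unname(ed),
                   bl = unname(bl[names(ed)]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
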