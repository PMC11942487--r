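#' Average-linkage hierarchical clustering of a distance matrix
#'
#' Unweighted average linkage (UPGMA-style): the distance between two
#' clusters is the arithmetic mean of all cross-pair distances. Ties in the
#' minimum inter-cluster distance are broken by the lexicographically
#' smallest index pair of the active clusters (leaves in input order first),
#' which makes trees bit-reproducible even on degenerate inputs such as
#' duplicated genes.
#'
#' @param dist Symmetric numeric matrix with zero diagonal, non-negative.
#' @param labels Leaf labels; defaults to `rownames(dist)`.
#' @return An object of class `c("coex_dendro", "hclust")` with the usual
#'   `merge`, `height`, `labels`, `order` fields. Merge heights are in the
#'   units of `dist` (TOM distance for coexpression trees).
#' @export
average_linkage <- function(dist, labels = rownames(dist)) {
  n <- nrow(dist)
  if (n < 2L) stop("need at least 2 leaves")
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  stopifnot(ncol(dist) == n, length(labels) == n)
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(dist) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(dist < 0)) stop("distances must be non-negative")

  D <- dist
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  id <- -seq_len(n)               # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    m <- min(sub)
    # lexicographically smallest (i, j): smallest row, then smallest column
    hits <- which(sub == m, arr.ind = TRUE)
    pick <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    i <- act[pick[1L]]; j <- act[pick[2L]]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- m
    # Lance-Williams update for unweighted average linkage
    others <- act[act != i & act != j]
    if (length(others)) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) / (size[i] + size[j])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }

  tree <- structure(list(merge = merge, height = height,
                         order = integer(0), labels = labels,
                         method = "average", call = match.call(),
                         dist.method = "tom"),
                    class = c("coex_dendro", "hclust"))
  tree$order <- dendro_leaf_order(tree)
  tree
}

# left-to-right leaf order implied by the merge matrix (iterative DFS)
dendro_leaf_order <- function(tree) {
  n <- nrow(tree$merge) + 1L
  stack <- n - 1L   # root merge index
  ord <- integer(0)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (node < 0L) {
      ord <- c(ord, -node)
    } else {
      # push right then left so left is emitted first
      stack <- c(stack, tree$merge[node, 2L], tree$merge[node, 1L])
    }
  }
  ord
}

# parent/leaf-count index over a coex_dendro; O(n), used by clade queries
dendro_index <- function(tree) {
  m <- tree$merge
  k <- nrow(m)
  parent <- rep(NA_integer_, k)       # parent merge of each merge (NA = root)
  leaf_parent <- rep(NA_integer_, k + 1L)
  count <- integer(k)
  for (i in seq_len(k)) {
    for (child in m[i, ]) {
      if (child < 0L) {
        leaf_parent[-child] <- i
        count[i] <- count[i] + 1L
      } else {
        parent[child] <- i
        count[i] <- count[i] + count[child]
      }
    }
  }
  list(parent = parent, leaf_parent = leaf_parent, leaf_count = count)
}

#' Leaves under an internal node
#'
#' @param tree A `coex_dendro` tree.
#' @param node Internal node id: the merge-row index, `1 .. n - 1` (the root
#'   is node `n - 1`).
#' @return Character vector of descendant leaf labels, in tree order.
#' @export
leaf_set <- function(tree, node) {
  k <- nrow(tree$merge)
  if (!is.numeric(node) || length(node) != 1L || node < 1L || node > k) {
    stop("unknown internal node: ", node)
  }
  stack <- as.integer(node)
  leaves <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v < 0L) leaves <- c(leaves, -v)
    else stack <- c(stack, tree$merge[v, 2L], tree$merge[v, 1L])
  }
  tree$labels[leaves]
}

#' Internal-node ancestors of a leaf, from parent to root
#'
#' @param tree A `coex_dendro` tree.
#' @param leaf Leaf label.
#' @return Integer vector of merge-row indices from the leaf's parent up to
#'   the root; its length is the depth of the leaf.
#' @export
ancestors <- function(tree, leaf) {
  pos <- match(leaf, tree$labels)
  if (is.na(pos)) stop("unknown leaf: ", leaf)
  idx <- dendro_index(tree)
  chain <- integer(0)
  node <- idx$leaf_parent[pos]
  while (!is.na(node)) {
    chain <- c(chain, node)
    node <- idx$parent[node]
  }
  chain
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths encode height differences (parent merge height minus own
#' height; leaves sit at height 0), so leaf-to-root path lengths reproduce
#' merge heights and the tree is ultrametric. The string is terminated by
#' `;`.
#'
#' @param tree A `coex_dendro` tree.
#' @param digits Significant digits for branch lengths (default 15).
#' @return A single Newick string.
#' @export
to_newick <- function(tree, digits = 15L) {
  bad <- grepl("[(),:;\\s]", tree$labels, perl = TRUE)
  if (any(bad)) {
    stop("leaf label(s) contain Newick metacharacters: ",
         paste(utils::head(tree$labels[bad], 5L), collapse = ", "))
  }
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  build <- function(node, parent_h) {
    if (node < 0L) {
      paste0(tree$labels[-node], ":", fmt(parent_h))
    } else {
      h <- tree$height[node]
      inner <- paste0("(", build(tree$merge[node, 1L], h), ",",
                      build(tree$merge[node, 2L], h), ")")
      if (is.na(parent_h)) inner else paste0(inner, ":", fmt(parent_h - h))
    }
  }
  paste0(build(nrow(tree$merge), NA_real_), ";")
}

#' Parse a rooted binary Newick string into a dendrogram
#'
#' Node heights are recovered as the maximum downstream path length, so
#' ultrametric input reproduces merge heights exactly. Only strictly binary
#' trees are accepted.
#'
#' @param text A Newick string (or a file's single line).
#' @return A `coex_dendro` tree.
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1L
    if (chars[pos] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", pos)
    }
  }
  if (depth != 0L) stop("unbalanced '(' : ", depth, " unclosed at end of string")
  if (!grepl(";\\s*$", text)) stop("missing terminal ';' at position ", nchar(text))
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("Newick parse failure")
  if (!ape::is.binary(phy) || ape::Ntip(phy) < 2L) {
    stop("tree is not strictly binary (polytomies are not supported)")
  }
  if (is.null(phy$edge.length)) stop("branch lengths are required")
  phylo_to_dendro(phy)
}

# convert an ape phylo (rooted, binary, with branch lengths) to coex_dendro
phylo_to_dendro <- function(phy) {
  n <- ape::Ntip(phy)
  phy <- stats::reorder(phy, "postorder")
  nnode <- n + phy$Nnode
  h <- numeric(nnode)                     # max downstream path length
  children <- vector("list", nnode)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; chl <- phy$edge[e, 2L]
    h[par] <- max(h[par], h[chl] + phy$edge.length[e])
    children[[par]] <- c(children[[par]], chl)
  }
  internal <- (n + 1L):nnode
  ord <- internal[order(h[internal], internal)]   # merges sorted by height
  merge_row <- integer(nnode)
  merge <- matrix(0L, length(ord), 2L)
  height <- numeric(length(ord))
  for (i in seq_along(ord)) {
    v <- ord[i]
    ch <- children[[v]]
    if (length(ch) != 2L) stop("tree is not strictly binary")
    enc <- vapply(ch, function(c) if (c <= n) -c else merge_row[c], 0L)
    merge[i, ] <- enc
    height[i] <- h[v]
    merge_row[v] <- i
  }
  tree <- structure(list(merge = merge, height = height, order = integer(0),
                         labels = phy$tip.label, method = "average",
                         call = match.call(), dist.method = "tom"),
                    class = c("coex_dendro", "hclust"))
  tree$order <- dendro_leaf_order(tree)
  tree
}

#' @export
print.coex_dendro <- function(x, ...) {
  cat("<coex_dendro> ", length(x$labels), " leaves, root height ",
      signif(max(x$height), 4L), "\n", sep = "")
  invisible(x)
}
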