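# static cut: component label per leaf after joining merges below a height
static_cut <- function(tree, h, strict = FALSE) {
  n <- nrow(tree$merge) + 1L
  # union-find over leaves (1..n) and merges (n+1..2n-1)
  parent_lab <- seq_len(2L * n - 1L)
  find <- function(x) { while (parent_lab[x] != x) { parent_lab[x] <<- parent_lab[parent_lab[x]]; x <- parent_lab[x] }; x }
  for (i in seq_len(n - 1L)) {
    keep <- if (strict) tree$height[i] < h else tree$height[i] <= h
    if (!keep) next
    ids <- vapply(tree$merge[i, ], function(ch) if (ch < 0L) -ch else n + ch, 0L)
    r1 <- find(ids[1L]); r2 <- find(ids[2L])
    parent_lab[r1] <- r2
    parent_lab[n + i] <- r2
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Detect modules on a dendrogram by hybrid dynamic tree cut
#'
#' Adaptive branch decomposition of the coexpression dendrogram. Branches
#' are grown bottom-up through the merge sequence below the static cut at
#' `cut_height` (by default 99% of the height range above the 5% quantile
#' of merge heights). A branch is a viable module core at the height where
#' it joins the rest of the tree when it has at least `min_cluster_size`
#' leaves, its core scatter (mean normalized height of its first
#' `min_cluster_size - 1` merges) is at most `0.64 + 0.10 * deep_split`,
#' and the gap between its joining height and the height at which it
#' reached `min_cluster_size` members is at least
#' `(1 - maxCoreScatter) * 3/4` (heights normalized to the
#' `[5% quantile, cut_height]` range). When two viable branches meet, both
#' become modules; a viable branch meeting an already-spent one is emitted
#' alone; branches still alive at the cut are evaluated against
#' `cut_height`. Members that a branch absorbed on the way up but that sit
#' far from its core are detached again (`fringe_frac`).
#'
#' Unassigned genes are optionally reassigned in a PAM-like stage: a gene
#' joins the module with smallest average TOM dissimilarity, provided that
#' dissimilarity is within the module's own radius (the largest average
#' dissimilarity of any current member to its co-members), so genuinely
#' unclustered background genes stay grey.
#'
#' @param tree A `coex_dendro` over the genes.
#' @param dist TOM distance matrix with dimnames matching the tree leaves.
#' @param min_cluster_size Minimum module size (default 15).
#' @param deep_split Split sensitivity 0-4 (default 2).
#' @param pam_stage Run the PAM-like reassignment stage (default `TRUE`).
#' @param fringe_frac Fringe-pruning threshold: a module member whose
#'   average similarity to its co-members is below this fraction of the
#'   module's median member similarity is detached and returned to the
#'   unassigned pool before the PAM stage (default 0.15; 0 disables).
#' @param max_pam_dist Numeric cap on the PAM assignment dissimilarity;
#'   `NULL` (default) uses the per-module radius rule described above.
#' @param cut_height Static cut height; `NULL` (default) uses
#'   `q05 + 0.99 * (max(height) - q05)`.
#' @return Integer vector of module labels along `tree$labels`; 0 = grey
#'   (unassigned). Labels are ordered by descending module size.
#' @export
dynamic_tree_cut <- function(tree, dist, min_cluster_size = 15L, deep_split = 2L,
                             pam_stage = TRUE, fringe_frac = 0.15,
                             max_pam_dist = NULL, cut_height = NULL) {
  n <- length(tree$labels)
  if (!identical(sort(tree$labels), sort(rownames(dist)))) {
    stop("tree leaves and distance matrix labels do not match")
  }
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4")
  dist <- dist[tree$labels, tree$labels]

  H <- tree$height
  hmin <- stats::quantile(H, 0.05, names = FALSE)
  if (is.null(cut_height)) cut_height <- hmin + 0.99 * (max(H) - hmin)
  rng <- cut_height - hmin
  norm_h <- function(h) if (rng <= 0) 0 else pmin(pmax((h - hmin) / rng, 0), 1)
  max_core_scatter <- 0.64 + 0.10 * deep_split
  min_gap <- (1 - max_core_scatter) * 3 / 4

  # Branches are grown bottom-up through the merge sequence (heights are
  # sorted by construction). Each branch tracks its members and the
  # normalized heights of its internal merges in height order. A branch is a
  # viable module core at closing height h when it has >= min_cluster_size
  # members, the mean height of its first (min_cluster_size - 1) merges (the
  # core scatter) is at most max_core_scatter, and the gap between h and the
  # height at which the branch reached min_cluster_size members is at least
  # min_gap. When two viable branches meet, both are emitted as modules and
  # the union continues as a spent branch that can absorb leaves but is
  # never emitted itself; a viable branch meeting a spent one is emitted
  # alone. Branches still alive at the static cut are evaluated against
  # cut_height.
  k <- n - 1L
  branches <- vector("list", k)         # branch state, indexed by merge row
  branch_at <- integer(k)               # current branch id holding merge i's subtree
  modules <- list()
  emit <- function(b) modules[[length(modules) + 1L]] <<- b$leaves
  core_m <- min_cluster_size - 1L
  viable <- function(b, h_close) {
    if (b$spent || length(b$leaves) < min_cluster_size) return(FALSE)
    mean(b$mh[seq_len(core_m)]) <= max_core_scatter &&
      (norm_h(h_close) - b$mh[core_m]) >= min_gap
  }
  child_branch <- function(ch) {
    if (ch < 0L) list(leaves = -ch, mh = numeric(0), spent = FALSE)
    else branches[[branch_at[ch]]]
  }
  alive <- rep(FALSE, k)
  for (i in seq_len(k)) {
    if (H[i] > cut_height) break        # merges above the cut never join branches
    b1 <- child_branch(tree$merge[i, 1L])
    b2 <- child_branch(tree$merge[i, 2L])
    q1 <- viable(b1, H[i]); q2 <- viable(b2, H[i])
    emitted <- FALSE
    if (q1 && q2) { emit(b1); emit(b2); emitted <- TRUE }
    else if (q1 && b2$spent) { emit(b1); emitted <- TRUE }
    else if (q2 && b1$spent) { emit(b2); emitted <- TRUE }
    branches[[i]] <- list(leaves = c(b1$leaves, b2$leaves),
                          mh = sort(c(b1$mh, b2$mh, norm_h(H[i]))),
                          spent = emitted || b1$spent || b2$spent)
    for (ch in tree$merge[i, ]) if (ch > 0L) alive[branch_at[ch]] <- FALSE
    branch_at[i] <- i
    alive[i] <- TRUE
  }
  for (i in which(alive)) {
    if (viable(branches[[i]], cut_height)) emit(branches[[i]])
  }

  assignment <- integer(n)
  for (m in seq_along(modules)) assignment[modules[[m]]] <- m

  # fringe pruning: branches absorb occasional spuriously-correlated leaves
  # on their way up; a member whose average similarity (1 - dissimilarity)
  # to its co-members falls under fringe_frac of the module's median member
  # similarity is detached as fringe and returned to the unassigned pool.
  if (fringe_frac > 0 && length(modules)) {
    for (m in seq_along(modules)) {
      g <- which(assignment == m)
      if (length(g) < 3L) next
      avg_sim <- vapply(seq_along(g),
                        function(t) 1 - mean(dist[g[t], g[-t]]), 0)
      assignment[g[avg_sim < fringe_frac * stats::median(avg_sim)]] <- 0L
    }
  }

  if (pam_stage && any(assignment > 0L)) {
    unlab <- which(assignment == 0L)
    mem <- split(seq_len(n)[assignment > 0L], assignment[assignment > 0L])
    radius <- vapply(mem, function(g) {
      max(vapply(seq_along(g), function(t) mean(dist[g[t], g[-t]]), 0))
    }, 0)
    for (g in unlab) {
      avgd <- vapply(mem, function(mm) mean(dist[g, mm]), 0)
      best <- which.min(avgd)
      cap <- if (is.null(max_pam_dist)) radius[best] else max_pam_dist
      if (avgd[best] <= cap) assignment[g] <- as.integer(names(mem)[best])
    }
  }

  relabel_by_size(assignment, tree$labels)
}

# renumber 1..K by descending size; ties by lexicographically smallest member
relabel_by_size <- function(assignment, labels) {
  stopifnot(length(assignment) == length(labels))
  ids <- setdiff(sort(unique(assignment)), 0L)
  if (!length(ids)) return(stats::setNames(assignment, labels))
  sizes <- vapply(ids, function(i) sum(assignment == i), 0L)
  firsts <- vapply(ids, function(i) min(labels[assignment == i]), "")
  ord <- ids[order(-sizes, firsts)]
  out <- integer(length(assignment))
  for (new in seq_along(ord)) out[assignment == ord[new]] <- new
  stats::setNames(out, labels)
}

#' Module eigengene
#'
#' The eigengene is the first right-singular direction of the module's
#' gene-standardized expression submatrix, scaled to unit variance across
#' samples and sign-oriented to correlate positively with the module's mean
#' standardized expression. `var_explained` is the leading singular value
#' squared over the total variance of the standardized submatrix.
#'
#' @param expr Genes x samples expression matrix.
#' @param member_genes Gene ids of the module (>= 1, all present in `expr`).
#' @return List with `eigengene` (named numeric over samples) and
#'   `var_explained` in `[0, 1]`.
#' @export
module_eigengene <- function(expr, member_genes) {
  missing <- setdiff(member_genes, rownames(expr))
  if (length(missing)) {
    stop("gene(s) absent from expression: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (!length(member_genes)) stop("module has no member genes")
  x <- expr[member_genes, , drop = FALSE]
  xs <- t(scale(t(x)))                    # per-gene zero mean, unit variance
  sv <- svd(xs)
  v <- sv$v[, 1L]
  mean_profile <- colMeans(xs)
  if (stats::sd(v) == 0) stop("degenerate eigengene (constant)")
  if (sum(v * mean_profile) < 0) v <- -v
  e <- v / stats::sd(v)
  list(eigengene = stats::setNames(e, colnames(expr)),
       var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

# eigengene matrix (modules x samples) for a gene -> label assignment
module_eigengenes <- function(expr, assignment) {
  labs <- setdiff(unique(assignment), c(0L, "0", "grey"))
  labs <- labs[order(as.character(labs))]
  E <- matrix(0, length(labs), ncol(expr),
              dimnames = list(as.character(labs), colnames(expr)))
  ve <- stats::setNames(numeric(length(labs)), as.character(labs))
  for (l in labs) {
    me <- module_eigengene(expr, names(assignment)[assignment == l])
    E[as.character(l), ] <- me$eigengene
    ve[[as.character(l)]] <- me$var_explained
  }
  list(eigengenes = E, var_explained = ve)
}

#' Merge modules with close eigengenes
#'
#' Iterates: compute module eigengenes, form the eigengene dissimilarity
#' `1 - PCC`, cluster modules by average linkage, and merge every group of
#' modules joined strictly below `merge_height`; stops when no merge occurs.
#' Grey (unassigned) genes never participate. After convergence no pair of
#' surviving eigengenes correlates above `1 - merge_height`.
#'
#' @param expr Genes x samples expression matrix.
#' @param assignment Named (by gene) module label vector; 0 or "grey" =
#'   unassigned.
#' @param merge_height Eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @return An object of class `module_partition`: list with `assignment`
#'   (gene -> color, "grey" for unassigned), `colors` (descending size),
#'   `eigengenes` (color x sample matrix), `var_explained`, `merge_log`,
#'   and `n_premerge` (module count before merging).
#' @export
merge_close_modules <- function(expr, assignment, merge_height = 0.25) {
  stopifnot(!is.null(names(assignment)))
  current <- assignment
  merge_log <- list()
  n_premerge <- length(setdiff(unique(current), c(0L, "0", "grey")))
  repeat {
    labs <- setdiff(unique(current), c(0L, "0", "grey"))
    if (length(labs) < 2L) break
    eig <- module_eigengenes(expr, current)
    diss <- 1 - stats::cor(t(eig$eigengenes))
    mtree <- average_linkage(diss, rownames(eig$eigengenes))
    groups <- static_cut(mtree, merge_height, strict = TRUE)
    if (max(groups) == length(labs)) break      # all singletons: converged
    round_log <- list()
    for (g in unique(groups)) {
      members <- mtree$labels[groups == g]
      if (length(members) < 2L) next
      sizes <- vapply(members, function(m) sum(current == m), 0L)
      target <- members[order(-sizes, members)][1L]
      current[current %in% members] <- target
      round_log[[length(round_log) + 1L]] <- list(merged = members, into = target)
    }
    merge_log[[length(merge_log) + 1L]] <- round_log
  }
  current_int <- ifelse(current %in% c(0L, "0", "grey"), 0L,
                        match(current, sort(unique(current[!current %in% c(0L, "0", "grey")]))))
  current_int <- relabel_by_size(as.integer(current_int), names(assignment))
  colors <- assign_colors(current_int)
  col_assign <- stats::setNames(colors[as.character(current_int)], names(assignment))
  col_assign[current_int == 0L] <- "grey"
  ordered_colors <- unname(colors[as.character(seq_len(max(c(current_int, 0L))))])
  eig <- if (any(current_int > 0L)) {
    tmp <- stats::setNames(col_assign, names(assignment))
    e <- module_eigengenes(expr, tmp[tmp != "grey"])
    # order rows by module size order
    list(eigengenes = e$eigengenes[ordered_colors, , drop = FALSE],
         var_explained = e$var_explained[ordered_colors])
  } else {
    list(eigengenes = matrix(0, 0L, ncol(expr), dimnames = list(NULL, colnames(expr))),
         var_explained = numeric(0))
  }
  structure(list(assignment = col_assign, colors = ordered_colors,
                 eigengenes = eig$eigengenes, var_explained = eig$var_explained,
                 merge_log = merge_log, n_premerge = n_premerge),
            class = "module_partition")
}

#' Map module labels to stable color names
#'
#' Modules are ordered by descending size (ties: lexicographically smallest
#' member gene) and mapped onto a fixed palette of distinct color names;
#' label 0 stays "grey". Beyond the palette, names continue as
#' `module<k>`.
#'
#' @param assignment Named integer vector of module labels (0 = grey).
#' @return Named character vector: module label (as character) -> color.
#' @export
assign_colors <- function(assignment) {
  ids <- setdiff(sort(unique(assignment)), 0L)
  if (!length(ids)) return(stats::setNames(character(0), character(0)))
  sizes <- vapply(ids, function(i) sum(assignment == i), 0L)
  firsts <- if (!is.null(names(assignment))) {
    vapply(ids, function(i) min(names(assignment)[assignment == i]), "")
  } else as.character(ids)
  ord <- ids[order(-sizes, firsts)]
  pal <- module_palette()
  cols <- if (length(ord) <= length(pal)) pal[seq_along(ord)] else {
    c(pal, paste0("module", seq_len(length(ord) - length(pal)) + length(pal)))
  }
  stats::setNames(cols[match(ids, ord)], as.character(ids))
}

#' Fixed module color palette
#' @return Character vector of 60 distinct color names (never "grey").
#' @export
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
    "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
    "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
    "brown4", "bisque4", "darkslateblue", "plum2", "thistle2", "thistle1",
    "salmon4", "palevioletred3", "navajowhite2", "maroon", "lightpink4",
    "lavenderblush3", "honeydew1", "darkseagreen4", "coral1")
}

#' Detect, merge and color modules in one call
#'
#' @param expr Genes x samples expression matrix.
#' @param tree Coexpression dendrogram over the genes.
#' @param dist TOM distance matrix.
#' @inheritParams dynamic_tree_cut
#' @param merge_height Eigengene dissimilarity merge threshold (default 0.25).
#' @return A `module_partition` (see [merge_close_modules()]).
#' @export
detect_modules <- function(expr, tree, dist, min_cluster_size = 15L,
                           deep_split = 2L, pam_stage = TRUE,
                           fringe_frac = 0.15, max_pam_dist = NULL,
                           merge_height = 0.25) {
  raw <- dynamic_tree_cut(tree, dist, min_cluster_size = min_cluster_size,
                          deep_split = deep_split, pam_stage = pam_stage,
                          fringe_frac = fringe_frac,
                          max_pam_dist = max_pam_dist)
  expr <- expr[tree$labels, , drop = FALSE]
  merge_close_modules(expr, raw, merge_height = merge_height)
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", length(x$colors), " modules (",
      x$n_premerge, " pre-merge), ", sum(x$assignment == "grey"),
      " grey gene(s)\n", sep = "")
  invisible(x)
}
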