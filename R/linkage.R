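#' Complete-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with the complete-linkage rule (cluster-pair
#' distance = maximum pairwise dissimilarity). Merge ties are broken by the
#' lexicographically smallest pair of cluster representatives (a cluster is
#' represented by its smallest ROI index), so the result is fully
#' deterministic. Complete linkage is monotone, so merge heights never
#' decrease towards the root; this is asserted on every run.
#'
#' The result is `hclust`-compatible (plot, cutree and conversion methods
#' work) and additionally carries `members`, the leaf set of every internal
#' node, plus `au`/`bp` slots filled by [multiscale_bootstrap()].
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [to_dissimilarity()]),
#'   or a `dist` object.
#' @return An object of class `c("cmbhc_tree", "hclust")`.
#' @export
complete_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (any(!is.finite(d))) {
    bad <- sort(which(!is.finite(d), arr.ind = TRUE)[1, ])
    stop("non-finite dissimilarity between '", labels[bad[1]], "' and '",
         labels[bad[2]], "'")
  }
  if (max(abs(d - t(d))) > 0) stop("dissimilarity matrix is not symmetric")

  D <- d
  diag(D) <- Inf
  active <- seq_len(n)             # representative = smallest member index
  node <- -seq_len(n)              # hclust coding: -leaf or +merge step
  members <- c(as.list(seq_len(n)), vector("list", n - 1L))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members_out <- vector("list", n - 1L)

  for (s in seq_len(n - 1L)) {
    sub <- D[active, active, drop = FALSE]
    m <- min(sub)
    # all tied pairs at the minimum, pick lexicographically smallest reps
    w <- which(sub == m, arr.ind = TRUE)
    cand <- cbind(active[w[, 1]], active[w[, 2]])
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pick <- order(cand[, 1], cand[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    a <- node[i]; b <- node[j]
    merge[s, ] <- if (a < 0 && b < 0) sort(c(a, b), decreasing = TRUE)
                  else if (a < 0 || b < 0) c(min(a, b), max(a, b))
                  else sort(c(a, b))
    height[s] <- m
    members_out[[s]] <- sort(c(members[[i]], members[[j]]))
    members[[i]] <- members_out[[s]]
    node[i] <- s
    D[i, active] <- D[active, i] <- pmax(D[i, active], D[j, active])
    D[i, i] <- Inf
    active <- setdiff(active, j)
  }
  if (is.unsorted(height)) stop("internal error: non-monotone linkage heights")

  tree <- structure(
    list(merge = merge, height = height,
         order = tree_leaf_order(merge), labels = labels,
         members = members_out,
         au = rep(NA_real_, n - 1L), bp = rep(NA_real_, n - 1L),
         method = "complete", dist.method = "1-mCC",
         call = match.call()),
    class = c("cmbhc_tree", "hclust"))
  tree
}

# leaf order for crossing-free plotting, by recursive traversal
tree_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  rec <- function(k) {
    if (k < 0) return(-k)
    c(rec(merge[k, 1]), rec(merge[k, 2]))
  }
  rec(nrow(merge))
}

#' @export
print.cmbhc_tree <- function(x, ...) {
  cat(sprintf("Complete-linkage dendrogram: %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  if (any(is.finite(x$au)))
    cat(sprintf("  AU p-values %.2f-%.2f, BP %.2f-%.2f\n",
                min(x$au, na.rm = TRUE), max(x$au, na.rm = TRUE),
                min(x$bp, na.rm = TRUE), max(x$bp, na.rm = TRUE)))
  invisible(x)
}

#' Cut a dendrogram at a dissimilarity threshold
#'
#' Clusters are the maximal subtrees whose merge height is strictly below
#' the threshold and that contain at least two leaves; remaining leaves are
#' reported as singletons rather than forced into clusters.
#'
#' @param tree A [complete_linkage()] tree (or a fitted [cmbhc()] object).
#' @param threshold Dissimilarity cut (> 0); 0.4 identifies the clusters
#'   whose members all exceed 0.6 mutual mCC.
#' @return An object of class `cluster_assignment`: `clusters` (list of
#'   ROI-name vectors), `singletons`, `membership` (integer vector, 0 for
#'   singletons), `threshold`.
#' @export
cut_dendrogram <- function(tree, threshold = 0.4) UseMethod("cut_dendrogram")

#' @export
cut_dendrogram.cmbhc_tree <- function(tree, threshold = 0.4) {
  if (threshold <= 0) stop("threshold must be > 0")
  n <- length(tree$labels)
  group <- seq_len(n)
  node_group <- integer(nrow(tree$merge))   # group id of each merged node
  for (s in seq_len(nrow(tree$merge))) {
    if (tree$height[s] >= threshold) next
    kids <- tree$merge[s, ]
    gids <- vapply(kids, function(k) if (k < 0) group[-k] else node_group[k],
                   integer(1))
    keep <- min(gids)
    group[group %in% gids] <- keep
    node_group[s] <- keep
  }
  sizes <- table(group)
  cluster_ids <- as.integer(names(sizes)[sizes >= 2L])
  clusters <- lapply(cluster_ids, function(g) tree$labels[group == g])
  names(clusters) <- sprintf("C%d", seq_along(clusters))
  membership <- integer(n)
  for (k in seq_along(clusters))
    membership[group == cluster_ids[k]] <- k
  names(membership) <- tree$labels
  structure(list(clusters = clusters,
                 singletons = tree$labels[membership == 0L],
                 membership = membership,
                 threshold = threshold),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cut at dissimilarity %g: %d cluster(s), %d singleton(s)\n",
              x$threshold, length(x$clusters), length(x$singletons)))
  for (k in seq_along(x$clusters))
    cat(sprintf("  %s (n=%d): %s\n", names(x$clusters)[k],
                length(x$clusters[[k]]),
                paste(x$clusters[[k]], collapse = ", ")))
  if (length(x$singletons))
    cat("  singletons:", paste(x$singletons, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a dendrogram as nested JSON
#'
#' Nested objects `{left, right, height, au, bp}` with leaves
#' `{label, id}`; heights are on the dissimilarity scale.
#'
#' @param tree A [complete_linkage()] tree.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
dendrogram_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cmbhc_tree"))
  build <- function(k) {
    if (k < 0) return(list(label = tree$labels[-k], id = -k))
    list(left = build(tree$merge[k, 1]), right = build(tree$merge[k, 2]),
         height = tree$height[k], au = tree$au[k], bp = tree$bp[k])
  }
  js <- jsonlite::toJSON(build(nrow(tree$merge)), auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname dendrogram_to_json
#' @export
dendrogram_from_json <- function(path) {
  nd <- if (length(path) == 1L && file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else jsonlite::parse_json(path)
  leaves <- list(); merges <- list()
  walk <- function(node) {   # returns hclust code of this node
    if (!is.null(node$label)) {
      leaves[[length(leaves) + 1L]] <<- node
      return(-node$id)
    }
    l <- walk(node$left); r <- walk(node$right)
    merges[[length(merges) + 1L]] <<-
      list(l = l, r = r, height = node$height,
           au = node$au %||% NA_real_, bp = node$bp %||% NA_real_)
    length(merges)
  }
  walk(nd)
  n <- length(leaves)
  labels <- character(n)
  for (lf in leaves) labels[lf$id] <- lf$label
  # re-sort merges by height to restore the agglomeration order
  o <- order(vapply(merges, `[[`, numeric(1), "height"))
  remap <- integer(length(merges)); remap[o] <- seq_along(merges)
  fix <- function(k) if (k < 0) k else remap[k]
  merge <- matrix(0L, n - 1L, 2L)
  height <- au <- bp <- numeric(n - 1L)
  for (s in seq_along(o)) {
    mg <- merges[[o[s]]]
    pair <- c(fix(mg$l), fix(mg$r))
    merge[s, ] <- if (all(pair < 0)) sort(pair, decreasing = TRUE)
                  else if (any(pair < 0)) c(min(pair), max(pair))
                  else sort(pair)
    height[s] <- mg$height
    au[s] <- as.numeric(mg$au); bp[s] <- as.numeric(mg$bp)
  }
  members <- rebuild_members(merge)
  structure(list(merge = merge, height = height,
                 order = tree_leaf_order(merge), labels = labels,
                 members = members, au = au, bp = bp,
                 method = "complete", dist.method = "1-mCC",
                 call = match.call()),
            class = c("cmbhc_tree", "hclust"))
}

rebuild_members <- function(merge) {
  out <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    kids <- merge[s, ]
    out[[s]] <- sort(unlist(lapply(kids, function(k)
      if (k < 0) -k else out[[k]])))
  }
  out
}

#' Newick export / import with node heights
#'
#' Branch lengths encode the ultrametric height difference between parent
#' and child, so topology and merge heights survive the round trip (to
#' ~1e-12). AU/BP values are not representable in plain Newick.
#'
#' @param tree A [complete_linkage()] tree.
#' @param path Optional file path.
#' @return Newick string (writer); a [complete_linkage()]-compatible tree
#'   (reader).
#' @export
dendrogram_to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cmbhc_tree"))
  build <- function(k, parent_h) {
    if (k < 0)
      return(sprintf("%s:%.*g", gsub("[(),:;]", "_", tree$labels[-k]),
                     15, parent_h))
    sprintf("(%s,%s):%.*g",
            build(tree$merge[k, 1], tree$height[k]),
            build(tree$merge[k, 2], tree$height[k]),
            15, parent_h - tree$height[k])
  }
  root <- nrow(tree$merge)
  nwk <- sprintf("(%s,%s);", build(tree$merge[root, 1], tree$height[root]),
                 build(tree$merge[root, 2], tree$height[root]))
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}

#' @rdname dendrogram_to_newick
#' @export
dendrogram_from_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "")
         else path
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick input")
  hc <- ape::as.hclust.phylo(ape::multi2di(phy))
  # ape's hclust conversion uses the cophenetic convention (height =
  # leaf-to-leaf distance = twice the ultrametric node depth); our heights
  # are node depths on the dissimilarity scale
  hc$height <- hc$height / 2
  members <- rebuild_members(hc$merge)
  structure(list(merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels, members = members,
                 au = rep(NA_real_, length(hc$height)),
                 bp = rep(NA_real_, length(hc$height)),
                 method = "complete", dist.method = "1-mCC",
                 call = match.call()),
            class = c("cmbhc_tree", "hclust"))
}
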