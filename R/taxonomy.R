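#' Build and validate a rooted taxonomy tree
#'
#' @param nodes data frame with columns `id`, `parent`, `rank`, `name`
#'   (characters). The root marks itself by `parent == id` or `parent` being
#'   `NA`/empty. Cycles, orphan parents and multiple roots are rejected.
#' @return an object of class `taxonomy_tree`: `nodes` (with the root's
#'   parent normalised to `NA`), `depth` (named integer, root = 0) and
#'   `children` (named list).
#' @export
build_taxonomy <- function(nodes) {
  stopifnot(is.data.frame(nodes), all(c("id", "parent") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  if (is.null(nodes$rank)) nodes$rank <- NA_character_
  if (is.null(nodes$name)) nodes$name <- nodes$id
  if (anyDuplicated(nodes$id)) stop("duplicated node ids", call. = FALSE)
  root_mask <- is.na(nodes$parent) | nodes$parent == "" | nodes$parent == nodes$id
  if (sum(root_mask) != 1L)
    stop("taxonomy must have exactly one root (found ", sum(root_mask), ")",
         call. = FALSE)
  nodes$parent[root_mask] <- NA_character_
  missing_parent <- setdiff(nodes$parent[!root_mask], nodes$id)
  if (length(missing_parent) > 0L)
    stop("missing parent node(s): ", paste(missing_parent, collapse = ", "),
         call. = FALSE)
  # depth by walking to the root; a walk longer than n nodes means a cycle
  n <- nrow(nodes)
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  depth <- stats::setNames(rep(NA_integer_, n), nodes$id)
  for (id in nodes$id) {
    cur <- id; steps <- 0L
    while (!is.na(parent_of[[cur]])) {
      cur <- parent_of[[cur]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at node ", id, call. = FALSE)
    }
    depth[[id]] <- steps
  }
  children <- split(nodes$id[!root_mask], nodes$parent[!root_mask])
  structure(list(nodes = nodes, depth = depth, children = children,
                 root = nodes$id[root_mask]),
            class = "taxonomy_tree")
}

#' Read a taxonomy from a headered TSV
#'
#' @param path TSV with columns `id`, `parent`, `rank`, `name`.
#' @return a `taxonomy_tree`.
#' @export
read_taxonomy <- function(path) {
  build_taxonomy(utils::read.delim(path, colClasses = "character"))
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, root '%s', max depth %d\n",
              nrow(x$nodes), x$root, max(x$depth)))
  invisible(x)
}

#' Ancestor path of a node (self to root)
#'
#' @param tree a `taxonomy_tree`.
#' @param id node id.
#' @return character vector from the node itself up to the root.
#' @export
ancestors <- function(tree, id) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!id %in% tree$nodes$id) stop("node not in tree: ", id, call. = FALSE)
  parent_of <- stats::setNames(tree$nodes$parent, tree$nodes$id)
  path <- id
  while (!is.na(parent_of[[path[length(path)]]]))
    path <- c(path, parent_of[[path[length(path)]]])
  path
}

#' Lowest common ancestor of a node set
#'
#' Deepest node ancestral to (or equal to) all inputs; `lca` of a single node
#' is that node. Implemented by repeatedly lifting the deeper of two nodes to
#' equal depth and then walking both upward in lockstep.
#'
#' @param tree a `taxonomy_tree`.
#' @param ids non-empty character vector of node ids.
#' @return a single node id.
#' @export
lca <- function(tree, ids) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  ids <- unique(as.character(ids))
  if (length(ids) == 0L) stop("lca of an empty node set", call. = FALSE)
  bad <- setdiff(ids, tree$nodes$id)
  if (length(bad) > 0L) stop("node(s) not in tree: ", paste(bad, collapse = ", "),
                             call. = FALSE)
  parent_of <- stats::setNames(tree$nodes$parent, tree$nodes$id)
  pair <- function(a, b) {
    da <- tree$depth[[a]]; db <- tree$depth[[b]]
    while (da > db) { a <- parent_of[[a]]; da <- da - 1L }
    while (db > da) { b <- parent_of[[b]]; db <- db - 1L }
    while (a != b) { a <- parent_of[[a]]; b <- parent_of[[b]] }
    a
  }
  Reduce(pair, ids)
}
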