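# Outgroup rooting and tree path queries.
#
# Convention: a Newick tree is taken exactly as written -- a basal degree-2
# node is kept as a real node, never suppressed. root_with_outgroup() places
# a new root on the branch immediately separating the outgroup from the rest,
# splitting that branch 50/50. The midpoint choice is immaterial for the
# timing statistic: neither the a-b nor the b-tip paths cross the root's
# outgroup side.

# undirected adjacency list of a phylo tree:
# for each node, integer neighbours and branch lengths
tree_adjacency <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  len <- if (is.null(tree$edge.length)) rep(0, nrow(tree$edge)) else tree$edge.length
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    adj[[p]] <- rbind(adj[[p]], c(ch, len[[e]]))
    adj[[ch]] <- rbind(adj[[ch]], c(p, len[[e]]))
  }
  adj
}

node_name <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[[node]])
  if (is.null(tree$node.label)) "" else tree$node.label[[node - n]]
}

# tips reachable from `node` moving away from `from`
tips_beyond <- function(tree, adj, node, from) {
  n <- length(tree$tip.label)
  out <- character()
  stack <- list(c(node, from))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- cur[[1]]
    if (v <= n) out <- c(out, tree$tip.label[[v]])
    nb <- adj[[v]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        if (nb[r, 1] != cur[[2]]) stack[[length(stack) + 1L]] <- c(nb[r, 1], v)
      }
    }
  }
  out
}

#' Root a tree with an outgroup
#'
#' Places the root on the branch separating the outgroup tips from the
#' ingroup, splitting that branch length equally between the two root
#' children. The outgroup must be monophyletic in the unrooted tree.
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup_tips character vector of tip labels (non-empty proper
#'   subset of the tips).
#' @return a rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup_tips) {
  stopifnot(inherits(tree, "phylo"))
  og <- unique(as.character(outgroup_tips))
  if (!length(og)) stop("outgroup must be non-empty")
  unknown <- setdiff(og, tree$tip.label)
  if (length(unknown)) stop("unknown outgroup tip(s): ", paste(unknown, collapse = ", "))
  if (length(og) >= length(tree$tip.label)) {
    stop("outgroup must be a proper subset of the tips")
  }
  adj <- tree_adjacency(tree)
  # Candidate separating edges have exactly the outgroup on one side. A
  # retained degree-2 node can put several edges on the ingroup-outgroup
  # path; the separating branch proper is the one incident to the outgroup's
  # own subtree root, i.e. the candidate with the smallest outgroup side.
  edge_found <- NULL
  best_size <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    for (ori in list(c(p, ch), c(ch, p))) {
      side <- tips_beyond(tree, adj, ori[[2]], ori[[1]])
      if (setequal(side, og)) {
        size <- count_nodes_beyond(tree, adj, ori[[2]], ori[[1]])
        if (size < best_size) {
          best_size <- size
          edge_found <- ori
        }
      }
    }
  }
  if (is.null(edge_found)) {
    # name the intruders inside the smallest clade spanning the outgroup
    best <- tree$tip.label
    for (e in seq_len(nrow(tree$edge))) {
      for (ori in 1:2) {
        side <- tips_beyond(tree, adj, tree$edge[e, ori], tree$edge[e, 3 - ori])
        if (all(og %in% side) && length(side) < length(best)) best <- side
      }
    }
    stop("outgroup is not monophyletic; conflicting tip(s): ",
         paste(sort(setdiff(best, og)), collapse = ", "))
  }
  ingroup_node <- edge_found[[1]]
  og_node <- edge_found[[2]]
  elen <- branch_between(tree, adj, ingroup_node, og_node)
  fmt <- function(x) sprintf("%.17g", x)
  sub <- function(node, from) {
    nb <- adj[[node]]
    kids <- if (is.null(nb)) integer() else nb[nb[, 1] != from, 1]
    if (!length(kids)) return(node_name(tree, node))
    parts <- vapply(kids, function(k) {
      paste0(sub(k, node), ":", fmt(branch_between(tree, adj, node, k)))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", node_name(tree, node))
  }
  txt <- paste0("(", sub(ingroup_node, og_node), ":", fmt(elen / 2), ",",
                sub(og_node, ingroup_node), ":", fmt(elen / 2), ");")
  ape::read.tree(text = txt)
}

count_nodes_beyond <- function(tree, adj, node, from) {
  total <- 0L
  stack <- list(c(node, from))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    total <- total + 1L
    nb <- adj[[cur[[1]]]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        if (nb[r, 1] != cur[[2]]) {
          stack[[length(stack) + 1L]] <- c(nb[r, 1], cur[[1]])
        }
      }
    }
  }
  total
}

branch_between <- function(tree, adj, u, v) {
  nb <- adj[[u]]
  hit <- which(nb[, 1] == v)
  if (!length(hit)) stop("nodes not adjacent")
  nb[hit[[1]], 2]
}

resolve_node <- function(tree, x) {
  if (is.character(x)) {
    i <- match(x, tree$tip.label)
    if (is.na(i)) stop("unknown label '", x, "'")
    return(i)
  }
  i <- as.integer(x)
  if (i < 1 || i > length(tree$tip.label) + tree$Nnode) {
    stop("node id out of range: ", x)
  }
  i
}

#' Most recent common ancestor
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param tips tip labels (or node numbers); a single tip is its own MRCA.
#' @return the MRCA node number.
#' @export
mrca <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  ids <- vapply(tips, function(t) resolve_node(tree, t), integer(1))
  if (!length(ids)) stop("tips must be non-empty")
  if (length(unique(ids)) == 1) return(unname(ids[[1]]))
  ape::getMRCA(tree, unique(ids))
}

#' Path length between two nodes
#'
#' Sum of branch lengths along the unique path.
#'
#' @param tree an [ape::phylo] tree.
#' @param u,v tip labels or node numbers.
#' @export
path_length <- function(tree, u, v) {
  i <- resolve_node(tree, u)
  j <- resolve_node(tree, v)
  ape::dist.nodes(tree)[i, j]
}
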