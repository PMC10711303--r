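#' Parse a rooted species tree from newick
#'
#' Wraps `ape::read.tree()` with the validation this pipeline needs: a
#' single rooted tree with uniquely labelled leaves.  Internal nodes are
#' (re)labelled deterministically `N1, N2, ...` in postorder so that node
#' and branch identifiers are stable across runs; every branch is
#' identified by the label of its child node.
#'
#' @param text newick string (used when `file` is missing).
#' @param file path to a newick file.
#' @return an `ape::phylo` tree with populated `node.label`.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- tryCatch(
    if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stopf("newick parse error: %s", conditionMessage(e)))
  if (is.null(tree)) stopf("newick parse error: no tree found")
  if (inherits(tree, "multiPhylo")) stopf("expected a single tree")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate leaf label(s): %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  label_nodes(tree)
}

# deterministic internal-node labels by postorder traversal
label_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  internal_po <- unique(po$edge[, 1])     # parents in postorder completion
  labels <- character(tree$Nnode)
  labels[internal_po - length(tree$tip.label)] <-
    paste0("N", seq_along(internal_po))
  tree$node.label <- labels
  tree
}

node_labels <- function(tree) c(tree$tip.label, tree$node.label)

# children list indexed by node number
children_of <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

# logical: is `node` within the clade rooted at `anc` (inclusive)?
descendants_of <- function(tree, anc) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  in_clade <- logical(n_nodes)
  in_clade[anc] <- TRUE
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(edges))))   # preorder: parents before children
    if (in_clade[edges[i, 1]]) in_clade[edges[i, 2]] <- TRUE
  in_clade
}

#' Dollo (single-gain) gain/loss reconstruction on a rooted tree
#'
#' For every binary character, the gain is placed on the most recent common
#' ancestor of the species possessing it (the latest possible single
#' origin), the root state before the gain is 0, and losses are the minimal
#' set of branches — one per maximal all-absent subtree within the gain
#' clade — required to reproduce the leaf states.  A character present in
#' every species gains at the root and is read as ancestral.  An all-zero
#' character has no gain and no losses.  `mode = "fitch"` instead reports
#' the unconstrained parsimony change count per character (no gain/loss
#' polarization), for comparison.
#'
#' @param tree rooted tree from [parse_newick()] (leaf set must equal the
#'   matrix species).
#' @param matrix a `character_matrix` from [build_character_matrix()], or a
#'   binary species-x-component matrix with dimnames.
#' @param mode `"dollo"` (default) or `"fitch"`.
#' @return object of class `gain_loss_scenario`: data.frame `events`
#'   (`character`, `gain_node`, `n_losses`, `loss_branches`
#'   semicolon-joined), list `losses` (per character, branch = child-node
#'   labels), matrix `states` (nodes x characters ancestral states; Dollo
#'   mode only), `tree`, `mode`, and for Fitch mode `fitch_changes`.
#' @export
dollo_reconstruct <- function(tree, matrix, mode = c("dollo", "fitch")) {
  mode <- match.arg(mode)
  m <- if (inherits(matrix, "character_matrix")) matrix$state else matrix
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("character matrix needs species rownames and component colnames")
  if (!setequal(rownames(m), tree$tip.label))
    stopf("matrix species do not match tree leaves")
  if (!all(m %in% c(0L, 1L))) stopf("character matrix must be binary")
  if (is.null(tree$node.label) || !length(tree$node.label) ||
      any(!nzchar(tree$node.label)))
    tree <- label_nodes(tree)
  m <- m[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  labels <- node_labels(tree)
  po_edges <- ape::reorder.phylo(tree, "postorder")$edge

  if (mode == "fitch") {
    changes <- vapply(colnames(m), function(ch)
      fitch_changes(tree, setNames(m[, ch], rownames(m))), integer(1))
    ev <- data.frame(character = colnames(m), fitch_changes = changes,
                     stringsAsFactors = FALSE)
    return(structure(list(events = ev, tree = tree, mode = mode),
                     class = "gain_loss_scenario"))
  }

  states <- matrix(0L, n_nodes, ncol(m), dimnames = list(labels, colnames(m)))
  gains <- character(ncol(m))
  losses <- vector("list", ncol(m))
  names(losses) <- colnames(m)
  for (j in seq_len(ncol(m))) {
    tips1 <- which(m[, j] == 1L)
    if (length(tips1) == 0L) {
      gains[j] <- NA_character_
      losses[[j]] <- character(0)
      next
    }
    gain_node <- if (length(tips1) == 1L) tips1 else
      ape::getMRCA(tree, tips1)
    # has1: subtree below node contains a present leaf
    has1 <- logical(n_nodes)
    has1[tips1] <- TRUE
    for (i in seq_len(nrow(po_edges)))
      if (has1[po_edges[i, 2]]) has1[po_edges[i, 1]] <- TRUE
    in_clade <- descendants_of(tree, gain_node)
    st <- as.integer(in_clade & has1)
    states[, j] <- st
    # a loss branch leads from a state-1 parent to a state-0 child
    loss_children <- po_edges[st[po_edges[, 1]] == 1L &
                                st[po_edges[, 2]] == 0L, 2]
    gains[j] <- labels[gain_node]
    losses[[j]] <- sort(labels[loss_children])
  }
  ev <- data.frame(character = colnames(m), gain_node = gains,
                   n_losses = lengths(losses),
                   loss_branches = vapply(losses, paste, character(1),
                                          collapse = ";"),
                   stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  structure(list(events = ev, losses = losses, states = states,
                 tree = tree, mode = mode),
            class = "gain_loss_scenario")
}

#' @export
print.gain_loss_scenario <- function(x, ...) {
  if (x$mode == "fitch") {
    cat(sprintf("Fitch parsimony: %d characters, %d total changes\n",
                nrow(x$events), sum(x$events$fitch_changes)))
  } else {
    cat(sprintf("Dollo scenario: %d characters, %d gains, %d losses\n",
                nrow(x$events), sum(!is.na(x$events$gain_node)),
                sum(x$events$n_losses)))
  }
  invisible(x)
}

# binary Fitch parsimony change count (rooted, uniform cost)
fitch_changes <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  sets <- vector("list", n_nodes)
  for (i in seq_len(ntip)) sets[[i]] <- tip_states[[tree$tip.label[i]]]
  kids <- children_of(tree)
  changes <- 0L
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (node in po) {
    s <- NULL
    for (child in kids[[node]]) {
      if (is.null(s)) { s <- sets[[child]]; next }
      inter <- intersect(s, sets[[child]])
      if (length(inter)) s <- inter
      else { s <- union(s, sets[[child]]); changes <- changes + 1L }
    }
    sets[[node]] <- s
  }
  changes
}

#' Replay a gain/loss scenario down the tree
#'
#' Forward-simulates a single character: state switches to 1 at the gain
#' node and back to 0 on each loss branch, inherited otherwise.  Used to
#' verify that a reconstruction reproduces its input leaf states.
#'
#' @param tree labelled rooted tree.
#' @param gain_node node label (or `NA` for an all-absent character).
#' @param loss_branches child-node labels of loss branches.
#' @return named integer vector of leaf states.
#' @export
evolve_character <- function(tree, gain_node, loss_branches = character(0)) {
  if (is.null(tree$node.label) || !length(tree$node.label))
    tree <- label_nodes(tree)
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  st <- integer(length(labels))
  if (!is.na(gain_node)) {
    g <- match(gain_node, labels)
    if (is.na(g)) stopf("unknown gain node '%s'", gain_node)
    st[g] <- 1L
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    loss_idx <- match(loss_branches, labels)
    if (anyNA(loss_idx)) stopf("unknown loss branch label")
    for (i in rev(seq_len(nrow(edges)))) {  # preorder: parent before child
      parent <- edges[i, 1]; child <- edges[i, 2]
      if (child == g) next                  # gain overrides inheritance
      inherited <- st[parent]
      if (child %in% loss_idx) inherited <- 0L
      st[child] <- max(st[child], inherited)
    }
  }
  setNames(st[seq_len(ntip)], tree$tip.label)
}

#' Compare gain/loss histories under two tree topologies
#'
#' Runs [dollo_reconstruct()] on the same character matrix under two rooted
#' trees over the same species (for example the two published placements of
#' a conflicting clade) and tabulates per-character event counts and their
#' difference.
#'
#' @param matrix binary character matrix (or `character_matrix`).
#' @param tree_a,tree_b rooted trees with identical leaf sets.
#' @return object of class `topology_comparison`: data.frame `table` with
#'   columns `character`, `gains_a`, `losses_a`, `gains_b`, `losses_b`,
#'   `delta_events` (`a - b`), `changed`; plus both scenarios.
#' @export
compare_topologies <- function(matrix, tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stopf("trees have different leaf sets")
  sc_a <- dollo_reconstruct(tree_a, matrix)
  sc_b <- dollo_reconstruct(tree_b, matrix)
  ga <- as.integer(!is.na(sc_a$events$gain_node))
  gb <- as.integer(!is.na(sc_b$events$gain_node))
  tab <- data.frame(character = sc_a$events$character,
                    gains_a = ga, losses_a = sc_a$events$n_losses,
                    gains_b = gb, losses_b = sc_b$events$n_losses,
                    stringsAsFactors = FALSE)
  tab$delta_events <- (tab$gains_a + tab$losses_a) -
    (tab$gains_b + tab$losses_b)
  tab$changed <- tab$delta_events != 0L |
    sc_a$events$loss_branches != sc_b$events$loss_branches
  structure(list(table = tab, scenario_a = sc_a, scenario_b = sc_b),
            class = "topology_comparison")
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf("Topology comparison: %d/%d characters change history; total event delta %+d\n",
              sum(x$table$changed), nrow(x$table), sum(x$table$delta_events)))
  invisible(x)
}

#' Write per-branch events and per-node states of a Dollo scenario
#'
#' @param scenario a `gain_loss_scenario` (Dollo mode).
#' @param events_file TSV path for (character, branch, event) rows.
#' @param states_file optional TSV path for node ancestral states.
#' @return `events_file`, invisibly.
#' @export
write_scenario <- function(scenario, events_file, states_file = NULL) {
  stopifnot(inherits(scenario, "gain_loss_scenario"))
  ev <- scenario$events
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    if (!is.na(ev$gain_node[i]))
      rows[[length(rows) + 1L]] <-
        data.frame(character = ev$character[i], branch = ev$gain_node[i],
                   event = "gain", stringsAsFactors = FALSE)
    for (b in scenario$losses[[ev$character[i]]])
      rows[[length(rows) + 1L]] <-
        data.frame(character = ev$character[i], branch = b, event = "loss",
                   stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character = character(0), branch = character(0),
               event = character(0))
  write_tsv(out, events_file)
  if (!is.null(states_file)) {
    st <- data.frame(node = rownames(scenario$states), scenario$states,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(st, states_file)
  }
  invisible(events_file)
}
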