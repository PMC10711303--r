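# Independent oracles used by the unit and acceptance tests.  These stay
# deliberately naive (explicit loops, exhaustive enumeration) and never call
# the code paths they check.

# ---- confusion-matrix recount ------------------------------------------

# per-protein recount over the labelled set, straight from the category
# definitions; no_call = "negative" treats a missing prediction as negative
brute_confusion <- function(calls, labels, tool, no_call = "negative") {
  tp <- tn <- fp <- fn <- 0L
  tc <- calls[calls$tool_name == tool, , drop = FALSE]
  for (i in seq_len(nrow(labels))) {
    id <- labels$protein_id[i]
    row <- tc[tc$protein_id == id, , drop = FALSE]
    norm <- if (nrow(row) == 0L) "NO_CALL" else row$normalized_class[1]
    if (no_call == "exclude" && norm == "NO_CALL") next
    pos <- norm %in% c("MT", "PT_TO_MT")
    if (labels$truth[i] == "MRO") {
      if (pos) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pos) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_)
}

# random labelled-call scenario for recount checks; total labelled <= n_max
random_confusion_scenario <- function(n_max = 1000) {
  n <- sample.int(n_max, 1)
  ids <- sprintf("p%04d", seq_len(n))
  labels <- data.frame(protein_id = ids,
                       truth = sample(c("MRO", "NON_MRO"), n, TRUE),
                       provenance = "KNOWN_MRO", species = NA_character_,
                       stringsAsFactors = FALSE)
  scored <- runif(n) < 0.9
  calls <- data.frame(
    tool_name = "T1",
    protein_id = ids[scored],
    raw_class = "x",
    normalized_class = sample(c("MT", "PT_TO_MT", "NON_MT", "NO_CALL"),
                              sum(scored), TRUE,
                              prob = c(.3, .1, .5, .1)),
    score = NA_real_, stringsAsFactors = FALSE)
  list(calls = calls, labels = labels)
}

# ---- Dollo parsimony ----------------------------------------------------

# all rooted binary tree shapes with n leaves, as newick strings with
# leaves t1..tn (Wedderburn-Etherington enumeration).  Character
# enumeration over leaves makes leaf labelling immaterial, so these shapes
# cover every labelled rooted binary topology.
tree_shapes <- local({
  memo <- list()
  skeletons <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (n == 1L) "X" else {
      out <- character(0)
      for (a in seq_len(n %/% 2)) {
        s1s <- skeletons(a); s2s <- skeletons(n - a)
        for (s1 in s1s) for (s2 in s2s) {
          if (a == n - a && s1 > s2) next
          out <- c(out, paste0("(", s1, ",", s2, ")"))
        }
      }
      unique(out)
    }
    memo[[key]] <<- res
    res
  }
  function(n) {
    vapply(skeletons(n), function(s) {
      for (i in seq_len(n)) s <- sub("X", sprintf("t%d", i), s, fixed = TRUE)
      paste0(s, ";")
    }, character(1), USE.NAMES = FALSE)
  }
})

# exhaustive minimum-loss table under the single-gain constraint: for every
# leaf pattern of `tree`, enumerate ALL node labelings whose 1-region is a
# single connected clade fragment (exactly one maximal 1-node) and take the
# minimum loss count.  Returns min losses indexed by pattern id
# (sum over present leaves of 2^(leaf-1)); all-zero pattern has 0 events.
dollo_oracle_table <- function(tree) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  edges <- tree$edge
  A <- as.matrix(expand.grid(rep(list(0:1), n_nodes), KEEP.OUT.ATTRS = FALSE))
  root <- ntip + 1L
  starts <- A[, root]
  losses <- numeric(nrow(A))
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1]; child <- edges[i, 2]
    starts <- starts + A[, child] * (1 - A[, parent])
    losses <- losses + A[, parent] * (1 - A[, child])
  }
  valid <- starts == 1
  pattern <- as.integer(A[, seq_len(ntip), drop = FALSE] %*% 2^(0:(ntip - 1)))
  out <- rep(NA_integer_, 2^ntip)
  for (r in which(valid)) {
    p <- pattern[r] + 1L
    if (is.na(out[p]) || losses[r] < out[p]) out[p] <- as.integer(losses[r])
  }
  out[1] <- 0L   # all-absent: no gain, no losses
  out
}
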