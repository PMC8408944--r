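#' Build a lineage tree from an edge list
#'
#' Constructs a directed (multi-root) lineage tree of (stage, cell-state)
#' nodes from a parent/child edge list. Parents with exactly two children
#' are bifurcations and enter trio analysis; parents with more than two
#' children ("quadfurcations") are flagged and excluded from trios, but all
#' pairwise sibling combinations are listed separately so they can still be
#' used for binding-site enrichment.
#'
#' @param edges data.frame with columns `parent_state`, `child_state`, and
#'   `stage` (the stage of the child).
#' @param stages ordered character vector of all stages in developmental
#'   time, including the stage of the root states as its first applicable
#'   element. If `NULL`, the order of child stages is inferred from tree
#'   depth and `root_stage` must be given.
#' @param root_stage stage label for root states (states that never appear
#'   as a child). Defaults to `stages[1]` when `stages` is supplied.
#' @return An object of class `lineage_tree`: list with `nodes` (state,
#'   stage, stage_idx), `edges`, `stages`, `children`, `parent`,
#'   `bifurcations` (parent, sib1, sib2), `quadfurcations` (state vector),
#'   `quad_pairs` (pairwise sibling combinations inside quadfurcations),
#'   `roots`, and `terminal_stage`.
#' @export
build_lineage <- function(edges, stages = NULL, root_stage = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("parent_state", "child_state", "stage") %in% names(edges)))
  if (anyDuplicated(edges$child_state))
    stopf("state '%s' has more than one parent",
          edges$child_state[duplicated(edges$child_state)][1])
  children <- split(edges$child_state, edges$parent_state)
  parent <- setNames(edges$parent_state, edges$child_state)
  roots <- setdiff(edges$parent_state, edges$child_state)
  if (length(roots) == 0)
    stopf("lineage edge list contains a cycle (no root state)")

  # depth-first walk, also detects cycles
  depth <- c()
  walk <- function(state, d, seen) {
    if (state %in% seen)
      stopf("cycle detected at state '%s'", state)
    depth[state] <<- d
    for (ch in children[[state]] %||% character())
      walk(ch, d + 1L, c(seen, state))
  }
  for (r in roots) walk(r, 1L, character())
  if (!all(edges$child_state %in% names(depth)))
    stopf("cycle detected: unreachable edges involving '%s'",
          setdiff(edges$child_state, names(depth))[1])

  child_stage <- setNames(edges$stage, edges$child_state)
  if (is.null(stages)) {
    if (is.null(root_stage))
      stopf("stages or root_stage must be supplied")
    by_depth <- tapply(depth[names(child_stage)], child_stage, min)
    stages <- c(root_stage, names(sort(by_depth)))
  }
  if (is.null(root_stage)) root_stage <- stages[1]

  states <- unique(c(edges$parent_state, edges$child_state))
  node_stage <- ifelse(states %in% names(child_stage),
                       child_stage[states], root_stage)
  if (!all(node_stage %in% stages))
    stopf("stage '%s' not in the supplied stage order",
          setdiff(node_stage, stages)[1])
  stage_idx <- match(node_stage, stages)
  names(stage_idx) <- states

  # stage consistency: each child must sit exactly one stage after parent
  for (i in seq_len(nrow(edges))) {
    p <- edges$parent_state[i]; ch <- edges$child_state[i]
    if (stage_idx[ch] != stage_idx[p] + 1L)
      stopf("edge %s -> %s skips stages (%s -> %s)",
            p, ch, stages[stage_idx[p]], stages[stage_idx[ch]])
  }

  n_children <- lengths(children)
  bif_parents <- names(n_children)[n_children == 2L]
  quad_parents <- names(n_children)[n_children > 2L]
  bifurcations <- if (length(bif_parents)) {
    data.frame(parent = bif_parents,
               sib1 = vapply(children[bif_parents], `[`, "", 1L),
               sib2 = vapply(children[bif_parents], `[`, "", 2L),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(parent = character(), sib1 = character(),
               sib2 = character(), stringsAsFactors = FALSE)
  }
  quad_pairs <- do.call(rbind, lapply(quad_parents, function(p) {
    cmb <- combn(children[[p]], 2)
    data.frame(parent = p, sib1 = cmb[1, ], sib2 = cmb[2, ],
               stringsAsFactors = FALSE)
  })) %||% data.frame(parent = character(), sib1 = character(),
                      sib2 = character(), stringsAsFactors = FALSE)

  structure(list(
    nodes = data.frame(state = states, stage = node_stage,
                       stage_idx = unname(stage_idx),
                       stringsAsFactors = FALSE),
    edges = edges, stages = stages, children = children,
    parent = parent, bifurcations = bifurcations,
    quadfurcations = quad_parents, quad_pairs = quad_pairs,
    roots = roots, terminal_stage = stages[max(stage_idx)]
  ), class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf(
    "lineage_tree: %d states over %d stages; %d bifurcations, %d quadfurcations\n",
    nrow(x$nodes), length(x$stages), nrow(x$bifurcations),
    length(x$quadfurcations)))
  invisible(x)
}

#' Descendant states of a lineage node
#'
#' @param tree a [build_lineage()] tree.
#' @param state state label.
#' @param at_stage optional stage label; restrict to descendants at that
#'   stage (the state itself qualifies if it is at `at_stage`).
#' @param include_self include `state` itself (default TRUE).
#' @return Character vector of state labels.
#' @export
lineage_descendants <- function(tree, state, at_stage = NULL,
                                include_self = TRUE) {
  if (!state %in% tree$nodes$state)
    stopf("state '%s' not in lineage", state)
  out <- character(); stack <- state
  while (length(stack)) {
    s <- stack[[1]]; stack <- stack[-1]
    out <- c(out, s)
    stack <- c(stack, tree$children[[s]] %||% character())
  }
  if (!include_self) out <- setdiff(out, state)
  if (!is.null(at_stage)) {
    st <- setNames(tree$nodes$stage, tree$nodes$state)
    out <- out[st[out] == at_stage]
  }
  out
}
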