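#' Tree encoding of an RNA secondary structure
#'
#' Full expansion: every matched base pair becomes an internal `P` node
#' containing the region it encloses, every unpaired base a `U` leaf, and
#' all top-level elements hang under a virtual root `R`. Children follow
#' 5'->3' sequence order, so the encoding is bijective and the resulting
#' tree edit distance is sensitive to bulge and loop size changes.
#'
#' @param dotbracket balanced dot-bracket string (may be empty)
#' @return a `structure_tree`: list with postorder `labels` (character),
#'   `lml` (leftmost-leaf postorder index per node) and `n` (node count,
#'   including the root)
#' @export
dotbracket_to_tree <- function(dotbracket) {
  p <- parse_dotbracket(dotbracket)
  labels <- character(0); lml <- integer(0)
  # emit postorder for the forest covering 1-based positions lo..hi,
  # returning the lml of the first emitted node in the segment
  emit <- function(lo, hi) {
    first_leaf <- NA_integer_
    i <- lo
    while (i <= hi) {
      if (is.na(p[i])) {
        labels[[length(labels) + 1L]] <<- "U"
        lml[[length(lml) + 1L]] <<- length(labels)
        if (is.na(first_leaf)) first_leaf <- length(labels)
        i <- i + 1L
      } else {
        j <- p[i]
        sub_first <- emit(i + 1L, j - 1L)
        labels[[length(labels) + 1L]] <<- "P"
        me <- length(labels)
        lml[[length(lml) + 1L]] <<- if (is.na(sub_first)) me else sub_first
        if (is.na(first_leaf)) first_leaf <- lml[[me]]
        i <- j + 1L
      }
    }
    first_leaf
  }
  first <- emit(1L, length(p))
  labels <- c(labels, "R")
  lml <- c(lml, if (is.na(first)) length(labels) else first)
  structure(list(labels = labels, lml = as.integer(lml), n = length(labels)),
            class = "structure_tree")
}

#' @export
print.structure_tree <- function(x, ...) {
  cat("structure_tree with", x$n, "nodes (",
      sum(x$labels == "P"), "pairs,", sum(x$labels == "U"), "unpaired )\n")
  invisible(x)
}

label_codes <- c(U = 0L, P = 1L, R = 2L)

#' Ordered tree edit distance (Zhang-Shasha, unit costs)
#'
#' Minimum number of node insertions, deletions and relabelings that
#' transform one ordered labeled tree into the other. Symmetric; zero iff
#' the trees are isomorphic with equal labels. Inputs may be
#' `structure_tree` objects or dot-bracket strings.
#'
#' @param t1,t2 trees from [dotbracket_to_tree()] or dot-bracket strings
#' @return non-negative integer distance
#' @export
tree_edit_distance <- function(t1, t2) {
  if (is.character(t1)) t1 <- dotbracket_to_tree(t1)
  if (is.character(t2)) t2 <- dotbracket_to_tree(t2)
  .zs_tree_distance(unname(label_codes[t1$labels]), t1$lml,
                    unname(label_codes[t2$labels]), t2$lml)
}
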