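# Independent oracles and generators shared across the test files.

# --- brute-force ordered tree edit distance ------------------------------
# Trees/forests are encoded as strings: "." = unpaired leaf (U), "(...)" =
# pair node (P) around its children, "{...}" = the virtual root (R).
# Distance by the textbook forest recursion (delete / insert / match root
# of the last tree), memoized globally across calls. Independent of the
# package's Zhang-Shasha implementation.

.oracle_memo <- new.env(parent = emptyenv())

oracle_nodes <- function(f) {
  if (!nzchar(f)) return(0L)
  sum(strsplit(f, "")[[1]] %in% c(".", "(", "{"))
}

# split forest into (rest, label, children) at its last tree
oracle_split <- function(f) {
  ch <- strsplit(f, "")[[1]]
  n <- length(ch)
  last <- ch[n]
  if (last == ".") return(list(rest = substr(f, 1, n - 1), label = "U",
                               children = ""))
  close <- if (last == ")") ")" else "}"
  open <- if (last == ")") "(" else "{"
  depth <- 0L
  for (i in n:1) {
    if (ch[i] %in% c(")", "}")) depth <- depth + 1L
    if (ch[i] %in% c("(", "{")) depth <- depth - 1L
    if (depth == 0L) break
  }
  list(rest = substr(f, 1, i - 1),
       label = if (open == "(") "P" else "R",
       children = substr(f, i + 1, n - 1))
}

oracle_forest_dist <- function(f1, f2) {
  if (!nzchar(f1)) return(oracle_nodes(f2))
  if (!nzchar(f2)) return(oracle_nodes(f1))
  key <- paste0(f1, "|", f2)
  hit <- .oracle_memo[[key]]
  if (!is.null(hit)) return(hit)
  a <- oracle_split(f1); b <- oracle_split(f2)
  d <- min(
    oracle_forest_dist(paste0(a$rest, a$children), f2) + 1L,
    oracle_forest_dist(f1, paste0(b$rest, b$children)) + 1L,
    oracle_forest_dist(a$rest, b$rest) +
      oracle_forest_dist(a$children, b$children) +
      (a$label != b$label))
  .oracle_memo[[key]] <- d
  d
}

# distance between two dot-bracket structures, roots included
oracle_ted <- function(db1, db2) {
  oracle_forest_dist(paste0("{", db1, "}"), paste0("{", db2, "}"))
}

# --- enumeration and random generation of structures ---------------------

# all balanced dot-bracket strings of exactly n characters
enumerate_dotbrackets <- function(n) {
  if (n == 0L) return("")
  out <- character(0)
  for (rest in enumerate_dotbrackets(n - 1L))
    out <- c(out, paste0(".", rest))
  if (n >= 2L) {
    for (k in 0:(n - 2L)) {
      inner <- enumerate_dotbrackets(k)
      after <- enumerate_dotbrackets(n - 2L - k)
      out <- c(out, as.vector(outer(inner, after,
                                    function(i, a) paste0("(", i, ")", a))))
    }
  }
  unique(out)
}

# all structures whose tree encoding (incl. root) has <= max_nodes nodes,
# optionally restricted to strings of at most max_len characters
trees_up_to <- function(max_nodes, max_len = 2L * (max_nodes - 1L)) {
  out <- character(0)
  for (len in 0:max_len) {
    cand <- enumerate_dotbrackets(len)
    nodes <- vapply(cand, function(s) {
      ch <- strsplit(s, "")[[1]]
      sum(ch == ".") + sum(ch == "(") + 1L
    }, 0L)
    out <- c(out, cand[nodes <= max_nodes])
  }
  unique(out)
}

# random balanced dot-bracket with about `budget` non-root nodes
random_dotbracket <- function(budget) {
  if (budget <= 0L) return("")
  out <- ""
  while (budget > 0L) {
    if (stats::runif(1) < 0.5 || budget == 1L) {
      out <- paste0(out, ".")
      budget <- budget - 1L
    } else {
      inner <- sample.int(budget - 1L, 1L) - 1L
      out <- paste0(out, "(", random_dotbracket(inner), ")")
      budget <- budget - 1L - inner
    }
  }
  out
}

# --- brute-force region merging ------------------------------------------
# fixed point of pairwise merging: repeatedly fuse any two same-seq,
# same-strand intervals sharing >= 1 nt until stable
oracle_merge_intervals <- function(df) {
  rows <- split(df[, c("seqid", "start", "end", "strand")], seq_len(nrow(df)))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    n <- length(rows)
    for (i in seq_len(n)) {
      if (changed) break
      for (j in seq_len(n)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$seqid == b$seqid && a$strand == b$strand &&
            a$start < b$end && b$start < a$end) {
          rows[[i]]$start <- min(a$start, b$start)
          rows[[i]]$end <- max(a$end, b$end)
          rows[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$seqid, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# --- misc ----------------------------------------------------------------

dinucleotide_counts <- function(s) {
  n <- nchar(s)
  table(substring(s, 1:(n - 1L), 2:n))
}

# a random hit table for property tests
random_hits <- function(n, family = "famX", seqids = c("c1", "c2")) {
  start <- sample.int(500L, n, replace = TRUE)
  width <- sample(10:80, n, replace = TRUE)
  data.frame(seqid = sample(seqids, n, replace = TRUE),
             start = start, end = start + width,
             strand = sample(c("+", "-"), n, replace = TRUE),
             family_id = family, engine = "blast",
             evalue = 10^-sample(3:30, n, replace = TRUE),
             bitscore = stats::runif(n, 30, 200),
             hsp_length = width, coverage = stats::runif(n, 0.7, 1),
             stringsAsFactors = FALSE)
}
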