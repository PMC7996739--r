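.fold_cache <- new.env(parent = emptyenv())

#' Check that the configured folding engine is available
#'
#' The folding step delegates to an RNAfold-compatible command-line engine.
#' Call this at startup; a missing engine is a configuration error, not a
#' mid-run failure.
#' @param engine executable name (default "RNAfold")
#' @export
check_fold_engine <- function(engine = getOption("mirhom.fold_engine", "RNAfold")) {
  if (!nzchar(Sys.which(engine)))
    stop("folding engine '", engine, "' not found on PATH; ",
         "install ViennaRNA or set options(mirhom.fold_engine=)")
  invisible(engine)
}

#' Predict the minimum-free-energy secondary structure of an RNA
#'
#' Delegates to the RNAfold-compatible engine on PATH (sequence on stdin,
#' dot-bracket plus `( -12.30)` energy on stdout). Deterministic for a fixed
#' engine version; results are cached by sequence within the session. DNA
#' input (T) is transcribed to RNA (U) before folding.
#'
#' @param sequence RNA/DNA string, length >= 10
#' @return list with `dotbracket` (balanced string over `(`, `)`, `.`) and
#'   `mfe` (kcal/mol)
#' @export
fold_mfe <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 10L) stop("sequence too short to fold (< 10 nt)")
  rna <- gsub("T", "U", sequence, fixed = TRUE)
  hit <- .fold_cache[[rna]]
  if (!is.null(hit)) return(hit)
  engine <- check_fold_engine()
  out <- system2(engine, c("--noPS"), input = rna, stdout = TRUE)
  # last line: "(((...))) ( -12.30)"; mfe 0 prints as "( 0.00)"
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3)
    stop("could not parse folding engine output: ", line)
  res <- list(dotbracket = m[2], mfe = as.numeric(m[3]))
  if (nchar(res$dotbracket) != nchar(rna))
    stop("folding engine returned a structure of wrong length")
  parse_dotbracket(res$dotbracket)  # validates balance
  .fold_cache[[rna]] <- res
  res
}

#' Pair table of a dot-bracket string
#'
#' @param dotbracket balanced string over `(`, `)`, `.`
#' @return integer vector p with p[i] = 1-based partner of position i, or
#'   NA when unpaired
#' @export
parse_dotbracket <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  p <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced dot-bracket: unmatched ')' at position ", i)
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    } else if (ch[i] != ".")
      stop("invalid dot-bracket character '", ch[i], "' at position ", i)
  }
  if (length(stack))
    stop("unbalanced dot-bracket: unmatched '(' at position ", stack[length(stack)])
  p
}

#' Hairpin loops of a structure
#'
#' A hairpin loop is a maximal run of unpaired positions enclosed directly
#' by a base pair (i, j) with no pair in between.
#'
#' @param dotbracket dot-bracket string
#' @return data.frame with 0-based half-open columns `start`, `end` (the
#'   unpaired loop region) per hairpin loop, ordered 5'->3'
#' @export
hairpin_loops <- function(dotbracket) {
  p <- parse_dotbracket(dotbracket)
  n <- length(p)
  loops <- list()
  for (i in seq_len(n)) {
    j <- p[i]
    if (is.na(j) || j <= i) next
    if (j > i + 1L && all(is.na(p[(i + 1L):(j - 1L)])))
      loops[[length(loops) + 1L]] <- data.frame(start = i, end = j - 1L)
  }
  if (!length(loops)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, loops)
}
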