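# Internal sequence and coordinate helpers. DNA alphabet (A,C,G,T) is used
# throughout; conversion to RNA (U) happens only at the folding-engine boundary.

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[GC]", "", x)) # residual after removing G/C
  ifelse(n > 0L, (n - gc) / n, NA_real_)
}

dna2rna <- function(x) chartr("T", "U", x)
rna2dna <- function(x) chartr("U", "T", x)

seq_to_int <- function(x) {
  # A=1 C=2 G=3 T=4; anything else 0
  m <- match(strsplit(x, "", fixed = TRUE)[[1L]], BASES)
  m[is.na(m)] <- 0L
  m
}

#' Parse a dot-bracket structure into a pairing-partner map
#'
#' @param structure dot-bracket string (only `(`, `)`, `.` are interpreted).
#' @return integer vector; position `i` holds the 1-based partner of `i`,
#'   or `NA` if unpaired.
#' @keywords internal
pair_map <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  pmap <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket structure at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pmap[i] <- j
      pmap[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure: unmatched '('")
  pmap
}

# innermost base pairs (a, b): paired, b = partner(a) > a, and no paired
# position strictly between them. One per hairpin loop.
innermost_pairs <- function(pmap) {
  n <- length(pmap)
  out <- NULL
  for (a in seq_len(n)) {
    b <- pmap[a]
    if (is.na(b) || b <= a) next
    inside <- if (b - a > 1L) (a + 1L):(b - 1L) else integer(0)
    if (!length(inside) || all(is.na(pmap[inside]))) out <- rbind(out, c(a, b))
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2L)
  colnames(out) <- c("a", "b")
  out
}

# ungapped distance between two sequences allowing the shorter to slide
# inside the longer with terminal offsets; Inf if length difference exceeds
# max_len_diff. Used for homology matching and family clustering.
sliding_mismatch <- function(x, y, max_len_diff = 2L) {
  if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
  lx <- nchar(x); ly <- nchar(y)
  if (ly - lx > max_len_diff) return(Inf)
  xv <- strsplit(x, "", fixed = TRUE)[[1L]]
  yv <- strsplit(y, "", fixed = TRUE)[[1L]]
  best <- Inf
  for (off in 0:(ly - lx)) {
    mm <- sum(xv != yv[(off + 1L):(off + lx)])
    if (mm < best) best <- mm
  }
  best
}

# deterministic RNG scope: evaluates expr with a local seed without
# disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
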