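# Independent brute-force re-implementation of the target rules r1-r5,
# written position by position with explicit loops, as a cross-check oracle
# for the vectorized scanner.

oracle_state <- function(mb, sb) {
  wc <- list(A = "T", C = "G", G = "C", T = "A")
  if (identical(wc[[mb]], sb)) return("match")
  if ((mb == "G" && sb == "T") || (mb == "T" && sb == "G")) return("GU")
  "mismatch"
}

oracle_states <- function(mirna, site) {
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(site, "")[[1]]
  L <- length(m)
  out <- character(L)
  for (i in seq_len(L)) out[i] <- oracle_state(m[i], s[L + 1 - i])
  out
}

oracle_rules <- function(states, gu_strict = TRUE) {
  score <- 0
  for (st in states) score <- score + switch(st, match = 0, GU = 0.5, 1)
  nm <- logical(length(states))
  for (i in seq_along(states)) {
    nm[i] <- if (gu_strict) states[i] != "match" else states[i] == "mismatch"
  }
  run <- 0; maxrun <- 0
  for (i in seq_along(nm)) {
    run <- if (nm[i]) run + 1 else 0
    if (run > maxrun) maxrun <- run
  }
  adj <- FALSE
  for (i in 2:11) if (nm[i] && nm[i + 1]) adj <- TRUE
  seed <- 0
  for (i in 1:12) seed <- seed + switch(states[i], match = 0, GU = 0.5, 1)
  c(r1 = score <= 4, r2 = maxrun <= 2, r3 = !adj,
    r4 = !nm[10] && !nm[11], r5 = seed <= 2.5)
}

# all window starts in the transcript where r1-r5 pass
oracle_scan <- function(mirna, transcript, gu_strict = TRUE) {
  L <- nchar(mirna)
  starts <- integer(0)
  if (nchar(transcript) < L) return(starts)
  for (s in 1:(nchar(transcript) - L + 1)) {
    st <- oracle_states(mirna, substr(transcript, s, s + L - 1))
    if (all(oracle_rules(st, gu_strict))) starts <- c(starts, s)
  }
  starts
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate k positions of a sequence (same-base/mismatch style substitutions)
mutate_seq <- function(x, k) {
  v <- strsplit(x, "")[[1]]
  pos <- sample(seq_along(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}
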