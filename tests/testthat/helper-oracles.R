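# Independent brute-force oracles for the counting estimators: direct
# enumeration over single-nucleotide neighbors and mutational pathway
# orderings, written against the genetic code table only.

oracle_genetic_code <- function(code = "11") Biostrings::getGeneticCode(code)

oracle_sense_codons <- function(code = "11") {
  gc <- oracle_genetic_code(code)
  names(gc)[gc != "*"]
}

# synonymous/nonsynonymous site counts of one codon: per position, the
# synonymous fraction among single-nucleotide changes, stop targets
# excluded from the denominator
oracle_count_sites <- function(codon, code = "11") {
  gc <- oracle_genetic_code(code)
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    syn <- 0; tot <- 0
    for (nt in setdiff(nts, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- nt
      if (gc[[mut]] == "*") next
      tot <- tot + 1
      if (gc[[mut]] == gc[[codon]]) syn <- syn + 1
    }
    s <- s + syn / tot
  }
  c(s = s, n = 3 - s)
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons: enumerate every ordering of the differing positions, drop
# pathways through stop codons, average the rest
oracle_count_differences <- function(a, b, code = "11") {
  gc <- oracle_genetic_code(code)
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orderings <- switch(k,
    list(1L),
    list(1:2, 2:1),
    list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
         c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  sds <- numeric(0); nds <- numeric(0)
  for (ord in orderings) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (s in ord) {
      p <- pos[s]
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (length(sds) == 0L) return(c(sd = k / 2, nd = k / 2))
  c(sd = mean(sds), nd = mean(nds))
}
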