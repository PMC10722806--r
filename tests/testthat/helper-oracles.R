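# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force and separate from the package's
# own code paths.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# pure-R quadratic Needleman-Wunsch, score only (match +1, mismatch -1,
# gap -2); independent of the C++ implementation
r_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * gap
  S[1, ] <- (0:m) * gap
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (a[i] == b[j]) match else mismatch,
      S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  S[n + 1, m + 1]
}

# Biostrings global alignment as an external identity/score oracle
bs_global <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(score = Biostrings::score(aln),
       identity = sum(pa == sa & pa != "-") / length(pa))
}

# recursive descendant-tip enumeration, used to recompute branch abundances
# from scratch (oracle for UniFrac / qPD)
oracle_desc_tips <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_desc_tips, tree = tree))
}

oracle_wunifrac <- function(tree, pA, pB, normalized = TRUE) {
  pA <- pA / sum(pA); pB <- pB / sum(pB)
  raw <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- oracle_desc_tips(tree, tree$edge[e, 2])
    aA <- sum(pA[intersect(names(pA), tips)])
    aB <- sum(pB[intersect(names(pB), tips)])
    raw <- raw + tree$edge.length[e] * abs(aA - aB)
    den <- den + tree$edge.length[e] * (aA + aB)
  }
  if (normalized) raw / den else raw
}

# patristic distance by explicit root-path sums (oracle for MNTD)
oracle_patristic <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  path_to_root <- function(tip) {
    edges <- integer(0); node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(nt), path_to_root)
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    shared <- intersect(paths[[i]], paths[[j]])
    D[i, j] <- D[j, i] <-
      sum(tree$edge.length[setdiff(paths[[i]], shared)]) +
      sum(tree$edge.length[setdiff(paths[[j]], shared)])
  }
  D
}

oracle_mntd <- function(tree, tips) {
  D <- oracle_patristic(tree)[tips, tips]
  mean(vapply(seq_along(tips), function(i) min(D[i, -i]), numeric(1)))
}

random_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}

random_abundance <- function(labels, seed) {
  set.seed(seed)
  p <- stats::runif(length(labels))
  stats::setNames(p / sum(p), labels)
}

# a minimal read data frame for unit-level EM tests
make_reads <- function(bases, qual = 30L, pair = NULL, mate = NULL,
                       tag = "S1") {
  n <- length(bases)
  data.frame(id = sprintf("%s:%06d", tag, seq_len(n)),
             mate = if (is.null(mate)) rep(1L, n) else mate,
             sample_tag = tag, bases = bases,
             quals = I(lapply(nchar(bases), function(l)
               rep(as.integer(qual), l))),
             pair = if (is.null(pair)) seq_len(n) else pair,
             stringsAsFactors = FALSE)
}

# plant exactly n substitutions at distinct random positions
mutate_seq <- function(seq, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), n)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# plant n substitutions at interior, non-adjacent positions (>= min_gap apart,
# >= margin from the ends): keeps the variant's signal in substitution space,
# away from end-coverage effects and gap/mismatch alignment ambiguity
spaced_snp_variant <- function(seq, n, seed = NULL, min_gap = 3L,
                               margin = 10L) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(seq, "")[[1]]
  cand <- seq.int(margin + 1L, length(s) - margin)
  pos <- integer(0)
  while (length(pos) < n && length(cand)) {
    p <- sample(cand, 1L)
    pos <- c(pos, p)
    cand <- cand[abs(cand - p) >= min_gap]
  }
  stopifnot(length(pos) == n)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}
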