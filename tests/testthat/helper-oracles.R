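## Independent oracles: small, literal implementations kept deliberately
## separate from the package's code paths.

## --- exhaustive genotype-likelihood oracle -----------------------------
## Literal per-read products over the three genotypes, flat prior.
oracle_genotype <- function(n1, n2, eps) {
  l_hom1 <- prod(rep(1 - eps, n1)) * prod(rep(eps, n2))
  l_het <- prod(rep(0.5, n1 + n2))
  l_hom2 <- prod(rep(eps, n1)) * prod(rep(1 - eps, n2))
  l <- c(hom1 = l_hom1, het = l_het, hom2 = l_hom2)
  post <- l / sum(l)
  best <- which.max(post)
  list(genotype = names(l)[best], qual = -10 * log10(1 - post[best]))
}

## --- semi-global affine alignment oracle (Gotoh) -----------------------
## Query end gaps penalized; subject end gaps free. Gap of length L
## costs open + L * extend. N scores 0 against anything.
oracle_semiglobal <- function(pattern, subject, match = 1, mismatch = -1,
                              open = 2, extend = 1) {
  p <- chars(pattern); s <- chars(subject)
  m <- length(p); n <- length(s)
  sub <- function(a, b) {
    if (a == "N" || b == "N") 0 else if (a == b) match else mismatch
  }
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)  # ends in aligned pair
  X <- matrix(NEG, m + 1L, n + 1L)  # gap in subject (query base unmatched)
  Y <- matrix(NEG, m + 1L, n + 1L)  # gap in query (subject base unmatched)
  M[1L, ] <- 0                       # free leading subject gap
  for (i in 2L:(m + 1L)) X[i, 1L] <- -(open + (i - 1L) * extend)
  if (m >= 1L) {
    for (i in 2L:(m + 1L)) {
      for (j in seq_len(n + 1L)[-1L]) {
        sc <- sub(p[i - 1L], s[j - 1L])
        M[i, j] <- sc + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                            Y[i - 1L, j - 1L],
                            if (i == 2L) 0 else NEG)
        X[i, j] <- max(M[i - 1L, j] - open - extend,
                       X[i - 1L, j] - extend)
        Y[i, j] <- max(M[i, j - 1L] - open - extend,
                       Y[i, j - 1L] - extend)
      }
    }
  }
  ## free trailing subject gap: best over last row, M or X states
  best <- max(M[m + 1L, ], X[m + 1L, ])
  best
}

## --- brute-force phasing oracle ---------------------------------------
## Fragment observations recomputed directly from read substrings, then
## exhaustive search over phase configurations per block.
oracle_frag_obs <- function(reads, site_pos, allele1, allele2) {
  obs <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]
    e <- s + nchar(reads$seq[i]) - 1L
    v <- chars(reads$seq[i])
    codes <- integer(0)
    for (j in seq_along(site_pos)) {
      p <- site_pos[j]
      if (p < s || p > e) next
      b <- v[p - s + 1L]
      code <- if (b == allele1[j]) 1L else if (b == allele2[j]) 2L else 0L
      codes[as.character(j)] <- code
    }
    fid <- reads$frag_id[i]
    if (is.null(obs[[fid]])) obs[[fid]] <- codes
    else {
      both <- intersect(names(obs[[fid]]), names(codes))
      merged <- c(obs[[fid]], codes[setdiff(names(codes), names(obs[[fid]]))])
      for (b2 in both) if (obs[[fid]][b2] != codes[b2]) merged[b2] <- 0L
      obs[[fid]] <- merged
    }
  }
  obs
}

## adjacent-pair cis/trans counts from fragment observations
oracle_pair_counts <- function(obs, k) {
  cis <- integer(k - 1L); trans <- integer(k - 1L)
  for (codes in obs) {
    codes <- codes[codes != 0L]
    for (i in seq_len(k - 1L)) {
      a <- codes[as.character(i)]; b <- codes[as.character(i + 1L)]
      if (is.na(a) || is.na(b)) next
      if (a == b) cis[i] <- cis[i] + 1L else trans[i] <- trans[i] + 1L
    }
  }
  list(cis = cis, trans = trans)
}

## concordant-fragment count of a phase configuration (side vector over
## the sites of one block, 1 = haplotype A carries allele1 there)
oracle_concordance <- function(obs, block_sites, side) {
  names(side) <- as.character(block_sites)
  total <- 0L
  for (codes in obs) {
    codes <- codes[names(codes) %in% as.character(block_sites)]
    codes <- codes[codes != 0L]
    if (length(codes) == 0L) next
    sd <- side[names(codes)]
    hapA <- all(codes == sd)
    hapB <- all(codes == 3L - sd)
    if (hapA || hapB) total <- total + 1L
  }
  total
}

## full oracle: partition by PQ threshold, then exhaustive optimum per block
oracle_phase <- function(reads, site_pos, allele1, allele2,
                         pq_thresh = 10, eps = 0.01) {
  k <- length(site_pos)
  obs <- oracle_frag_obs(reads, site_pos, allele1, allele2)
  pc <- oracle_pair_counts(obs, k)
  pq <- 10 * abs(pc$cis - pc$trans) * log10((1 - eps) / eps)
  linked <- pq >= pq_thresh & (pc$cis + pc$trans) > 0L
  blocks <- list()
  bstart <- 1L
  for (i in seq_len(k)) {
    if (i < k && linked[i]) next
    sites <- bstart:i
    m <- length(sites)
    best_score <- -1L
    best_sides <- list()
    grid <- if (m == 1L) matrix(1L, 1L, 1L) else
      as.matrix(expand.grid(rep(list(1:2), m - 1L)))
    for (r in seq_len(nrow(grid))) {
      side <- c(1L, if (m > 1L) grid[r, ] else integer(0))
      sc <- oracle_concordance(obs, sites, side)
      if (sc > best_score) { best_score <- sc; best_sides <- list(side) }
      else if (sc == best_score) best_sides <- c(best_sides, list(side))
    }
    blocks[[length(blocks) + 1L]] <- list(sites = sites,
                                          best_score = best_score,
                                          best_sides = best_sides)
    bstart <- i + 1L
  }
  list(blocks = blocks, obs = obs, cis = pc$cis, trans = pc$trans, pq = pq)
}

## side vector of a package block (1 where hap0 carries allele1)
block_sides <- function(block, allele1_by_pos) {
  ifelse(block$hap0 == allele1_by_pos[as.character(block$sites$pos)], 1L, 2L)
}
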