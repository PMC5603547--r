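## Independent brute-force oracles used to validate the package's
## implementations on small inputs. Each is written directly from the
## defining formula, not from the code paths it checks.

## N50: try every observed length as a candidate, keep the largest whose
## covered bases reach half the total.
bf_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

## Benjamini-Hochberg step-up by the definition: q_(i) = min_{j>=i} p_(j)*m/j.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(1, ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

## Upper-tail hypergeometric p by exhaustive enumeration of all C(N, n)
## query subsets of a universe of size N with K marked elements.
bf_hyper <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # elements 1..K are the marked ones
  mean(hits >= k)
}

## Pearson r straight from the covariance/variance definition.
bf_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## Two-sided minimum-likelihood exact binomial test on a partition (a, b)
## of t = a + b with success probability pA, by full enumeration.
bf_binom_partition <- function(a, b, pA = 0.5) {
  t <- a + b
  pr <- dbinom(0:t, t, pA)
  sum(pr[pr <= pr[a + 1] * (1 + 1e-12)])
}

## Longest ORF by a literal positional walk: from every ATG occurrence on
## either strand, step forward codon by codon until the first stop.
bf_longest_orf <- function(seq) {
  seq <- toupper(seq)
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]),
              collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(seq, rc)) {
    n <- nchar(s)
    for (i in seq_len(max(0L, n - 2L))) {
      if (substring(s, i, i + 2) != "ATG") next
      j <- i
      aa <- 0L
      while (j + 2 <= n) {
        codon <- substring(s, j, j + 2)
        if (aa > 0L && codon %in% stops) {
          best <- max(best, aa)
          break
        }
        aa <- aa + 1L
        j <- j + 3L
      }
    }
  }
  best
}

## Small random count matrix with dimnames.
rand_counts <- function(n_genes, n_samples, lambda = 50) {
  matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}
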