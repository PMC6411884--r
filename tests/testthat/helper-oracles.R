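# Independent oracles used by the tests. These deliberately use the
# slowest, most literal formulation of each quantity.

# One-sided ("treatment greater") rank-sum permutation p by complete
# enumeration of all control/treatment partitions of the pooled values.
enumerate_ranksum_p <- function(control, treatment) {
  pooled <- c(control, treatment)
  n1 <- length(control)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[-seq_len(n1)])
  combs <- combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(ci) sum(rank(pooled)[-ci]))
  mean(w_all >= w_obs - 1e-12)
}

# Two-sided Fisher exact p by full hypergeometric enumeration with fixed
# margins; tables whose probability is at most the observed one (up to a
# relative tolerance guarding floating-point equality) are summed.
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Literal per-site recount of base frequencies from a read table.
recount_site <- function(reads, site) {
  hits <- character(0)
  for (r in seq_len(nrow(reads))) {
    off <- site - reads$start[r]
    if (off >= 0 && off < nchar(reads$seq[r])) {
      hits <- c(hits, substring(reads$seq[r], off + 1, off + 1))
    }
  }
  table(factor(hits, levels = c("A", "C", "G", "T", "N")))
}

# Minimal read-table constructor for hand-built fixtures.
make_reads <- function(seqs, starts, strands = NULL, quals = NULL,
                       rname = "ref") {
  n <- length(seqs)
  tibble::tibble(
    id = sprintf("r%02d", seq_len(n)),
    rname = rname,
    start = as.integer(starts),
    strand = strands %||% rep("+", n),
    seq = seqs,
    qual = quals %||% vapply(nchar(seqs),
                             function(l) strrep(rawToChar(as.raw(33 + 35)), l),
                             character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
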