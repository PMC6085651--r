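# Independent brute-force oracles used across test files. These deliberately
# avoid the code paths of the implementation (and, where possible, the same
# stats primitives).

# Two-sided Fisher p by full enumeration of all tables with the observed
# margins; point probabilities from explicit factorial products.
enumFisher <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d; n <- r1 + r2
    lfac <- lfactorial(0:max(n, 1))
    ptab <- function(x) {
        # P(table with [x, r1-x; c1-x, ...]) under fixed margins
        exp(lfac[r1 + 1] + lfac[r2 + 1] + lfac[c1 + 1] + lfac[c2 + 1] -
            lfac[n + 1] - lfac[x + 1] - lfac[r1 - x + 1] -
            lfac[c1 - x + 1] - lfac[d - a + x + 1])
    }
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- vapply(support, ptab, numeric(1))
    sum(probs[probs <= ptab(a) * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct products of small factors (exact to
# ~1e-13 relative for N <= 60), independent of phyper/dhyper.
enumHyperUpper <- function(N, K, n, k) {
    # P(X = x) = C(K,x) C(N-K,n-x) / C(N,n)
    ch <- function(n_, k_) {
        if (k_ < 0 || k_ > n_) return(0)
        prod((n_ - k_ + seq_len(k_)) / seq_len(k_))
    }
    xs <- k:min(K, n)
    sum(vapply(xs, function(x) ch(K, x) * ch(N - K, n - x), numeric(1))) /
        ch(N, n)
}

# Benjamini-Yekutieli by the direct step-up formula.
directBY <- function(p) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    q <- rep(NA_real_, m)
    sorted <- p[o]
    adj <- m * cm * sorted / seq_len(m)
    q[o] <- pmin(1, rev(cummin(rev(adj))))
    q
}

# Longest stop-free six-frame stretch via Biostrings translation + regex.
bruteLongestOrf <- function(seq) {
    best <- 0L
    d <- Biostrings::DNAString(seq)
    for (s in list(d, Biostrings::reverseComplement(d))) {
        for (f in 0:2) {
            L <- length(s) - f
            L <- L - L %% 3
            if (L < 3) next
            aa <- as.character(Biostrings::translate(
                Biostrings::subseq(s, f + 1, f + L)))
            runs <- nchar(strsplit(aa, "*", fixed = TRUE)[[1]])
            best <- max(best, runs)
        }
    }
    best
}

# RBH by a double loop over all query-subject pairs.
bruteRbh <- function(ab, ba) {
    bestOf <- function(df, q) {
        sub <- df[df$query == q, ]
        top <- sub[sub$bit_score == max(sub$bit_score), ]
        if (length(unique(top$subject)) == 1L) top$subject[1] else NA
    }
    pairs <- character(0)
    for (a in unique(ab$query)) {
        b <- bestOf(ab, a)
        if (is.na(b) || !b %in% ba$query) next
        if (identical(bestOf(ba, b), a))
            pairs <- c(pairs, paste(a, b, sep = "\t"))
    }
    sort(pairs)
}

# Ancestor closure by breadth-first walk on the raw edge list.
bfsAncestors <- function(term, edges) {
    out <- character(0)
    frontier <- term
    while (length(frontier)) {
        up <- unique(edges$parent[edges$child %in% frontier])
        up <- setdiff(up, out)
        out <- c(out, up)
        frontier <- up
    }
    out
}
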