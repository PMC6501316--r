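# Fixtures built in code; all randomness locally seeded.

randomScMatrix <- function(n, m, zeroFrac = 0, seed = 1) {
    set.seed(seed)
    v <- matrix(rexp(n * m, rate = 1 / 3), n, m)
    if (zeroFrac > 0)
        v[matrix(runif(n * m), n, m) < zeroFrac] <- 0
    ScMatrix(v)
}

# low-rank positive truth: sum of r positive rank-1 factors
rankKTruth <- function(n, m, r = 2, seed = 1) {
    set.seed(seed)
    M <- matrix(0, n, m)
    for (i in seq_len(r))
        M <- M + outer(rexp(n, 1 / (2 + i)), rexp(m, 1 / (2 + i)))
    M
}

frob <- function(A) sqrt(sum(A^2))
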