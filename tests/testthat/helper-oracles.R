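## Independent oracles used to cross-check the package's implementations.
## These deliberately share no code with the package internals.

## direct mixture log-likelihood (plain dnorm sum, no shared helpers)
oracleMixtureLogLik <- function(x, mean, sd, weight) {
    total <- rep(0, length(x))
    for (j in seq_along(mean))
        total <- total + weight[j] * exp(-(x - mean[j])^2 / (2 * sd[j]^2)) /
            (sqrt(2 * pi) * sd[j])
    sum(log(total))
}

## coarse grid search over two-component mixture parameters; returns the
## best log-likelihood found (a lower bound on the ML value)
oracleGridMixture <- function(x, means1, means2, sds, weights) {
    best <- -Inf
    for (m1 in means1) for (m2 in means2) for (s in sds) for (w in weights) {
        ll <- oracleMixtureLogLik(x, c(m1, m2), c(s, s), c(w, 1 - w))
        if (ll > best) best <- ll
    }
    best
}

## McGhee-von Hippel binding density via stats::uniroot on the original
## isotherm form nu/L = (1/kd)(1-n nu)((1-n nu)/(1-(n-1)nu))^(n-1)
oracleMvhTheta <- function(L, kd, n) {
    if (L == 0) return(0)
    f <- function(nu) {
        a <- 1 - n * nu
        b <- 1 - (n - 1) * nu
        nu / L - (1 / kd) * a * (a / b)^(n - 1)
    }
    nu <- uniroot(f, c(1e-300, 1 / n - 1e-14), tol = 1e-16)$root
    n * nu
}

## textbook Benjamini-Hochberg step-up on a small instance
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
    pmin(q, 1)[order(o)]
}

## brute-force membership enumeration for a three-set Venn partition
oracleVennCounts <- function(a, b, c) {
    u <- unique(c(a, b, c))
    key <- vapply(u, function(el)
        paste0(as.integer(el %in% a), as.integer(el %in% b),
               as.integer(el %in% c)), character(1))
    c(onlyA = sum(key == "100"), onlyB = sum(key == "010"),
      onlyC = sum(key == "001"), AB = sum(key == "110"),
      AC = sum(key == "101"), BC = sum(key == "011"),
      ABC = sum(key == "111"))
}
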