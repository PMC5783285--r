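## Shared fixture builders: everything is generated in code at test time.

## A tiny labelled DecoySet with hand-set features (no coordinates).
tinySet <- function(complexId = "cplx1",
                    labels = c("high", "incorrect", "incorrect"),
                    features = matrix(c(2, 1, 3, 9, 9, 9), ncol = 2,
                                      dimnames = list(NULL, c("f1", "f2"))),
                    initialRanks = seq_along(labels)) {
    DecoySet(complexId, features, labels, initialRanks = initialRanks)
}

## Minimal 2-column schema matching tinySet.
tinySchema <- function() FeatureSchema(c("f1", "f2"))

## A DecoySet with point-cloud coordinates at planted pose clusters.
## `centers`: k x 3 matrix; `members`: cluster index per decoy.
geomSet <- function(members, centers, spread = 0, nAtoms = 4L, seed = 1L,
                    labels = rep("incorrect", length(members))) {
    set.seed(seed)
    n <- length(members)
    lig0 <- matrix(rnorm(nAtoms * 3), ncol = 3)
    rec0 <- matrix(rnorm(18), ncol = 3)
    lig <- lapply(seq_len(n), function(i) {
        sweep(lig0, 2L, -centers[members[i], ]) +
            matrix(rnorm(3, sd = spread), nAtoms, 3, byrow = TRUE)
    })
    DecoySet("geom", matrix(0, n, 1, dimnames = list(NULL, "f1")),
             labels, receptorCoords = rep(list(rec0), n), ligandCoords = lig)
}

## Brute-force single-linkage oracle: repeated transitive closure over the
## threshold graph, independent of igraph.
bruteForceComponents <- function(d, cutoff) {
    n <- nrow(d)
    adj <- d <= cutoff
    diag(adj) <- TRUE
    reach <- adj
    repeat {
        nxt <- (reach %*% reach) > 0
        if (identical(nxt, reach > 0)) break
        reach <- nxt
    }
    comp <- integer(n)
    cid <- 0L
    for (i in seq_len(n)) {
        if (comp[i] == 0L) {
            cid <- cid + 1L
            comp[reach[i, ] > 0] <- cid
        }
    }
    comp
}

## Random symmetric distance matrix.
randomDistMatrix <- function(n, scale = 10) {
    m <- matrix(runif(n * n, 0, scale), n, n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    d
}

## Dense QP oracle for the ranking SVM via kernlab::ipop (dual box QP):
##   max 1'a - 0.5 a'Q a,  0 <= a <= C,  Q = X X'  (ridge for strict pd)
## Returns both a primal upper bound (true objective at w = X'a) and the dual
## lower bound (weak duality), which together sandwich the true optimum.
qpOracleObjective <- function(X, C) {
    n <- nrow(X)
    G <- X %*% t(X)
    Q <- G + diag(1e-6 * mean(diag(G)), n)   # relative ridge: strict pd
    ## vacuous constraint 0 <= sum(a) <= nC keeps ipop's KKT system regular
    fit <- kernlab::ipop(c = rep(-1, n), H = Q,
                         A = matrix(1, 1, n), b = 0, r = n * C,
                         l = rep(0, n), u = rep(C, n),
                         sigf = 7, maxiter = 400)
    a <- kernlab::primal(fit)
    w <- drop(t(X) %*% a)
    xi <- pmax(0, 1 - drop(X %*% w))
    list(upper = 0.5 * sum(w^2) + C * sum(xi),
         lower = sum(a) - 0.5 * drop(t(a) %*% (X %*% t(X)) %*% a))
}

## Exhaustive widest-path oracle: enumerate all simple paths a -> b.
bruteForceStrongestPaths <- function(w) {
    n <- nrow(w)
    out <- matrix(0, n, n)
    ## recursive enumeration of all simple paths, tracking max-min strength
    strongest <- function(a, b) {
        best <- -Inf
        rec <- function(node, strength, visited) {
            for (nxt in seq_len(n)) {
                if (nxt %in% visited) next
                s <- min(strength, w[node, nxt])
                if (nxt == b) {
                    if (s > best) best <<- s
                } else if (s > best) {  # prune: strength only decreases
                    rec(nxt, s, c(visited, nxt))
                }
            }
        }
        rec(a, Inf, c(a))
        best
    }
    for (a in seq_len(n)) for (b in seq_len(n)) if (a != b)
        out[a, b] <- strongest(a, b)
    out
}

## cosine similarity
cosineSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
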