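test_that("decoy tables parse, reject malformed input, and round-trip", {
    schema <- tinySchema()
    dir <- withr::local_tempdir()
    p <- file.path(dir, "toy.tsv")
    writeLines(c("decoy_id\tinitial_rank\tlabel\tf1\tf2",
                 "a\t1\thigh\t2\t9",
                 "b\t2\tincorrect\t1\t9",
                 "c\t3\tincorrect\t3\t9"), p)
    ds <- readDecoyTable(p, schema)
    expect_s4_class(ds, "DecoySet")
    expect_equal(nDecoys(ds), 3L)
    expect_equal(dim(features(ds)), c(3L, 2L))
    expect_equal(as.character(labels(ds)),
                 c("high", "incorrect", "incorrect"))

    ## one empty feature cell -> exactly one missing marker
    p2 <- file.path(dir, "miss.tsv")
    writeLines(c("decoy_id\tinitial_rank\tlabel\tf1\tf2",
                 "a\t1\thigh\t\t9",
                 "b\t2\tincorrect\t1\t9"), p2)
    ds2 <- readDecoyTable(p2, schema)
    expect_equal(sum(is.na(features(ds2))), 1L)

    ## duplicate decoy id -> error
    p3 <- file.path(dir, "dup.tsv")
    writeLines(c("decoy_id\tinitial_rank\tlabel\tf1\tf2",
                 "a\t1\thigh\t2\t9",
                 "a\t2\tincorrect\t1\t9"), p3)
    expect_error(readDecoyTable(p3, schema), "duplicate decoy_id")

    ## non-numeric feature cell -> error naming row and column
    p4 <- file.path(dir, "bad.tsv")
    writeLines(c("decoy_id\tinitial_rank\tlabel\tf1\tf2",
                 "a\t1\thigh\tx\t9"), p4)
    expect_error(readDecoyTable(p4, schema), "row 1, column f1")

    ## header mismatch -> error
    p5 <- file.path(dir, "hdr.tsv")
    writeLines(c("decoy_id\tinitial_rank\tlabel\tzz\tf2",
                 "a\t1\thigh\t1\t9"), p5)
    expect_error(readDecoyTable(p5, schema), "malformed header")

    ## write -> read round trip is exact (ids, features, labels, ranks)
    set.seed(8)
    orig <- tinySet(features = matrix(rnorm(6), 3, 2,
                    dimnames = list(NULL, c("f1", "f2"))),
                    initialRanks = c(2L, 3L, 1L))
    pp <- file.path(dir, "rt.tsv")
    writeDecoyTable(orig, pp)
    back <- readDecoyTable(pp, schema, complexId = complexId(orig))
    expect_identical(decoyIds(back), decoyIds(orig))
    expect_identical(initialRanks(back), initialRanks(orig))
    expect_identical(labels(back), labels(orig))
    expect_equal(features(back), features(orig), tolerance = 0)
})

test_that("labels are derived from fnat/lrmsd/irmsd when absent", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "metrics.tsv")
    writeLines(c("decoy_id\tinitial_rank\tfnat\tlrmsd\tirmsd\tf1\tf2",
                 "a\t1\t0.8\t0.5\t0.5\t1\t2",
                 "b\t2\t0.05\t2.0\t1.0\t1\t2",
                 "c\t3\t0.2\t8.0\t3.0\t1\t2"), p)
    ds <- readDecoyTable(p, tinySchema())
    expect_equal(as.character(labels(ds)), c("high", "incorrect", "acceptable"))
})

test_that("CAPRI categorisation matches the published criteria and is monotone", {
    expect_equal(as.character(capriCategorize(0.8, 0.5, 0.5)), "high")
    expect_equal(as.character(capriCategorize(0.05, 2, 1)), "incorrect")
    expect_equal(as.character(capriCategorize(0.2, 8, 3)), "acceptable")
    expect_error(capriCategorize(-0.1, 1, 1), "fnat")
    expect_error(capriCategorize(0.5, -1, 1), "non-negative")

    ## monotonicity: improving fnat / lowering RMSDs never lowers the category
    set.seed(42)
    for (i in 1:200) {
        fnat <- runif(1); l <- runif(1, 0, 15); ir <- runif(1, 0, 6)
        c1 <- capriCategorize(fnat, l, ir)
        c2 <- capriCategorize(min(1, fnat + runif(1, 0, 0.3)),
                              max(0, l - runif(1, 0, 5)),
                              max(0, ir - runif(1, 0, 2)))
        expect_true(c2 >= c1)
    }
})

test_that("imputation uses pooled column means and touches only missing cells", {
    f1 <- matrix(c(1, NA, 3, 5, 6, 7), ncol = 2,
                 dimnames = list(NULL, c("f1", "f2")))
    s1 <- tinySet(features = f1)
    out <- imputeMissing(list(s1))[[1]]
    expect_equal(features(out)[2, 1], 2)              # mean of 1 and 3
    expect_equal(features(out)[, 2], features(s1)[, 2])  # untouched

    ## mean pooled across complexes: [1,3] and [missing] -> 2
    a <- DecoySet("a", matrix(c(1, 3), 2, 1, dimnames = list(NULL, "f1")),
                  c("incorrect", "incorrect"))
    b <- DecoySet("b", matrix(NA_real_, 1, 1, dimnames = list(NULL, "f1")),
                  "incorrect")
    out2 <- imputeMissing(list(a, b))
    expect_equal(features(out2[[2]])[1, 1], 2)

    ## no missing values -> identity
    out3 <- imputeMissing(list(a))
    expect_identical(features(out3[[1]]), features(a))

    ## entirely missing column -> error
    cset <- DecoySet("c", matrix(NA_real_, 2, 1, dimnames = list(NULL, "f1")),
                     c("incorrect", "incorrect"))
    expect_error(imputeMissing(list(cset)), "entirely missing")
})

test_that("z-score normalization fits population parameters on the pool", {
    s <- DecoySet("a", matrix(c(0, 2, 5, 5), 2, 2,
                              dimnames = list(NULL, c("f1", "f2"))),
                  c("incorrect", "acceptable"))
    expect_warning(schema <- fitNormalizer(list(s), FeatureSchema(c("f1", "f2"))),
                   "constant")
    expect_equal(schema@means, c(1, 5))
    expect_equal(schema@sigmas, c(1, 0))     # population sigma of (0,2) is 1
    z <- applyNormalizer(s, schema)
    expect_equal(features(z)[, 1], c(-1, 1), ignore_attr = TRUE)
    expect_equal(features(z)[, 2], c(0, 0), ignore_attr = TRUE)  # sigma-0 col

    ## held-out sets are transformed with the TRAINING parameters
    h <- DecoySet("b", matrix(c(10, 20, 1, 2), 2, 2,
                              dimnames = list(NULL, c("f1", "f2"))),
                  c("incorrect", "incorrect"))
    zh <- applyNormalizer(h, schema)
    expect_equal(features(zh)[, 1], c(9, 19), ignore_attr = TRUE)

    expect_error(fitNormalizer(list(), FeatureSchema("f1")), "empty")
})

test_that("after fit+transform the training pool has mean 0 and sigma 1", {
    set.seed(21)
    sets <- lapply(1:3, function(k)
        DecoySet(paste0("c", k),
                 matrix(rnorm(40, mean = k, sd = k), 10, 4,
                        dimnames = list(NULL, paste0("f", 1:4))),
                 sample(capriLevels(), 10, replace = TRUE)))
    schema <- fitNormalizer(sets, FeatureSchema(paste0("f", 1:4)))
    pooled <- do.call(rbind, lapply(sets, function(s)
        features(applyNormalizer(s, schema))))
    expect_lt(max(abs(colMeans(pooled))), 1e-9)
    expect_lt(max(abs(sqrt(colMeans(sweep(pooled, 2, colMeans(pooled))^2)) - 1)),
              1e-9)
})

test_that("truncation keeps top-ranked decoys and reports near-native survival", {
    set.seed(3)
    n <- 600
    labs <- rep("incorrect", n)
    labs[n] <- "acceptable"   # near-native at some initial rank
    ranks <- sample(n)
    s <- DecoySet("big", matrix(rnorm(n), n, 1, dimnames = list(NULL, "f1")),
                  labs, initialRanks = ranks)
    tr <- truncateToTop(s, 500)
    expect_equal(nDecoys(tr), 500L)
    expect_true(all(initialRanks(s)[match(decoyIds(tr), decoyIds(s))] <= 500))

    ## all retained when fewer decoys than the limit
    small <- tinySet()
    expect_equal(nDecoys(truncateToTop(small, 500)), 3L)

    ## the lone near-native sits exactly at rank 501 -> flagged lost
    labs2 <- rep("incorrect", 501)
    labs2[501] <- "acceptable"
    s2 <- DecoySet("edge", matrix(0, 501, 1, dimnames = list(NULL, "f1")),
                   labs2, initialRanks = 1:501)
    tr2 <- truncateToTop(s2, 500)
    expect_false(tr2@metadata$nearNativeRetained)
    expect_error(truncateToTop(small, 0), "positive")
})

test_that("schema JSON round-trips with normalization parameters", {
    dir <- withr::local_tempdir()
    sc <- FeatureSchema(c("a", "b"), means = c(1.5, -2), sigmas = c(0.5, 3))
    p <- file.path(dir, "schema.json")
    writeSchema(sc, p)
    back <- readSchema(p)
    expect_identical(featureNames(back), featureNames(sc))
    expect_equal(back@means, sc@means)
    expect_equal(back@sigmas, sc@sigmas)
})

test_that("DecoySet validity enforces its invariants", {
    expect_error(DecoySet("x", matrix(0, 2, 1), c("incorrect", "incorrect"),
                          decoyIds = c("a", "a")), "unique")
    expect_error(DecoySet("x", matrix(0, 2, 1), c("incorrect", "incorrect"),
                          initialRanks = c(1L, 3L)), "permutation")
    expect_error(DecoySet("x", matrix(0, 2, 1), c("incorrect", "nonsense")),
                 "unknown CAPRI category")
})
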