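test_that("AAC matches the letter-count oracle and its invariants", {
    expect_equal(unname(encodeAAC(c(x = "AAAA"))[1, ]),
                 c(1, rep(0, 19)))
    expect_equal(unname(encodeAAC(c(x = "ACDE"))[1, ]),
                 c(rep(0.25, 4), rep(0, 16)))
    # worked-example peptide, component-by-component against the oracle
    aac <- encodeAAC(c(ACP_1 = SAMPLE_SEQ))[1, ]
    oracle <- aacOracle(SAMPLE_SEQ)
    expect_equal(unname(aac), unname(oracle), tolerance = 1e-15)
    expect_equal(unname(aac["AAC:K"]), 6 / 33)
    expect_equal(unname(aac["AAC:G"]), 4 / 33)
    # random sequences vs oracle; permutation invariance
    for (s in randomPeptides(20, seed = 41)) {
        expect_equal(unname(encodeAAC(c(a = s))[1, ]), unname(aacOracle(s)))
        shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
        expect_equal(encodeAAC(c(a = s))[1, ], encodeAAC(c(a = shuf))[1, ])
    }
})

test_that("DPC counts adjacent pairs over L-1 windows", {
    expect_equal(unname(encodeDPC(c(x = "AAA"))[1, "DPC:AA"]), 1)
    expect_equal(sum(encodeDPC(c(x = "AAA"))), 1)
    d <- encodeDPC(c(x = "ACAC"))[1, ]
    expect_equal(unname(d["DPC:AC"]), 2 / 3)
    expect_equal(unname(d["DPC:CA"]), 1 / 3)
    expect_equal(unname(encodeDPC(c(x = "AC"))[1, "DPC:AC"]), 1)
    expect_error(encodeDPC(c(tooShort = "A")), "tooShort")
    # random sequences against the sliding-window oracle
    for (s in randomPeptides(10, seed = 43)) {
        d <- encodeDPC(c(a = s))[1, ]
        ok <- kmerOracle(s, 2)
        expect_equal(unname(d[paste0("DPC:", names(ok))]),
                     unname(as.numeric(ok)))
        expect_equal(sum(d), 1, tolerance = 1e-12)
    }
})

test_that("TPC counts triples over L-2 windows", {
    expect_equal(unname(encodeTPC(c(x = "AAAA"))[1, "TPC:AAA"]), 1)
    t1 <- encodeTPC(c(x = "ACDACD"))[1, ]
    expect_equal(unname(t1["TPC:ACD"]), 2 / 4)
    expect_equal(unname(t1["TPC:CDA"]), 1 / 4)
    expect_equal(unname(t1["TPC:DAC"]), 1 / 4)
    # any L=3 sequence: exactly one component, equal to 1
    t2 <- encodeTPC(c(x = "WYK"))[1, ]
    expect_equal(sum(t2 > 0), 1)
    expect_equal(unname(t2["TPC:WYK"]), 1)
    expect_error(encodeTPC(c(shorty = "AC")), "shorty")
    for (s in randomPeptides(8, seed = 47)) {
        tv <- encodeTPC(c(a = s))[1, ]
        ok <- kmerOracle(s, 3)
        expect_equal(unname(tv[paste0("TPC:", names(ok))]),
                     unname(as.numeric(ok)))
        expect_equal(sum(tv), 1, tolerance = 1e-12)
    }
})

test_that("sequence correlation matches direct evaluation of I(.,.)", {
    pt <- defaultPropertyTable()
    # homopolymer: zero at any tier
    expect_equal(sequenceCorrelation("KKKK", 1), 0)
    expect_equal(sequenceCorrelation("KKKK", 3), 0)
    # hand evaluation for GK at tier 1: mean over 9 scales of (H_K - H_G)^2
    H <- propertyValues(pt)
    expect_equal(sequenceCorrelation("GK", 1),
                 mean((H["K", ] - H["G", ])^2))
    # reversal symmetry on random sequences, several tiers
    for (s in randomPeptides(6, minLen = 8, maxLen = 15, seed = 53)) {
        rev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
        for (n in c(1, 2, 3)) {
            expect_equal(sequenceCorrelation(s, n),
                         sequenceCorrelation(rev, n))
            expect_gte(sequenceCorrelation(s, n), 0)
        }
    }
    expect_error(sequenceCorrelation("GLWSK", 5), "tier")
    # literal tier mode keeps adjacent pairs, only the window shrinks
    s <- "GLWSKIKEVG"
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    n <- 3
    manual <- mean(vapply(seq_len(L - n), function(k)
        mean((H[ch[k + 1], ] - H[ch[k], ])^2), numeric(1)))
    expect_equal(sequenceCorrelation(s, n, tierMode = "literal"), manual)
})

test_that("IPseAAC is the normalized AAC + weighted correlation vector", {
    # homopolymer: composition concentrates, theta is zero
    v <- encodeIPseAAC(c(x = "AAAA"), lambda = 1)[1, ]
    expect_equal(unname(v["PSE:A"]), 1)
    expect_equal(unname(v["PSE:theta1"]), 0)
    # w = 0 reduces to AAC with zero correlation components
    v0 <- encodeIPseAAC(c(x = "GLWSKIKEVG"), lambda = 2, w = 0)[1, ]
    expect_equal(unname(v0[1:20]),
                 unname(encodeAAC(c(x = "GLWSKIKEVG"))[1, ]))
    expect_equal(unname(v0[21:22]), c(0, 0))
    # direct evaluation of the normalization for GLWSK, lambda 1, w 0.05
    s <- "GLWSK"
    f <- aacOracle(s)
    th <- sequenceCorrelation(s, 1)
    expected <- c(f, 0.05 * th) / (sum(f) + 0.05 * th)
    got <- encodeIPseAAC(c(x = s), lambda = 1, w = 0.05)[1, ]
    expect_equal(unname(got), unname(expected), tolerance = 1e-14)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
    expect_error(encodeIPseAAC(c(pp = "GLWSK"), lambda = 5), "pp")
})

test_that("encoder fusion concatenates in order with prefixed names", {
    ps <- generatePeptides(3, 3, lengthRange = c(10, 20), seed = 61)
    expect_identical(dim(encodeDataset(ps, "AAC")), c(6L, 20L))
    fm <- encodeDataset(ps, c("AAC", "DPC"))
    expect_identical(ncol(fm), 420L)
    expect_identical(colnames(fm)[1:20], paste0("AAC:", AA20))
    full <- encodeDataset(ps, c("AAC", "DPC", "TPC", "IPseAAC"), lambda = 1)
    expect_identical(ncol(full), 8441L)
    expect_identical(ncol(encodeDataset(ps, c("AAC", "DPC", "TPC",
                                              "IPseAAC"), lambda = 2)),
                     8442L)
    expect_identical(rownames(full), peptideIds(ps))
    expect_true(all(is.finite(full)))
    # order of encoders is respected
    swapped <- encodeDataset(ps, c("DPC", "AAC"))
    expect_identical(colnames(swapped)[1:400], colnames(fm)[21:420])
    expect_identical(colnames(swapped)[401:420], colnames(fm)[1:20])
    # length preconditions reported with offending ids
    bad <- peptideSet(c(ok = "GLWSKIKEVG", tiny = "GL"), name = "bad")
    expect_error(encodeDataset(bad, c("AAC", "TPC")), "tiny")
})

test_that("DPC, TPC and IPseAAC are order-sensitive (witness pair)", {
    a <- c(x = "ACDE")
    b <- c(x = "EDCA")  # same composition, different order
    expect_equal(encodeAAC(a)[1, ], encodeAAC(b)[1, ])
    expect_false(isTRUE(all.equal(encodeDPC(a)[1, ], encodeDPC(b)[1, ])))
    a2 <- c(x = "ACDEF"); b2 <- c(x = "FEDCA")
    expect_false(isTRUE(all.equal(encodeTPC(a2)[1, ], encodeTPC(b2)[1, ])))
    a3 <- c(x = "AKAKDD"); b3 <- c(x = "AAKKDD")
    expect_false(isTRUE(all.equal(
        encodeIPseAAC(a3, lambda = 1)[1, 21],
        encodeIPseAAC(b3, lambda = 1)[1, 21])))
})
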