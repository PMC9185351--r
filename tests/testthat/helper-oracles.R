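# Independent oracles and small fixtures used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# brute-force dynamic-programming count of maximal matches over all global
# alignments with match=1, mismatch=0, gap=0 (pure R, independent of src/)
lcsOracle <- function(a, b) {
    a <- strsplit(a, "")[[1]]
    b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    D <- matrix(0L, n + 1, m + 1)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        D[i + 1, j + 1] <- if (a[i] == b[j]) D[i, j] + 1L
                           else max(D[i, j + 1], D[i + 1, j])
    }
    D[n + 1, m + 1]
}

randomPeptides <- function(n, minLen = 10, maxLen = 50, seed = 1,
                           prefix = "pep") {
    set.seed(seed)
    lenPool <- seq.int(minLen, maxLen)
    lens <- lenPool[sample.int(length(lenPool), n, replace = TRUE)]
    seqs <- vapply(lens, function(L)
        paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
    names(seqs) <- paste0(prefix, seq_len(n))
    seqs
}

# letter-count oracle for amino acid composition
aacOracle <- function(s) {
    ch <- strsplit(s, "")[[1]]
    vapply(AA20, function(r) sum(ch == r), numeric(1)) / length(ch)
}

# sliding-window k-mer frequency oracle
kmerOracle <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    words <- vapply(seq_len(L - k + 1), function(i)
        paste(ch[i:(i + k - 1)], collapse = ""), character(1))
    tab <- table(words) / (L - k + 1)
    tab
}

# two well-separated Gaussian blobs for classifier sanity checks
makeBlobs <- function(n = 30, p = 4, sep = 3, seed = 1) {
    set.seed(seed)
    x <- rbind(matrix(rnorm(n * p, sep), n, p),
               matrix(rnorm(n * p, -sep), n, p))
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, y = factor(rep(c("ACP", "NACP"), each = n),
                           levels = c("ACP", "NACP")))
}

# reference peptide used in worked examples
SAMPLE_ID <- "ACP_1"
SAMPLE_SEQ <- "GLWSKIKEVGKEAAKAAAKAAGKAALGAVSEAV"

smallSvmArgs <- list(cRange = 2^c(-1, 1, 3), gammaRange = 2^c(-5, -3, -1))
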