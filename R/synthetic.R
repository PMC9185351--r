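#' Generate a two-class synthetic peptide dataset
#'
#' Emulates an ACP/NACP peptide collection with a single, interpretable
#' separation knob. NACP residues are drawn i.i.d. from a background
#' composition (uniform 1/20 by default); ACP residues from the same
#' background exponentially tilted toward a residue set enriched in real
#' anticancer peptides (cationic and hydrophobic residues
#' K, R, L, A, G, F, W), i.e. weights \eqn{\propto b_r e^{\beta[r \in S]}},
#' renormalized. \code{effectSize} \eqn{\beta = 0} makes the two classes
#' identically distributed (an exact null); larger values increase
#' compositional divergence. Lengths are uniform on \code{lengthRange}
#' (default 10–50 residues, the typical anticancer-peptide range).
#' Generation is deterministic for a fixed seed.
#'
#' @param nAcp,nNacp Class sizes (positive).
#' @param lengthRange Integer length interval, min >= 1.
#' @param effectSize Tilting strength \eqn{\beta \ge 0}.
#' @param seed Integer seed.
#' @param background Length-20 residue probability vector (A..Y order).
#' @param tiltSet Residues favoured in the ACP class.
#' @param name Dataset name.
#' @return A labelled [PeptideSet-class] with ids \code{ACP_i} /
#'   \code{NACP_i}.
#' @examples
#' ps <- generatePeptides(5, 5, effectSize = 2, seed = 7)
#' peptideLabels(ps)
#' @export
generatePeptides <- function(nAcp, nNacp, lengthRange = c(10, 50),
                             effectSize = 0, seed = 1,
                             background = rep(1 / 20, 20),
                             tiltSet = c("K", "R", "L", "A", "G", "F", "W"),
                             name = "synthetic") {
    stopifnot(nAcp > 0, nNacp > 0, effectSize >= 0,
              length(lengthRange) == 2, lengthRange[1] >= 1,
              lengthRange[1] <= lengthRange[2],
              length(background) == 20, all(background > 0),
              all(tiltSet %in% .AA20))
    background <- background / sum(background)
    tilt <- background * exp(effectSize * (.AA20 %in% tiltSet))
    tilt <- tilt / sum(tilt)
    withSeed(seed, {
        draw <- function(nSeq, prob, prefix) {
            lenPool <- seq.int(lengthRange[1], lengthRange[2])
            lens <- lenPool[sample.int(length(lenPool), nSeq,
                                       replace = TRUE)]
            seqs <- vapply(lens, function(L)
                paste(sample(.AA20, L, replace = TRUE, prob = prob),
                      collapse = ""), character(1))
            names(seqs) <- paste0(prefix, "_", seq_len(nSeq))
            seqs
        }
        acp <- draw(nAcp, tilt, "ACP")
        nacp <- draw(nNacp, background, "NACP")
        peptideSet(c(acp, nacp),
                   labels = rep(c("ACP", "NACP"), c(nAcp, nNacp)),
                   name = name)
    })
}

#' Generate datasets shaped like the two study collections
#'
#' Produces two synthetic datasets with the class structure of the
#' benchmark-scale collections this framework targets: 138 ACP + 206 NACP
#' (total 344) and 225 ACP + 2250 NACP (total 2475, the 1:10 imbalanced
#' case) — for end-to-end rehearsal of the pipeline at realistic scale.
#'
#' @param seed Integer seed.
#' @param effectSize Class divergence passed to [generatePeptides()]
#'   (default 1, a moderate, imperfectly separable signal).
#' @return \code{list(psd1 = , psd2 = )} of labelled [PeptideSet-class]s.
#' @export
generateBenchmarkShaped <- function(seed = 1, effectSize = 1) {
    list(psd1 = generatePeptides(138, 206, effectSize = effectSize,
                                 seed = seed, name = "PSD1"),
         psd2 = generatePeptides(225, 2250, effectSize = effectSize,
                                 seed = seed + 1L, name = "PSD2"))
}
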