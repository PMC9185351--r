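#' Physicochemical property table
#'
#' The improved pseudo amino acid composition correlates residues through
#' nine physicochemical scales: hydrophobicity, hydrophilicity, charge,
#' flexibility, irreplaceability, solvent-accessible surface area,
#' polarity, polarizability and rigidity. The package ships a versioned
#' table of standard literature scales
#' (\code{system.file("extdata", "aa_properties.tsv", package = "pepVote")});
#' each scale is standardized to mean 0 and population standard deviation 1
#' across the 20 residues, which makes the squared-difference correlation
#' function scale-free.
#'
#' @param path Path to a tab-separated table with a \code{residue} column
#'   and nine numeric property columns (lines starting with \code{#} are
#'   comments). Defaults to the shipped table.
#' @return A [PropertyTable-class].
#' @examples
#' pt <- defaultPropertyTable()
#' propertyNames(pt)
#' @export
loadPropertyTable <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "aa_properties.tsv",
                            package = "pepVote")
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot("residue" %in% colnames(tab))
    raw <- as.matrix(tab[, setdiff(colnames(tab), "residue")])
    rownames(raw) <- tab$residue
    raw <- raw[order(rownames(raw)), , drop = FALSE]
    if (!identical(rownames(raw), .AA20))
        stop("property table must cover exactly the 20 canonical residues")
    if (ncol(raw) != 9)
        stop("property table must have exactly 9 property columns")
    mu <- colMeans(raw)
    popSD <- sqrt(colMeans(sweep(raw, 2, mu)^2))
    if (any(popSD == 0)) stop("constant property scale")
    norm <- sweep(sweep(raw, 2, mu), 2, popSD, "/")
    new("PropertyTable", raw = raw, normalized = norm,
        version = basename(path))
}

#' @rdname loadPropertyTable
#' @export
defaultPropertyTable <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- loadPropertyTable()
        cache
    }
})

#' @rdname loadPropertyTable
#' @param x A \code{PropertyTable}.
#' @export
propertyNames <- function(x) colnames(x@raw)

#' @rdname loadPropertyTable
#' @param normalized Return the standardized values (default) or the raw
#'   literature values.
#' @export
propertyValues <- function(x, normalized = TRUE) {
    if (normalized) x@normalized else x@raw
}

#' @export
setMethod("show", "PropertyTable", function(object) {
    cat(sprintf("PropertyTable (%s): %d scales x 20 residues\n",
                object@version, ncol(object@raw)))
    cat("  ", paste(propertyNames(object), collapse = ", "), "\n")
    invisible(object)
})
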