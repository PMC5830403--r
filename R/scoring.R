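## Bespoke scoring utilities: GIS immunoreactivity score, tissue
## microarray polarity grading, logarithmised metastatic capacity, and
## the exact/association tests applied to them.

#' German immunohistochemical score (GIS) for MCAM expression
#'
#' The immuno-reactive score is the product of the positivity grade and
#' the average staining intensity. Positivity is graded 0 = negative,
#' 1 = up to 10\% positive cells, 2 = 11--50\%, 3 = 51--90\%, 4 = >90\%;
#' intensity is graded 0 (negative), 1 (weak) or 2 (moderate/strong).
#' A score of 4 or more is classed \code{"high"}, below 4 \code{"low"}.
#' Exactly 10\% still grades 1; the 11--50\% bracket starts strictly
#' above 10\%.
#'
#' @param percentPositive Percent positive cells in [0, 100]
#'   (vectorised).
#' @param intensity Staining intensity grade: 0, 1 or 2.
#' @return data.frame with columns \code{grade}, \code{score} (0--8) and
#'   \code{class} (\code{"high"}/\code{"low"}).
#' @examples
#' gisScore(60, 2)   # grade 3 x intensity 2 = 6, high
#' @export
gisScore <- function(percentPositive, intensity) {
    if (any(!is.finite(percentPositive)) ||
        any(percentPositive < 0 | percentPositive > 100))
        stop("percentPositive must lie in [0, 100]")
    if (!all(intensity %in% c(0, 1, 2)))
        stop("intensity grade must be 0, 1 or 2")
    grade <- ifelse(percentPositive == 0, 0L,
             ifelse(percentPositive <= 10, 1L,
             ifelse(percentPositive <= 50, 2L,
             ifelse(percentPositive <= 90, 3L, 4L))))
    score <- grade * intensity
    data.frame(grade = grade, score = score,
               class = factor(ifelse(score >= 4, "high", "low"),
                              levels = c("low", "high")))
}

#' Grade a tissue-microarray spot by its polarised-cell count
#'
#' Spots containing three or more polarised cells are graded polarised;
#' spots with 0--2 polarised cells are graded unpolarised.
#'
#' @param nPolarisedCells Non-negative integer count(s).
#' @return Factor with levels \code{"unpolarised"}, \code{"polarised"}.
#' @export
tmaGrade <- function(nPolarisedCells) {
    if (any(!is.finite(nPolarisedCells)) || any(nPolarisedCells < 0))
        stop("polarised-cell counts must be non-negative")
    factor(ifelse(nPolarisedCells >= 3, "polarised", "unpolarised"),
           levels = c("unpolarised", "polarised"))
}

#' Logarithmised metastatic capacity
#'
#' Tumour cells seeded in the lung normalised by circulating tumour cells
#' in the blood, on a log scale: \code{log_base(lung / blood)}. The scale
#' is invariant to common factors, so counts and percentages give the
#' same capacity. Entries with a non-positive numerator or denominator
#' are undefined and returned as NA with a warning.
#'
#' @param lungCells,bloodCTCs Positive counts (vectorised).
#' @param base Logarithm base (default 10; \code{exp(1)} for natural
#'   log -- correlations are identical either way).
#' @return Numeric vector of log capacities.
#' @export
metastaticCapacity <- function(lungCells, bloodCTCs, base = 10) {
    bad <- !is.finite(lungCells) | !is.finite(bloodCTCs) |
        lungCells <= 0 | bloodCTCs <= 0
    if (any(bad))
        warning(sprintf("%d observation(s) with non-positive counts excluded",
                        sum(bad)))
    out <- log(lungCells / bloodCTCs, base = base)
    out[bad] <- NA_real_
    out
}

.checkTable2x2 <- function(x) {
    x <- as.matrix(x)
    if (any(x < 0) || any(!is.finite(x)) || any(x != round(x)))
        stop("contingency table entries must be non-negative integers")
    x
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test of association: the p-value sums the
#' probabilities, under fixed margins, of all tables no more probable
#' than the observed one (two-sided default). Degenerate tables with an
#' empty margin carry no information and return p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"}.
#' @return The p-value.
#' @examples
#' fisherExact(matrix(c(5, 0, 0, 5), 2))
#' @export
fisherExact <- function(table, alternative = "two.sided") {
    x <- .checkTable2x2(table)
    if (!all(dim(x) == c(2, 2))) stop("table must be 2x2")
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
        message("degenerate margin: p = 1 by convention")
        return(1)
    }
    stats::fisher.test(x, alternative = alternative)$p.value
}

#' Pearson's chi-squared test of association for an r x c table
#'
#' Plain Pearson chi-squared statistic without continuity correction, as
#' used to compare expression frequencies between patient groups.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @return List with \code{statistic}, \code{df} and \code{p.value}.
#' @export
pearsonChisq <- function(table) {
    x <- .checkTable2x2(table)
    ht <- stats::chisq.test(x, correct = FALSE)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with non-zero
#'   variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("x and y must have equal length >= 3")
    if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance: correlation undefined")
    stats::cor(x, y)
}
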