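#' @include validation.R
NULL

#' Incurred-sample conformity of a measurement pair
#'
#' Percent difference between two methods' concentrations, relative to the
#' pair mean: `100 * (a - b) / ((a + b) / 2)`. The pair conforms when the
#' absolute percent difference is within `limitPct`. Both values zero makes
#' the difference undefined; the pair is flagged (`conform = NA`).
#'
#' @param a,b concentrations from the two methods (ng/mL); vectorized.
#' @param limitPct conformity limit (percent, default 20).
#' @return data.frame with `conc_method_a`, `conc_method_b`,
#'   `pct_difference`, `conform`.
#' @examples
#' conformity(100, 120)  # -18.18%, conform
#' @export
conformity <- function(a, b, limitPct = 20) {
    if (any(a < 0) || any(b < 0)) stop("concentrations must be >= 0")
    m <- (a + b) / 2
    pd <- ifelse(m > 0, 100 * (a - b) / m, NA_real_)
    data.frame(conc_method_a = a, conc_method_b = b, pct_difference = pd,
               conform = ifelse(is.na(pd), NA, abs(pd) <= limitPct))
}

#' Average technical duplicates per method before pairing
#'
#' @param df data.frame with `sample_id`, `conc_method_a`, `conc_method_b`.
#' @return data.frame with one row per sample id (method means).
#' @export
averageDuplicates <- function(df) {
    stats::aggregate(df[c("conc_method_a", "conc_method_b")],
                     by = list(sample_id = df$sample_id), mean)
}

#' Cross-validate two methods by the incurred-sample rule
#'
#' The cross-validation passes when at least `minFraction` of the pairs
#' conform (difference within `limitPct` of the pair mean). Undefined pairs
#' (both zero) are excluded from the fraction. A correlation summary
#' ([pearsonCorrelation()]) is attached when there are enough pairs.
#'
#' @param a,b paired concentrations from the two methods (ng/mL), technical
#'   duplicates already averaged per method.
#' @param limitPct conformity limit (percent).
#' @param minFraction minimum conforming fraction (default 0.67).
#' @param minN recommended minimum number of incurred samples; fewer draws
#'   a warning.
#' @return list with `n`, `n_conform`, `conforming_fraction`, `verdict`,
#'   `pairs` (the per-pair table), `r`, `p_value`.
#' @export
crossValidate <- function(a, b, limitPct = 20, minFraction = 0.67,
                          minN = 20L) {
    if (!length(a) || length(a) != length(b))
        stop("need non-empty paired concentration vectors")
    if (length(a) < minN)
        warning("fewer than ", minN, " incurred samples (n = ", length(a),
                ")")
    pairs <- conformity(a, b, limitPct)
    def <- !is.na(pairs$conform)
    frac <- sum(pairs$conform[def]) / sum(def)
    r <- p <- NA_real_
    if (sum(def) >= 3L && stats::sd(a) > 0 && stats::sd(b) > 0) {
        ct <- pearsonCorrelation(a, b)
        r <- ct$r; p <- ct$p_value
    }
    list(n = sum(def), n_conform = sum(pairs$conform[def]),
         conforming_fraction = frac, verdict = frac >= minFraction,
         pairs = pairs, r = r, p_value = p)
}

#' Pearson product-moment correlation of two methods
#'
#' r with the two-sided p-value from the t transform on n - 2 degrees of
#' freedom.
#'
#' @param a,b paired concentrations; n >= 3, non-zero variance in both.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearsonCorrelation <- function(a, b) {
    if (length(a) < 3L) stop("need at least 3 pairs")
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("zero variance in one of the methods")
    ct <- stats::cor.test(a, b, method = "pearson")
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
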