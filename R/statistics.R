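#' Build a rater score table
#'
#' Two expert raters score each case image on an ordinal staining
#' scale: the 3-point scale runs 0..3 (0 = no staining up to 3 =
#' staining in more than 70% of cells), the 4-point scale runs 0..4.
#'
#' @param case_id Character vector of case identifiers.
#' @param group_label Diagnostic group per case (see [field_record()]).
#' @param scale `"THREE_POINT"` or `"FOUR_POINT"`, recycled if scalar.
#' @param rater_a,rater_b Integer scores within the scale's range.
#' @return A data frame of class `rating_table`.
#' @export
rating_table <- function(case_id, group_label, scale, rater_a, rater_b) {
  n <- length(case_id)
  scale <- rep_len(as.character(scale), n)
  group_label <- rep_len(as.character(group_label), n)
  if (!all(scale %in% c("THREE_POINT", "FOUR_POINT"))) {
    stop("`scale` must be THREE_POINT or FOUR_POINT")
  }
  if (!all(group_label %in% GROUP_LABELS)) {
    stop("`group_label` must be one of: ",
         paste(GROUP_LABELS, collapse = ", "))
  }
  if (length(rater_a) != n || length(rater_b) != n) {
    stop("score vectors must match `case_id` in length")
  }
  if (anyNA(rater_a) || anyNA(rater_b)) stop("scores must not be missing")
  top <- ifelse(scale == "THREE_POINT", 3L, 4L)
  ok <- rater_a == floor(rater_a) & rater_b == floor(rater_b) &
    rater_a >= 0 & rater_b >= 0 & rater_a <= top & rater_b <= top
  if (!all(ok)) {
    stop("scores out of range for their scale at rows: ",
         paste(which(!ok), collapse = ", "))
  }
  out <- data.frame(case_id = as.character(case_id),
                    group_label = group_label, scale = scale,
                    rater_a = as.integer(rater_a),
                    rater_b = as.integer(rater_b),
                    stringsAsFactors = FALSE)
  class(out) <- c("rating_table", "data.frame")
  out
}

scale_categories <- function(scale) {
  if (scale == "THREE_POINT") 0:3 else 0:4
}

#' Weighted Cohen kappa for two raters
#'
#' Chance-corrected agreement with squared ("quadratic") disagreement
#' weights `w_ij = (i - j)^2`:
#' `kappa = 1 - sum(w * O) / sum(w * E)`, where `O` is the observed
#' joint proportion table and `E` the product of its marginals.  The
#' squared weights penalize a two-category disagreement four times as
#' heavily as an adjacent one, which matches how ordinal staining
#' scores are read in practice.
#'
#' The test statistic `z = kappa / SE0(kappa)` uses the large-sample
#' standard error of weighted kappa under the null hypothesis of
#' chance agreement (Fleiss, Cohen & Everitt, 1969), with a two-sided
#' normal p-value.
#'
#' @param table A [rating_table()] (subset to one scale, or pass
#'   `scale` to subset here).
#' @param scale Optional scale to subset to; required when `table`
#'   mixes scales.
#' @param weighting `"squared"` (default) or `"unweighted"` (all
#'   disagreements weighted equally, i.e. classical Cohen kappa).
#' @return A list of class `kappa_result` with `kappa`, `z`, `p`,
#'   `n_items`, `n_raters`, `interpretation` and `se0`.
#' @export
weighted_kappa <- function(table, scale = NULL,
                           weighting = c("squared", "unweighted")) {
  weighting <- match.arg(weighting)
  if (!inherits(table, "rating_table")) {
    stop("`table` must be a rating_table")
  }
  if (!is.null(scale)) table <- table[table$scale == scale, ]
  if (length(unique(table$scale)) > 1L) {
    stop("table mixes scales; pass `scale` to select one")
  }
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rated items")
  cats <- scale_categories(table$scale[1L])
  if (length(unique(c(table$rater_a, table$rater_b))) < 2L) {
    stop("kappa is undefined: raters jointly used fewer than 2 ",
         "distinct categories")
  }
  k <- length(cats)
  O <- table(factor(table$rater_a, levels = cats),
             factor(table$rater_b, levels = cats)) / n
  O <- unclass(O)
  pa <- rowSums(O)
  pb <- colSums(O)
  E <- outer(pa, pb)
  d <- outer(cats, cats, function(i, j) (i - j)^2)
  if (weighting == "unweighted") d <- (d > 0) * 1
  kappa <- 1 - sum(d * O) / sum(d * E)

  # Null-hypothesis SE (Fleiss-Cohen-Everitt), written with agreement
  # weights w = 1 - d / max(d); kappa is invariant to this affine
  # change of weights.
  w <- 1 - d / max(d)
  pe <- sum(w * E)
  wbar_i <- as.vector(w %*% pb)       # row means weighted by column marginals
  wbar_j <- as.vector(pa %*% w)       # column means weighted by row marginals
  cross <- outer(wbar_i, wbar_j, "+")
  var0 <- (sum(E * (w - cross)^2) - pe^2) / (n * (1 - pe)^2)
  se0 <- sqrt(var0)
  z <- kappa / se0
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(kappa = kappa, z = z, p = p, n_items = n, n_raters = 2L,
         interpretation = classify_agreement(kappa), se0 = se0,
         weighting = weighting),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Weighted kappa = %.3f (%s), z = %.3f, p = %.3g, n = %d\n",
              x$kappa, x$interpretation, x$z, x$p, x$n_items))
  invisible(x)
}

#' Verbal interpretation of a kappa coefficient
#'
#' Landis-Koch bands, closed at the upper end of each interval (a
#' kappa of exactly 0.60 is "Moderate Agreement").
#'
#' @param kappa Numeric vector, each value <= 1.
#' @return Character vector of band labels.
#' @examples
#' classify_agreement(c(0.672, 0.02))
#' @export
classify_agreement <- function(kappa) {
  if (any(kappa > 1)) stop("kappa cannot exceed 1")
  vapply(kappa, function(k) {
    if (k < 0) "Poor"
    else if (k <= 0.20) "Slight Agreement"
    else if (k <= 0.40) "Fair Agreement"
    else if (k <= 0.60) "Moderate Agreement"
    else if (k <= 0.80) "Substantial Agreement"
    else "Almost Perfect Agreement"
  }, character(1))
}

#' Concordance between two scores
#'
#' Two scores on the same scale are concordant iff they differ by less
#' than one point.  For integer scores this literal rule admits only
#' exact agreement; averaged or half-point scores can still be
#' concordant at a half-point difference.
#'
#' @param score_a,score_b Numeric vectors of equal length.
#' @return Character vector of `"CONCORDANT"` / `"DISCORDANT"`.
#' @export
concordance_classify <- function(score_a, score_b) {
  if (length(score_a) != length(score_b)) {
    stop("score vectors must have equal length")
  }
  ifelse(abs(score_a - score_b) < 1, "CONCORDANT", "DISCORDANT")
}

#' Chi-square comparison of discordance between two scales
#'
#' Pearson chi-square (no continuity correction) on the 2 x 2 table of
#' concordant/discordant counts for two scoring scales, answering
#' whether the scales show a similar degree of inter-rater discordance.
#'
#' @param counts_scale1,counts_scale2 Integer vectors
#'   `c(concordant, discordant)`.
#' @param correct Apply the Yates continuity correction (default
#'   `FALSE`).
#' @return Two-sided p-value.
#' @export
chi_square_discordance <- function(counts_scale1, counts_scale2,
                                   correct = FALSE) {
  m <- rbind(scale1 = as.numeric(counts_scale1),
             scale2 = as.numeric(counts_scale2))
  if (ncol(m) != 2L || any(m < 0)) {
    stop("each counts argument must be c(concordant, discordant) >= 0")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square is undefined: a table margin is zero")
  }
  suppressWarnings(stats::chisq.test(m, correct = correct))$p.value
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Fits a one-way ANOVA of a metric on diagnostic group and returns
#' Tukey honest-significant-difference adjusted p-values for every
#' group pair, based on the studentized range distribution
#' (Tukey-Kramer form for unbalanced group sizes).
#'
#' @param values Numeric vector of per-image metric values (images
#'   pooled within each group).
#' @param groups Factor or character vector of group labels, same
#'   length as `values`.
#' @param metric_name Optional label copied into the output.
#' @return A data frame of class `pairwise_comparisons` with columns
#'   `metric_name`, `group_a`, `group_b`, `diff`, `lwr`, `upr`,
#'   `p_adjusted`.
#' @export
anova_tukey <- function(values, groups, metric_name = "metric") {
  groups <- factor(groups)
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length")
  }
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(tabulate(groups) < 2L)) {
    stop("every group needs at least 2 values")
  }
  if (all(vapply(split(values, groups), stats::var, numeric(1)) == 0)) {
    stop("zero within-group variance in every group; ANOVA undefined")
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    metric_name = metric_name,
    group_a = vapply(pairs, `[`, character(1), 2L),
    group_b = vapply(pairs, `[`, character(1), 1L),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adjusted = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

#' Two-sample pooled-variance (homoscedastic) t-test
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df` and two-sided `p`.
#' @export
t_test_homoscedastic <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("zero pooled variance; t-test undefined")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Average the two raters' scores per case
#'
#' @param table A [rating_table()].
#' @return A data frame with one row per (case_id, scale): `case_id`,
#'   `group_label`, `scale`, `mean_score`.
#' @export
average_raters <- function(table) {
  if (!inherits(table, "rating_table")) {
    stop("`table` must be a rating_table")
  }
  out <- stats::aggregate(
    cbind(mean_score = (table$rater_a + table$rater_b) / 2),
    by = list(case_id = table$case_id, group_label = table$group_label,
              scale = table$scale),
    FUN = mean
  )
  out[order(out$scale, out$case_id), , drop = FALSE]
}
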