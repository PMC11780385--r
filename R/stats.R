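#' Round half away from zero
#'
#' Reported percentages use commercial rounding (0.5 rounds away from
#' zero), not banker's rounding; classification itself never rounds.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' 2x2 confusion table of response vs. surgical benefit
#'
#' Cross-tabulates binarized radiological response (positive = CR or PR)
#' against the surgical-benefit reference label. `tp` counts responders
#' with benefit, `fp` responders without benefit, `fn` non-responders with
#' benefit, `tn` non-responders without benefit.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return A `confusion_table` object.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("responder", "non-responder"),
                              c("benefit", "no benefit")))
  print(m)
  invisible(x)
}

#' Cross-tabulate predictions against labels
#'
#' @param response Logical vector, `TRUE` = radiological responder.
#' @param benefit Logical vector, `TRUE` = surgical benefit.
#' @return A [confusion_table()].
#' @export
tabulate_response <- function(response, benefit) {
  stopifnot(length(response) == length(benefit),
            !anyNA(response), !anyNA(benefit))
  confusion_table(tp = sum(response & benefit),
                  fp = sum(response & !benefit),
                  fn = sum(!response & benefit),
                  tn = sum(!response & !benefit))
}

#' Binarize a response status
#'
#' Maps the four-category status onto the binary scale the benefit labels
#' live on: CR and PR count as response.
#'
#' @param status CR/PR/SD/PD (factor or character, vectorised).
#' @return Logical vector.
#' @export
binarize_response <- function(status) {
  status <- as.character(status)
  if (any(!status %in% response_levels))
    stop("status must be CR, PR, SD or PD", call. = FALSE)
  status %in% c("CR", "PR")
}

#' Diagnostic performance of a confusion table
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)` (proportion of
#' surgical-benefit patients detected) and specificity `tn/(tn+fp)`, as
#' percentages. Published tables in this field sometimes label the latter
#' two in the opposite direction, so the transposed pair is also returned
#' (`sensitivity_transposed` = our specificity and vice versa).
#'
#' @param table A [confusion_table()] with `total > 0` and both
#'   denominators positive.
#' @param round Round to whole percent, half away from zero (default TRUE;
#'   the convention for reported values).
#' @return A list: `accuracy`, `sensitivity`, `specificity`,
#'   `sensitivity_transposed`, `specificity_transposed` (percent).
#' @export
performance <- function(table, round = TRUE) {
  stopifnot(inherits(table, "confusion_table"))
  total <- table$tp + table$fp + table$fn + table$tn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  if (table$tp + table$fn == 0)
    stop("sensitivity is undefined: no benefit patients", call. = FALSE)
  if (table$tn + table$fp == 0)
    stop("specificity is undefined: no non-benefit patients", call. = FALSE)
  sens <- 100 * table$tp / (table$tp + table$fn)
  spec <- 100 * table$tn / (table$tn + table$fp)
  out <- list(accuracy = 100 * (table$tp + table$tn) / total,
              sensitivity = sens, specificity = spec,
              sensitivity_transposed = spec, specificity_transposed = sens)
  if (round) out <- lapply(out, round_half_away)
  out
}

#' Reconstruct 2x2 tables from published marginals
#'
#' Publications often print only the marginals of a response-vs-benefit
#' cross-table (e.g. "22 of 39 patients benefited" and "18 PR") together
#' with rounded performance metrics. This enumerates every integer 2x2
#' table consistent with both marginals and keeps those satisfying the
#' supplied constraints, each either a structural condition on a cell
#' (e.g. `fp = 0`, which any printed 100 % metric forces) or a metric
#' equal to a printed whole-percent value under half-away-from-zero
#' rounding.
#'
#' @param benefit_marginals Integer pair `c(n_benefit, n_nonbenefit)`.
#' @param responder_marginals Integer pair
#'   `c(n_responders, n_nonresponders)`; totals must agree.
#' @param constraints A list; each element is `list(cell = "fp", value = 0)`
#'   or `list(metric = "sensitivity", value = 82)` with metric one of
#'   `accuracy`, `sensitivity`, `specificity`. Metric constraints use the
#'   benefit-detection orientation of [performance()].
#' @return A list of [confusion_table()] objects (possibly empty).
#' @export
reconstruct_table <- function(benefit_marginals, responder_marginals,
                              constraints = list()) {
  b <- as.integer(benefit_marginals); r <- as.integer(responder_marginals)
  stopifnot(length(b) == 2L, length(r) == 2L, all(b >= 0), all(r >= 0))
  if (sum(b) != sum(r))
    stop(sprintf("marginals disagree on the total: %d vs %d", sum(b), sum(r)),
         call. = FALSE)
  tp_range <- max(0L, r[1L] - b[2L]):min(r[1L], b[1L])
  tables <- lapply(tp_range, function(tp)
    confusion_table(tp = tp, fp = r[1L] - tp, fn = b[1L] - tp,
                    tn = b[2L] - r[1L] + tp))
  Filter(function(tab) all(vapply(constraints, satisfies_constraint,
                                  logical(1), tab = tab)),
         tables)
}

satisfies_constraint <- function(con, tab) {
  if (!is.null(con$cell)) return(tab[[con$cell]] == con$value)
  if (!is.null(con$metric)) {
    perf <- performance(tab, round = TRUE)
    return(perf[[con$metric]] == con$value)
  }
  stop("constraint must name a `cell` or a `metric`", call. = FALSE)
}

#' Cohen's kappa for interobserver agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two raters
#' labelling the same subjects, with expected agreement from the product of
#' the raters' marginal distributions. When both raters are constant and
#' identical (p_e = p_o = 1) agreement is perfect and 1 is returned.
#'
#' @param labels_a,labels_b Equal-length vectors (logical or categorical)
#'   of per-subject ratings, length >= 2.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("rating vectors differ in length", call. = FALSE)
  n <- length(labels_a)
  if (n < 2L) stop("need at least two rated subjects", call. = FALSE)
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_e >= 1) return(if (p_o >= 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Intraclass correlation, two-way random, absolute agreement, single rater
#'
#' ICC(2,1): both subjects and raters are treated as random samples and
#' systematic rater offsets count against agreement. Computed from the
#' two-way mean-squares decomposition
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`
#' raters.
#'
#' @param meas_a,meas_b Equal-length numeric vectors (length >= 3) of the
#'   two raters' measurements on the same subjects; not all identical.
#' @return The ICC estimate.
#' @export
icc_absolute_agreement <- function(meas_a, meas_b) {
  if (length(meas_a) != length(meas_b))
    stop("measurement vectors differ in length", call. = FALSE)
  n <- length(meas_a)
  if (n < 3L) stop("need at least three subjects", call. = FALSE)
  y <- cbind(meas_a, meas_b)
  if (stats::var(as.vector(y)) == 0)
    stop("measurements are constant; ICC is undefined", call. = FALSE)
  k <- 2L
  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small problems
#' (`n_x + n_y <= exact_limit`) the two-sided p-value is exact, from full
#' enumeration of all assignments of the pooled ranks to the two groups
#' (valid under ties); larger problems use the tie-corrected normal
#' approximation with continuity correction. `U` counts pairs where `x`
#' exceeds `y` (ties count one half).
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Largest pooled size for enumeration (default 12).
#' @return A list: `U`, `p_value`, `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_limit) {
    splits <- utils::combn(nx + ny, nx)
    u_all <- apply(splits, 2L, function(id)
      sum(ranks[id]) - nx * (nx + 1) / 2)
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
    return(list(U = u_obs, p_value = min(1, p), method = "exact"))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(ranks)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u_obs, p_value = 1, method = "normal"))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  list(U = u_obs, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Fisher's exact test (two-sided, point-probability method)
#'
#' Conditions on both marginals of a 2x2 table and sums the
#' hypergeometric probabilities of every table as or less probable than
#' the observed one.
#'
#' @param table A [confusion_table()] (or anything with `tp,fp,fn,tn`).
#' @return Two-sided p-value in (0, 1\].
#' @export
fisher_exact <- function(table) {
  m <- table$tp + table$fn      # benefit column total
  n2 <- table$fp + table$tn
  k <- table$tp + table$fp      # responder row total
  if (m + n2 == 0) stop("empty table", call. = FALSE)
  support <- max(0L, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(table$tp, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
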