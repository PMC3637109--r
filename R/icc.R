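#' Intraclass correlation coefficients for reliability studies
#'
#' Single-measure intraclass correlations from the two-way ANOVA
#' decomposition of a subjects x raters matrix (Shrout & Fleiss taxonomy):
#' \itemize{
#'   \item \code{"3,1"} — two-way mixed effects, consistency: invariant to
#'     per-rater additive shifts (used for intra-rater reliability).
#'   \item \code{"2,1"} — two-way random effects, absolute agreement:
#'     penalizes systematic rater offsets (used for inter-rater
#'     reliability).
#' }
#' With mean squares MSR (subjects), MSC (raters), MSE (residual), n
#' subjects and k raters:
#' \deqn{ICC(3,1) = (MSR - MSE) / (MSR + (k - 1) MSE)}
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)}
#'
#' @param ratings numeric matrix, subjects in rows (>= 2), raters in
#'   columns (>= 2), no missing cells.
#' @param model \code{"2,1"} or \code{"3,1"}.
#' @return the coefficient (a value in (-Inf, 1]).
#' @export
icc <- function(ratings, model = c("2,1", "3,1")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L || ncol(ratings) < 2L)
    stop("ratings matrix must be at least 2 subjects x 2 raters")
  if (anyNA(ratings)) stop("ratings matrix must have no missing cells")
  n <- nrow(ratings)
  k <- ncol(ratings)
  grand <- mean(ratings)
  rm <- rowMeans(ratings)
  cm <- colMeans(ratings)
  MSR <- k * sum((rm - grand)^2) / (n - 1)
  MSC <- n * sum((cm - grand)^2) / (k - 1)
  resid <- ratings - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- if (model == "3,1") MSR + (k - 1) * MSE
           else MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * max(1, abs(MSR)))
    stop("zero between-subject variance: ICC undefined")
  (MSR - MSE) / denom
}

#' Read a ratings matrix from CSV
#'
#' @param path CSV with one column per rater, one row per subject (numeric;
#'   an optional first column named \code{subject} is dropped).
#' @return numeric matrix.
#' @export
read_ratings <- function(path) {
  df <- read.csv(path)
  if (tolower(names(df)[1]) %in% c("subject", "id"))
    df <- df[, -1, drop = FALSE]
  as.matrix(df)
}
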