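#' Four-category rating matrix
#'
#' Cases x observers integer matrix of reader classifications in the four
#' categories used for staging reads: 1 = low diffuse uptake, no focal
#' lesion; 2 = low diffuse, focal lesion(s); 3 = high diffuse, no focal;
#' 4 = high diffuse, focal lesion(s).
#'
#' @param x Integer matrix (or data.frame) of ratings, one row per case,
#'   one column per observer; every entry in 1..4, no missing values.
#' @return An integer matrix of class `rating_matrix`.
#' @export
rating_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (anyNA(x)) stop("ratings must not contain missing values")
  if (!all(x %in% 1:4)) stop("ratings must be in categories 1..4")
  if (is.null(rownames(x))) rownames(x) <- paste0("case", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("obs", seq_len(ncol(x)))
  class(x) <- c("rating_matrix", class(x))
  x
}

#' Read a ratings CSV (one row per case, one column per observer)
#'
#' An optional leading `case` / `case_id` / `id` column is used for row
#' names; all remaining columns must hold categories 1..4.
#'
#' @param path CSV path.
#' @return A [rating_matrix()].
#' @export
read_ratings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  idcol <- match(c("case", "case_id", "id"), tolower(names(df)))
  idcol <- idcol[!is.na(idcol)][1]
  if (!is.na(idcol)) {
    rn <- as.character(df[[idcol]])
    df <- df[, -idcol, drop = FALSE]
    rownames(df) <- rn
  }
  rating_matrix(df)
}

#' Dichotomize four-category ratings
#'
#' The focal view calls categories 2 and 4 positive (focal lesion
#' present); the diffuse view calls categories 3 and 4 positive (high
#' diffuse uptake).
#'
#' @param r A [rating_matrix()] (or any array of categories 1..4).
#' @param view `"focal"` or `"diffuse"`.
#' @return Logical matrix of the same shape.
#' @export
dichotomize <- function(r, view = c("focal", "diffuse")) {
  view <- match.arg(view)
  pos <- if (view == "focal") c(2L, 4L) else c(3L, 4L)
  out <- array(unclass(r) %in% pos, dim(r))
  dimnames(out) <- dimnames(r)
  out
}

#' 2x2 contingency table of two dichotomous raters
#'
#' @param n11 Both No; `n12` rater A No / rater B Yes; `n21` A Yes / B No;
#'   `n22` both Yes.
#' @param n12,n21,n22 See `n11`.
#' @return An object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(35, 4, 6, 3)  # the lowest-agreement reader pair
#' @export
contingency_2x2 <- function(n11, n12, n21, n22) {
  counts <- c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("empty table")
  structure(as.list(counts), class = "contingency_2x2")
}

#' Build the 2x2 table of two logical rating vectors
#' @param a,b Equal-length logical vectors (one entry per case).
#' @return A [contingency_2x2()].
#' @export
table2x2 <- function(a, b) {
  if (length(a) != length(b)) stop("raters must rate the same cases")
  contingency_2x2(sum(!a & !b), sum(!a & b), sum(a & !b), sum(a & b))
}

#' Percentage agreement of a 2x2 table
#'
#' @param t A [contingency_2x2()].
#' @return Proportion of concordant cases, (n11 + n22) / total.
#' @examples
#' percent_agreement(contingency_2x2(35, 4, 6, 3))  # 38/48
#' @export
percent_agreement <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  (t$n11 + t$n22) / (t$n11 + t$n12 + t$n21 + t$n22)
}

#' Cohen's kappa of a 2x2 table
#'
#' Chance-corrected agreement kappa = (Po - Pe) / (1 - Pe), where Po is
#' the observed agreement and Pe the agreement expected from the two
#' raters' marginal rates. When both raters are constant and identical
#' (Pe = 1) kappa is undefined and `NA` is returned with a warning.
#'
#' @param t A [contingency_2x2()].
#' @return Kappa in \[-1, 1\], or `NA` when undefined.
#' @examples
#' cohens_kappa(contingency_2x2(35, 4, 6, 3))  # ~0.25
#' @export
cohens_kappa <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  n <- t$n11 + t$n12 + t$n21 + t$n22
  po <- (t$n11 + t$n22) / n
  pe <- ((t$n11 + t$n12) * (t$n11 + t$n21) +
         (t$n21 + t$n22) * (t$n12 + t$n22)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("kappa undefined: both raters constant and identical (Pe = 1)")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

# half-up rounding to match printed tables (R's round() is half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  trunc(x * p + sign(x) * 0.5) / p
}

#' Verbal interpretation band of a kappa value
#'
#' Standard guideline bands on the 2-decimal printed value: < 0 no
#' agreement, 0-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-1 almost perfect.
#'
#' @param kappa Numeric kappa value(s).
#' @return Character vector of band labels (`NA` for undefined kappa).
#' @export
kappa_interpretation <- function(kappa) {
  k <- round_half_up(kappa, 2)
  out <- rep(NA_character_, length(k))
  out[!is.na(k) & k < 0] <- "no agreement"
  out[!is.na(k) & k >= 0 & k <= 0.20] <- "slight"
  out[!is.na(k) & k >= 0.21 & k <= 0.40] <- "fair"
  out[!is.na(k) & k >= 0.41 & k <= 0.60] <- "moderate"
  out[!is.na(k) & k >= 0.61 & k <= 0.80] <- "substantial"
  out[!is.na(k) & k >= 0.81 & k <= 1] <- "almost perfect"
  out
}

#' Pairwise agreement grid over all observer pairs
#'
#' Builds, for every unordered pair of observers, the 2x2 table of the
#' dichotomized view and reports percentage agreement and Cohen's kappa,
#' with summary mean and range. Pairs with undefined kappa are flagged
#' and excluded from the kappa summaries.
#'
#' @param r A [rating_matrix()].
#' @param view `"focal"` or `"diffuse"`.
#' @return An object of class `pairwise_agreement`: list with `pairs`
#'   (data frame: obs_a, obs_b, pa, kappa), `mean_pa`, `range_pa`,
#'   `mean_kappa`, `range_kappa`, and `n_undefined_kappa`.
#' @export
pairwise_agreement <- function(r, view = c("focal", "diffuse")) {
  view <- match.arg(view)
  d <- dichotomize(r, view)
  if (ncol(d) < 2) stop("need at least 2 observers")
  idx <- combn(ncol(d), 2)
  rows <- apply(idx, 2, function(p) {
    t <- table2x2(d[, p[1]], d[, p[2]])
    k <- suppressWarnings(cohens_kappa(t))
    data.frame(obs_a = colnames(d)[p[1]], obs_b = colnames(d)[p[2]],
               pa = percent_agreement(t), kappa = k)
  })
  pairs <- do.call(rbind, rows)
  nun <- sum(is.na(pairs$kappa))
  if (nun > 0)
    warning(nun, " pair(s) with undefined kappa excluded from summaries")
  kap <- pairs$kappa[!is.na(pairs$kappa)]
  structure(list(
    view = view, pairs = pairs,
    mean_pa = mean(pairs$pa), range_pa = range(pairs$pa),
    mean_kappa = if (length(kap)) mean(kap) else NA_real_,
    range_kappa = if (length(kap)) range(kap) else c(NA_real_, NA_real_),
    n_undefined_kappa = nun
  ), class = "pairwise_agreement")
}

#' @export
print.pairwise_agreement <- function(x, ...) {
  cat(sprintf(
    "Pairwise agreement (%s view), %d pairs:\n  mean PA %.0f%% (range %.0f-%.0f%%)\n  mean kappa %.2f (range %.2f-%.2f)%s\n",
    x$view, nrow(x$pairs), 100 * x$mean_pa, 100 * x$range_pa[1],
    100 * x$range_pa[2], x$mean_kappa, x$range_kappa[1], x$range_kappa[2],
    if (x$n_undefined_kappa)
      sprintf("  [%d undefined]", x$n_undefined_kappa) else ""))
  invisible(x)
}

#' Per-case majority vote over observers
#'
#' A strict majority of the dichotomized votes decides; an exact split is
#' reported as a tie rather than resolved.
#'
#' @param r A [rating_matrix()].
#' @param view `"focal"` or `"diffuse"`.
#' @return Factor per case with levels `negative`, `positive`, `tie`.
#' @export
majority_vote <- function(r, view = c("focal", "diffuse")) {
  d <- dichotomize(r, match.arg(view))
  yes <- rowSums(d)
  n <- ncol(d)
  out <- ifelse(yes * 2 > n, "positive",
                ifelse(yes * 2 < n, "negative", "tie"))
  factor(setNames(out, rownames(d)),
         levels = c("negative", "positive", "tie"))
}

#' Agreement of consensus verdicts with a reference classifier
#'
#' Compares per-case majority verdicts with a reference (for instance the
#' automated focal calls), counting agreements, disagreements and ties
#' separately.
#'
#' @param verdicts Factor/character per case: `positive`, `negative` or
#'   `tie` (as from [majority_vote()]).
#' @param reference Logical per case (TRUE = positive).
#' @return List with `n_cases`, `n_agree`, `n_disagree`, `n_tie`,
#'   `proportion` (agreements over all cases) and `proportion_decided`
#'   (over non-tie cases; `NA` when every case is a tie).
#' @export
agreement_vs_reference <- function(verdicts, reference) {
  if (length(verdicts) != length(reference))
    stop("verdicts and reference must have equal length")
  v <- as.character(verdicts)
  tie <- v == "tie"
  agree <- !tie & ((v == "positive") == as.logical(reference))
  n <- length(v)
  nd <- sum(!tie)
  list(n_cases = n, n_agree = sum(agree),
       n_disagree = nd - sum(agree), n_tie = sum(tie),
       proportion = sum(agree) / n,
       proportion_decided = if (nd > 0) sum(agree) / nd else NA_real_)
}
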