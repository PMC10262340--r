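#' Rank-Sum importance weights for an expert panel
#'
#' Converts expert ranks (1 = most reliable) into normalised importance
#' weights for linear opinion pooling:
#' \deqn{\pi_j = \frac{J - \mathrm{Rank}_j + 1}{\sum_i (J - \mathrm{Rank}_i + 1)}}
#' for a panel of `J` experts. Ties are allowed and yield equal weights; the
#' weights always sum to one and a better (lower) rank never receives a
#' smaller weight. With eight experts of whom two are downgraded to rank 8 and
#' six kept at rank 1 this gives 0.02 for each downgraded expert and 0.16 for
#' each of the others.
#'
#' @param ranks integer vector of per-expert ranks, each in `1..J` where
#'   `J = length(ranks)`.
#' @return a list of class `"importance_weights"` with elements `pi`
#'   (normalised weights, named after `ranks` names if present) and `ranks`.
#' @examples
#' rank_sum_weights(c(1, 1, 1, 8, 8, 1, 1, 1))
#' rank_sum_weights(1:3)  # (0.5, 1/3, 1/6)
#' @export
rank_sum_weights <- function(ranks) {
  J <- length(ranks)
  if (J < 1L) stop("at least one rank required")
  if (any(!is.finite(ranks)) || any(ranks != round(ranks)))
    stop("ranks must be integers")
  if (any(ranks < 1) || any(ranks > J))
    stop("ranks must lie in 1..J (J = ", J, ")")
  score <- J - ranks + 1
  out <- list(pi = score / sum(score), ranks = as.integer(ranks))
  names(out$pi) <- names(ranks)
  class(out) <- "importance_weights"
  out
}

#' @export
print.importance_weights <- function(x, digits = 4, ...) {
  cat("Rank-Sum importance weights (J =", length(x$pi), "):\n")
  print(round(x$pi, digits))
  invisible(x)
}

#' Linear opinion pooling of expert relevance ratings
#'
#' Aggregates a panel's ratings into one pooled relevance weight per item as
#' the convex combination `sum_j pi_j * rating[j, item]`. Experts who did not
#' rate an item are dropped for that item and the importance weights
#' renormalised over those who did. Pooled weights of exactly zero would make
#' the hierarchical model's variances (`sigma^2 / w`) infinite, so they are
#' floored at `floor` with a warning.
#'
#' @param ratings numeric matrix, experts in rows, items in columns, entries
#'   in `[0, 1]`; `NA` marks a missing rating.
#' @param pi an [rank_sum_weights()] object, or a numeric vector of
#'   nonnegative importance weights summing to 1.
#' @param floor smallest pooled weight allowed to enter the model; set to 0
#'   to disable flooring.
#' @return named numeric vector of pooled weights, one per item (column),
#'   each in `[max(0, floor), 1]`.
#' @examples
#' r <- rbind(e1 = c(a = 0.2, b = 1), e2 = c(a = 0.8, b = 1))
#' pool_opinions(r, c(0.5, 0.5))  # a = 0.5, b = 1
#' @export
pool_opinions <- function(ratings, pi, floor = 0.01) {
  ratings <- as.matrix(ratings)
  if (inherits(pi, "importance_weights")) pi <- pi$pi
  if (length(pi) != nrow(ratings))
    stop("length of pi (", length(pi), ") must equal the number of experts (",
         nrow(ratings), ")")
  if (any(pi < 0)) stop("importance weights must be nonnegative")
  ok <- is.finite(ratings)
  if (any(ratings[ok] < 0 | ratings[ok] > 1))
    stop("ratings must lie in [0, 1]")
  rated <- colSums(ok * pi) > 0
  if (any(!rated)) {
    nm <- colnames(ratings)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(ratings)))
    stop("item(s) rated by no (positively weighted) expert: ",
         paste(nm[!rated], collapse = ", "))
  }
  r0 <- ratings
  r0[!ok] <- 0
  pooled <- colSums(r0 * pi) / colSums(ok * pi)
  if (floor > 0 && any(pooled < floor)) {
    warning("pooled weight(s) below ", floor, " floored before modelling")
    pooled <- pmax(pooled, floor)
  }
  pooled
}

#' Cronbach's alpha for an expert ratings matrix
#'
#' Internal-consistency reliability of the panel, treating experts as test
#' items and the rated studies/outcomes as cases:
#' \deqn{\alpha = \frac{J}{J-1}\Bigl(1 - \frac{\sum_j \mathrm{var}_j}
#'   {\mathrm{var}(\mathrm{total})}\Bigr).}
#' Values near 1 indicate proportional raters, values near 0 independent
#' ones. Rows (experts) with missing ratings trigger a complete-case
#' reduction over items, with a warning.
#'
#' @inheritParams pool_opinions
#' @return a single number `<= 1`.
#' @examples
#' r <- rbind(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
#' cronbach_alpha(r)  # identical raters: exactly 1
#' @export
cronbach_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  J <- nrow(ratings)
  if (J < 2L) stop("at least two experts required")
  if (anyNA(ratings)) {
    keep <- colSums(is.na(ratings)) == 0L
    warning("missing ratings: reducing to ", sum(keep), " complete item(s)")
    ratings <- ratings[, keep, drop = FALSE]
  }
  if (ncol(ratings) < 2L) stop("at least two (complete) items required")
  var_j <- apply(ratings, 1L, stats::var)
  var_total <- stats::var(colSums(ratings))
  if (var_total == 0)
    stop("total score has zero variance: Cronbach's alpha is undefined")
  J / (J - 1) * (1 - sum(var_j) / var_total)
}

#' Inter-rater correlations and per-item rating spread
#'
#' Pairwise Pearson correlations between experts across items (the
#' reliability-analysis "inter-item" matrix with experts as items), together
#' with the five-number summary of the panel's ratings for each item — the
#' boxplot view of how widely experts disagree about each study's relevance.
#' A constant rater has no defined correlation with anyone; those entries are
#' `NA` with a warning.
#'
#' @inheritParams pool_opinions
#' @return list of class `"interrater"` with elements `correlations`
#'   (`J x J`, unit diagonal) and `item_spread` (data.frame with `min`, `q25`,
#'   `median`, `q75`, `max` per item).
#' @export
interrater_correlations <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L) stop("at least two experts required")
  if (ncol(ratings) < 2L) stop("at least two items required")
  sd0 <- apply(ratings, 1L, function(x) stats::sd(x, na.rm = TRUE)) == 0
  if (any(sd0))
    warning("constant rater(s): correlations undefined for expert(s) ",
            paste(which(sd0), collapse = ", "))
  cors <- suppressWarnings(
    stats::cor(t(ratings), use = "pairwise.complete.obs"))
  diag(cors) <- 1
  fv <- apply(ratings, 2L, function(x)
    stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE, names = FALSE))
  spread <- data.frame(item = colnames(ratings) %||%
                         as.character(seq_len(ncol(ratings))),
                       min = fv[1, ], q25 = fv[2, ], median = fv[3, ],
                       q75 = fv[4, ], max = fv[5, ], row.names = NULL)
  structure(list(correlations = cors, item_spread = spread),
            class = "interrater")
}

#' @export
print.interrater <- function(x, digits = 3, ...) {
  cat("Inter-rater correlation matrix:\n")
  print(round(x$correlations, digits))
  cat("\nPer-item rating spread:\n")
  print(x$item_spread, digits = digits)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
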