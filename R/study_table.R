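#' Construct and validate a study table of external ICC estimates
#'
#' A study table holds one row per outcome-level intracluster correlation
#' coefficient (ICC) estimate extracted from an external study, together with
#' the size of the study it came from and relevance weights. Rows belonging to
#' the same study share a `study_id` and a single study-level weight; the
#' outcome-level weight may differ between rows.
#'
#' @param study_id vector of study identifiers (coerced to character).
#' @param outcome_id vector of outcome identifiers, unique within study.
#' @param icc observed ICC estimates, each in `[0, 1)`. An estimate of exactly
#'   0 is legal (small studies often report "0.00"); only the latent true ICC
#'   is constrained to the open interval.
#' @param n total number of participants per record; must exceed `k`.
#' @param k number of clusters per record; at least 2.
#' @param study_weight study-level relevance weight in `(0, 1]`; recycled
#'   within study. Defaults to 1 (fully relevant).
#' @param outcome_weight outcome-level relevance weight in `(0, 1]`.
#' @param label free-text outcome description.
#'
#' @return A `data.frame` of class `"study_table"` with columns
#'   `study_id`, `outcome_id`, `label`, `icc`, `n`, `k`, `study_weight`,
#'   `outcome_weight`, ordered as supplied.
#' @seealso [read_study_table()], [classical_icc_summaries()], [icc_fit()]
#' @examples
#' study_table(study_id = c(1, 1, 2), outcome_id = c(1, 2, 1),
#'             icc = c(0.05, 0.1, 0.02), n = c(200, 200, 500), k = c(10, 10, 25))
#' @export
study_table <- function(study_id, outcome_id, icc, n, k,
                        study_weight = 1, outcome_weight = 1,
                        label = "") {
  L <- length(icc)
  tab <- data.frame(
    study_id = as.character(rep_len(study_id, L)),
    outcome_id = as.character(rep_len(outcome_id, L)),
    label = as.character(rep_len(label, L)),
    icc = as.numeric(icc),
    n = as.numeric(rep_len(n, L)),
    k = as.numeric(rep_len(k, L)),
    study_weight = as.numeric(rep_len(study_weight, L)),
    outcome_weight = as.numeric(rep_len(outcome_weight, L)),
    stringsAsFactors = FALSE
  )
  validate_study_table(tab)
}

#' Validate a study table
#'
#' Checks every record-level invariant (`k >= 2`, `n > k`, `0 <= icc < 1`,
#' weights in `(0, 1]`) and the table-level invariants (unique study ids with
#' contiguous rows, a single study weight per study). Called by all
#' constructors and by [read_study_table()].
#'
#' @param tab a data.frame with the `study_table` columns.
#' @return `tab`, classed as `"study_table"`, invisibly usable downstream.
#' @export
validate_study_table <- function(tab) {
  req <- c("study_id", "outcome_id", "icc", "n", "k")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("study table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) {
    tab$label <- character(0)
    tab$study_weight <- numeric(0)
    tab$outcome_weight <- numeric(0)
    class(tab) <- c("study_table", "data.frame")
    return(tab)
  }
  if (is.null(tab$label)) tab$label <- ""
  if (is.null(tab$study_weight)) tab$study_weight <- 1
  if (is.null(tab$outcome_weight)) tab$outcome_weight <- 1
  tab$study_weight[is.na(tab$study_weight)] <- 1
  tab$outcome_weight[is.na(tab$outcome_weight)] <- 1

  bad_record <- function(cond, what) {
    if (any(cond)) {
      i <- which(cond)
      stop("invalid record(s) at row(s) ", paste(i, collapse = ", "),
           ": ", what, call. = FALSE)
    }
  }
  bad_record(!is.finite(tab$icc) | tab$icc < 0 | tab$icc >= 1,
             "icc must lie in [0, 1)")
  bad_record(!is.finite(tab$k) | tab$k < 2, "k must be at least 2")
  bad_record(!is.finite(tab$n) | tab$n <= tab$k,
             "n must exceed the number of clusters k")
  bad_record(!is.finite(tab$study_weight) | tab$study_weight <= 0 |
               tab$study_weight > 1,
             "study_weight must lie in (0, 1]")
  bad_record(!is.finite(tab$outcome_weight) | tab$outcome_weight <= 0 |
               tab$outcome_weight > 1,
             "outcome_weight must lie in (0, 1]")

  # study ids must form contiguous blocks and be unique across blocks
  ids <- as.character(tab$study_id)
  blocks <- rle(ids)$values
  if (anyDuplicated(blocks))
    stop("rows of the same study must be contiguous and study ids unique; ",
         "duplicated study block(s): ",
         paste(unique(blocks[duplicated(blocks)]), collapse = ", "),
         call. = FALSE)
  # one study weight per study; first occurrence wins only if all agree
  sw <- tapply(tab$study_weight, ids, function(x) length(unique(x)))
  if (any(sw > 1))
    stop("conflicting study_weight values within study ",
         paste(names(sw)[sw > 1], collapse = ", "), call. = FALSE)
  dup <- duplicated(paste(ids, tab$outcome_id, sep = "\r"))
  if (any(dup))
    stop("duplicated outcome_id within study at row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)

  class(tab) <- unique(c("study_table", class(tab)))
  rownames(tab) <- NULL
  tab
}

#' Read a study table from a delimited text file
#'
#' Reads a UTF-8 comma-separated file with header columns `study_id`,
#' `outcome_id`, `icc`, `n`, `k` and optional `label`, `study_weight`,
#' `outcome_weight`. Missing weight columns (or empty cells) are filled with
#' 1.0, i.e. full relevance. Zero weights are rejected: the hierarchical model
#' divides variances by the weights. Malformed numeric cells are reported with
#' their file line number (header is line 1).
#'
#' The 34-record table of stroke-trial ICC estimates used throughout the
#' package documentation is bundled as
#' `system.file("extdata", "table1_icc.csv", package = "iccpool")`.
#'
#' @param path path to a CSV file.
#' @param sep field separator, default comma.
#' @return a validated [study_table()].
#' @examples
#' tab <- read_study_table(system.file("extdata", "table1_icc.csv",
#'                                     package = "iccpool"))
#' nrow(tab)            # 34 outcome-level estimates
#' length(unique(tab$study_id))  # from 16 studies
#' @export
read_study_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           encoding = "UTF-8", check.names = TRUE)
  req <- c("study_id", "outcome_id", "icc", "n", "k")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  num_col <- function(col, name) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !(is.na(col) | col == ""))
    if (length(bad))
      stop("malformed value in column '", name, "' at file line ",
           paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
    x
  }
  tab <- data.frame(
    study_id = raw$study_id,
    outcome_id = raw$outcome_id,
    label = if (is.null(raw$label)) "" else raw$label,
    icc = num_col(raw$icc, "icc"),
    n = num_col(raw$n, "n"),
    k = num_col(raw$k, "k"),
    study_weight = if (is.null(raw$study_weight)) 1
                   else num_col(raw$study_weight, "study_weight"),
    outcome_weight = if (is.null(raw$outcome_weight)) 1
                     else num_col(raw$outcome_weight, "outcome_weight"),
    stringsAsFactors = FALSE
  )
  validate_study_table(tab)
}

#' Write a study table to CSV
#'
#' Inverse of [read_study_table()]: `read_study_table(write_study_table(t))`
#' reproduces `t` field for field (numbers are written at full precision).
#'
#' @param tab a [study_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(tab, path) {
  tab <- validate_study_table(as.data.frame(tab))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  invisible(path)
}

#' Attach externally supplied relevance weights to a study table
#'
#' Replaces the `study_weight` and/or `outcome_weight` columns with pooled
#' weights, e.g. the output of [pool_opinions()] on an expert panel. Study
#' weights are matched by `study_id`; outcome weights positionally by
#' (`study_id`, `outcome_id`).
#'
#' @param tab a [study_table()].
#' @param study_weights named numeric vector, names are study ids.
#' @param outcome_weights numeric vector of length `nrow(tab)`, in table
#'   order, or `NULL` to leave unchanged.
#' @return the re-validated table.
#' @export
set_relevance_weights <- function(tab, study_weights = NULL,
                                  outcome_weights = NULL) {
  tab <- as.data.frame(tab)
  if (!is.null(study_weights)) {
    if (is.null(names(study_weights)))
      stop("study_weights must be named by study_id")
    idx <- match(as.character(tab$study_id), names(study_weights))
    if (anyNA(idx))
      stop("no study weight supplied for study ",
           paste(unique(tab$study_id[is.na(idx)]), collapse = ", "))
    tab$study_weight <- as.numeric(study_weights[idx])
  }
  if (!is.null(outcome_weights)) {
    if (length(outcome_weights) != nrow(tab))
      stop("outcome_weights must have one value per record")
    tab$outcome_weight <- as.numeric(outcome_weights)
  }
  validate_study_table(tab)
}

#' @export
print.study_table <- function(x, ...) {
  ns <- length(unique(x$study_id))
  cat("Study table of external ICC estimates:", nrow(x), "record(s) from",
      ns, "study(ies)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Forest-style plot of a study table
#'
#' Plots each record's ICC estimate with its Swiger-variance confidence
#' interval, in table order, the way pooled external estimates are usually
#' displayed before modelling.
#'
#' @param x a [study_table()].
#' @param level confidence level for the intervals.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.study_table <- function(x, level = 0.95, ...) {
  ci <- t(vapply(seq_len(nrow(x)), function(i) {
    e <- icc_confidence_interval(x$icc[i], x$n[i], x$k[i], level = level)
    c(e$lower, e$upper)
  }, numeric(2)))
  ord <- rev(seq_len(nrow(x)))
  graphics::plot(x$icc, ord, xlim = c(0, max(ci[, 2])), pch = 16,
                 xlab = "ICC estimate", ylab = "record", yaxt = "n", ...)
  graphics::segments(ci[, 1], ord, ci[, 2], ord)
  graphics::axis(2, at = ord, labels = paste(x$study_id, x$outcome_id,
                                             sep = "."), las = 1, cex.axis = 0.6)
  invisible(x)
}
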