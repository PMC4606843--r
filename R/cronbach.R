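#' Sample Cronbach alpha of an item-score matrix
#'
#' Plug-in estimator from the sample covariance matrix \eqn{\Sigma} of the
#' item columns:
#' \deqn{C_\alpha = \frac{k}{k-1}
#'   \left(1 - \frac{trace(\Sigma)}{1^T \Sigma 1}\right).}
#' The covariance matrix uses the unbiased (N - 1) denominator. The
#' estimate is returned as computed: it may be negative when the average
#' inter-item covariance is negative, and it is not clamped to \[0, 1\].
#'
#' @param scores a numeric matrix or data frame of item scores, one row
#'   per subject and one column per item (N >= 2 rows, k >= 2 columns).
#' @return the sample Cronbach alpha (scalar).
#' @examples
#' m <- parallel_items(k = 5, rho = 0.5)
#' y <- simulate_scores(200, m, seed = 1)
#' cronbach_alpha(y)
#' @export
cronbach_alpha <- function(scores) {
  scores <- as_score_matrix(scores)
  k <- ncol(scores)
  if (k < 2L) {
    stop("sample Cronbach alpha needs at least 2 items; it is undefined ",
         "for a single item (use the test-retest correlation instead)",
         call. = FALSE)
  }
  if (nrow(scores) < 2L) stop("need at least 2 subjects", call. = FALSE)
  S <- stats::cov(scores)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

as_score_matrix <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("'scores' must be a numeric matrix or data frame", call. = FALSE)
  }
  if (anyNA(scores)) stop("'scores' contains missing values", call. = FALSE)
  scores
}

#' Read an item-score matrix from delimited text
#'
#' Wide format: a header row of item labels, one row per subject.
#' Long format: three columns named `subject`, `item`, `score`, which are
#' pivoted to wide (items become columns, ordered by first appearance).
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param format `"wide"` (default) or `"long"`.
#' @return a numeric matrix, rows = subjects, columns = items.
#' @seealso [write_scores()]
#' @export
read_scores <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "wide") {
    return(as_score_matrix(df))
  }
  need <- c("subject", "item", "score")
  if (!all(need %in% names(df))) {
    stop("long format needs columns 'subject', 'item', 'score'", call. = FALSE)
  }
  subj <- factor(df$subject, levels = unique(df$subject))
  item <- factor(df$item, levels = unique(df$item))
  wide <- tapply(df$score, list(subj, item), function(v) {
    if (length(v) != 1L) stop("duplicate (subject, item) pair", call. = FALSE)
    v
  })
  if (anyNA(wide)) stop("long data are not rectangular", call. = FALSE)
  m <- matrix(as.numeric(wide), nrow = nlevels(subj),
              dimnames = list(levels(subj), levels(item)))
  m
}

#' Write an item-score matrix as delimited text
#'
#' @param scores matrix or data frame of item scores (rows = subjects).
#' @param path output path; `.tsv`/`.txt` write tab-separated, anything
#'   else comma-separated.
#' @export
write_scores <- function(scores, path) {
  scores <- as_score_matrix(scores)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("item", seq_len(ncol(scores)))
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(scores, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
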