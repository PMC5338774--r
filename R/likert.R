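#' Likert questionnaire table
#'
#' Holds per-item integer ratings on the 1-6 Likert scale (increasing
#' agreement) used for software-ergonomics evaluation.
#'
#' @param ratings named list of integer vectors, one per item, each
#'   rating in 1..6, at least one rating per item.
#' @return an object of class `likert_table`.
#' @export
likert_table <- function(ratings) {
  if (!is.list(ratings) || is.null(names(ratings)) ||
      any(!nzchar(names(ratings))))
    stop("ratings must be a named list of integer vectors")
  for (nm in names(ratings)) {
    r <- ratings[[nm]]
    if (length(r) == 0) stop("parameter error: item ", nm, " has no ratings")
    if (any(r != round(r)) || any(r < 1 | r > 6))
      stop("parameter error: item ", nm, " has ratings outside 1..6")
    ratings[[nm]] <- as.integer(r)
  }
  structure(list(ratings = ratings), class = "likert_table")
}

# round half away from zero, the convention that reproduces the
# published questionnaire table (R's round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small guard against binary representation of exact .xx5 inputs
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-item mean and standard error of a Likert table
#'
#' For each item reports the arithmetic mean and the standard error of
#' the mean computed from the population standard deviation (divide by
#' n, not n - 1), both rounded half-up to two decimals — the
#' conventions that reproduce published small-sample questionnaire
#' summaries of this kind. Note that such published tables sometimes
#' label the mean column "Median" and occasionally truncate rather
#' than round the error (0.8165 printed as 0.81); `likert_summary`
#' always computes the mean and rounds half-up.
#'
#' @param table a [likert_table()], or a named list coercible to one.
#' @return data.frame with columns `item`, `n`, `mean`, `sem`.
#' @export
likert_summary <- function(table) {
  if (!inherits(table, "likert_table")) table <- likert_table(table)
  items <- names(table$ratings)
  res <- lapply(items, function(nm) {
    r <- table$ratings[[nm]]
    n <- length(r)
    mu <- mean(r)
    sem <- sqrt(mean((r - mu)^2)) / sqrt(n)
    data.frame(item = nm, n = n,
               mean = round_half_up(mu), sem = round_half_up(sem))
  })
  do.call(rbind, res)
}

#' Read a ratings CSV
#'
#' Long format with header `item,subject,rating`; one row per rating.
#' The package ships an example at
#' `system.file("extdata", "likert_ratings.csv", package = "cranioplan")`
#' with three raters scoring eleven usability questions.
#'
#' @param path CSV path.
#' @return a [likert_table()].
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "rating") %in% names(df)))
    stop("ratings file needs columns 'item' and 'rating'")
  items <- unique(df$item)
  likert_table(stats::setNames(
    lapply(items, function(i) df$rating[df$item == i]), items))
}

#' Bar chart of Likert summaries
#'
#' Simple base-graphics bar chart of per-item means with SEM error
#' bars.
#'
#' @param summary data.frame from [likert_summary()].
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_likert <- function(summary, ...) {
  mids <- graphics::barplot(summary$mean, names.arg = summary$item,
                            ylim = c(0, 6.5),
                            ylab = "mean rating (1-6)", ...)
  graphics::arrows(mids, summary$mean - summary$sem,
                   mids, summary$mean + summary$sem,
                   angle = 90, code = 3, length = 0.04)
  invisible(mids)
}
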