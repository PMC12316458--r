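#' Construct a phenotype outcome table
#'
#' An outcome table holds the multinomial category counts observed for one
#' experimental condition, e.g. heart-looping outcomes
#' (D-loop / mild-no-loop / S-loop) scored across N embryos of one genotype.
#'
#' @param condition Character label for the condition (genotype / treatment).
#' @param categories Character vector of outcome category labels
#'   (length >= 2). Category order is meaningful: two tables entering a test
#'   must share the same ordered categories.
#' @param counts Non-negative integer vector of per-category counts, same
#'   length as `categories`.
#'
#' @return An object of class `outcome_table`: a list with elements
#'   `condition`, `categories`, `counts` (named integer vector) and
#'   `total_n`.
#' @examples
#' outcome_table("WT", c("D-loop", "mild/no-loop", "S-loop"), c(107, 14, 0))
#' @export
outcome_table <- function(condition, categories, counts) {
  categories <- as.character(categories)
  if (length(categories) < 2L) {
    stop("an outcome table needs at least 2 categories", call. = FALSE)
  }
  if (length(counts) != length(categories)) {
    stop("`counts` and `categories` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(categories)) {
    stop("duplicated category labels", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  names(counts) <- categories
  structure(
    list(
      condition = as.character(condition)[1L],
      categories = categories,
      counts = counts,
      total_n = sum(counts)
    ),
    class = "outcome_table"
  )
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Outcome table:", x$condition, "(N =", x$total_n, ")\n")
  tab <- rbind(
    count = x$counts,
    percent = round(100 * x$counts / max(x$total_n, 1L), 2)
  )
  print(tab)
  invisible(x)
}

# Coerce an outcome_table or bare count vector to integer counts.
.as_counts <- function(x, arg = "counts") {
  if (inherits(x, "outcome_table")) return(x$counts)
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric counts or an outcome_table", arg), call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop(sprintf("`%s` must be non-negative integer counts", arg), call. = FALSE)
  }
  as.integer(round(x))
}

# Check that two tables are comparable (same ordered category labels when
# both carry labels; same number of categories always).
.check_comparable <- function(a, b) {
  ca <- .as_counts(a, "table_a")
  cb <- .as_counts(b, "table_b")
  if (length(ca) != length(cb)) {
    stop("tables have different numbers of categories (",
         length(ca), " vs ", length(cb), ")", call. = FALSE)
  }
  if (inherits(a, "outcome_table") && inherits(b, "outcome_table") &&
      !identical(a$categories, b$categories)) {
    stop("category labels/order differ between the two tables", call. = FALSE)
  }
  list(a = ca, b = cb)
}
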