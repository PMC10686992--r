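#' Build a group partition from node labels
#'
#' Maps each node to a group index \code{1..B} and records group sizes and
#' proportional sizes (fractions) \eqn{f_i}. By convention the minority
#' group (smallest fraction) comes first, so group 1 plays the role of the
#' minority; ties are broken lexicographically by category name.
#'
#' @param groups named vector (or named factor): node id -> group category.
#'   Names are node identifiers; values are arbitrary hashable categories.
#' @param minority_first logical; if \code{TRUE} (default) group levels are
#'   ordered by increasing fraction, so index 1 is the minority. If
#'   \code{FALSE}, levels keep lexicographic order.
#' @return an object of class \code{group_partition}: a list with
#'   \code{index} (named integer vector, node -> group index),
#'   \code{levels} (category name per group index), \code{sizes}
#'   (node counts) and \code{fractions} (\eqn{f_i}, summing to 1).
#' @examples
#' p <- group_partition(c(u = "F", v = "F", w = "M", x = "M", y = "M"))
#' p$fractions  # minority first: 0.4, 0.6
#' @export
group_partition <- function(groups, minority_first = TRUE) {
  if (length(groups) == 0L) stop("empty partition")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named vector (node id -> category)")
  if (anyNA(groups)) stop("missing group label")
  cats <- as.character(groups)
  tab <- table(cats)
  lev <- names(tab)[order(as.integer(tab), names(tab))]  # by size then name
  if (!minority_first) lev <- sort(names(tab))
  index <- match(cats, lev)
  names(index) <- names(groups)
  sizes <- as.integer(table(factor(cats, levels = lev)))
  structure(
    list(index = index, levels = lev, sizes = sizes,
         fractions = sizes / length(index)),
    class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("Group partition: %d nodes, %d group%s\n",
              length(x$index), length(x$levels),
              if (length(x$levels) == 1L) "" else "s"))
  for (i in seq_along(x$levels))
    cat(sprintf("  [%d] %-12s n = %d  f = %.4f\n",
                i, x$levels[i], x$sizes[i], x$fractions[i]))
  invisible(x)
}

n_groups <- function(partition) length(partition$levels)
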