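#' Aggregate gender-mixing counts for nine empirical networks
#'
#' Published per-network summaries for social networks with annotated
#' binary gender: scientific collaboration (APS, DBLP across four
#' decades, INFORMS), collaborative coding (GitHub) and face-to-face
#' contact (two SocioPatterns school classes). Each record carries the
#' node count \code{N}, minority fraction \code{f0}, total edge count
#' \code{E}, the minority-minority (\code{E00}), inter-group
#' (\code{E01}) and majority-majority (\code{E11}) edge counts, and the
#' originally reported nominal and adjusted assortativity
#' (\code{r_printed}, \code{r_adj_printed}, rounded to two decimals).
#' Group 0 is the minority.
#'
#' Only these aggregate counts are shipped; the underlying networks are
#' not. The counts satisfy \code{E00 + E01 + E11 == E} for every record,
#' and \code{\link{empirical_regression}} verifies that both
#' coefficients recompute from them.
#'
#' @return data frame with nine rows and the columns above.
#' @examples
#' emp <- empirical_networks()
#' with(emp, all(E00 + E01 + E11 == E))
#' @export
empirical_networks <- function() {
  path <- system.file("extdata", "empirical_mixing_counts.tsv",
                      package = "groupmix", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = TRUE, stringsAsFactors = FALSE)
}

#' Recompute assortativity from the empirical count fixtures
#'
#' For each record of \code{\link{empirical_networks}}, recomputes the
#' nominal and adjusted assortativity from the count triplet and the
#' minority fraction via \code{\link{assortativity_counts}} and compares
#' with the reported two-decimal values. Because \code{f0} is itself
#' rounded to two decimals, agreement is asserted within a tolerance
#' (default \code{0.01}) rather than exactly. The function errors,
#' naming the offending record, if any deviation exceeds the tolerance;
#' otherwise it returns the per-record report.
#'
#' As a descriptive check the report also records that the nominal
#' coefficient never exceeds the adjusted one at printed precision
#' (they coincide for the most balanced network, SocioPatterns 5).
#'
#' @param tolerance maximum allowed absolute deviation (> 0).
#' @return data frame with per-record recomputed \code{r}, \code{r_adj}
#'   and deviations from the reported values, invisibly printed.
#' @examples
#' rep <- empirical_regression()
#' max(abs(rep$dev_r), abs(rep$dev_r_adj)) <= 0.01
#' @export
empirical_regression <- function(tolerance = 0.01) {
  if (tolerance <= 0) stop("tolerance must be positive")
  emp <- empirical_networks()
  rec <- t(mapply(assortativity_counts,
                  emp$E00, emp$E01, emp$E11, emp$f0))
  out <- data.frame(name = emp$name,
                    r = rec[, "r"], r_adj = rec[, "r_adj"],
                    r_printed = emp$r_printed,
                    r_adj_printed = emp$r_adj_printed,
                    dev_r = rec[, "r"] - emp$r_printed,
                    dev_r_adj = rec[, "r_adj"] - emp$r_adj_printed)
  bad <- abs(out$dev_r) > tolerance | abs(out$dev_r_adj) > tolerance
  if (any(bad))
    stop(sprintf("recomputed assortativity deviates beyond %g for: %s",
                 tolerance, paste(out$name[bad], collapse = ", ")))
  under <- out$r_printed <= out$r_adj_printed
  if (!all(under))
    stop(sprintf("nominal exceeds adjusted at printed precision for: %s",
                 paste(out$name[!under], collapse = ", ")))
  out
}
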