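#' Write an association/cascade results table
#'
#' Tab-separated output with a header and a deterministic column order.
#' Reporting rules: odds ratios and their confidence bounds are truncated
#' to two decimals; allele frequencies (`maf_*` columns) are printed as
#' percentages with three decimals and carrier frequencies (`freq_*`
#' columns) as percentages with two decimals; p-values are printed with
#' four decimals.  All other columns are written as-is.
#'
#' @param rows data frame of homogeneous result records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  out <- rows
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    if (nm %in% c("or", "ci_low", "ci_high")) {
      out[[nm]] <- fmt_or(out[[nm]])
    } else if (startsWith(nm, "maf_")) {
      out[[nm]] <- fmt_pct(out[[nm]], 3)
    } else if (startsWith(nm, "freq_")) {
      out[[nm]] <- fmt_pct(out[[nm]], 2)
    } else if (nm %in% c("p", "p_corrected")) {
      out[[nm]] <- sprintf("%.4f", out[[nm]])
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
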