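#' Per-donor mutation burden
#'
#' Counts the mutations carried by each enrolled donor. The catalog should
#' already be restricted to the consequence classes of interest (see
#' [filter_consequences()]) — typically exonic classes, so the counts are
#' per-donor exonic burdens. Roster donors without any passing call
#' receive a count of 0.
#'
#' @param catalog a `mut_catalog`.
#' @return data.table with columns `donor_id`, `cancer_type`,
#'   `n_mutations`, one row per roster donor.
#' @export
donor_burden <- function(catalog) {
  counts <- catalog$calls[, .(n_mutations = .N), by = donor_id]
  burden <- merge(catalog$roster, counts, by = "donor_id", all.x = TRUE)
  burden[is.na(n_mutations), n_mutations := 0L]
  setkeyv(burden, c("cancer_type", "donor_id"))
  burden[]
}

# median-of-halves quartiles: split the sorted values at the median,
# excluding the middle element when n is odd, and take each half's median
mh_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(c(q1 = x, q3 = x))
  h <- n %/% 2L
  c(q1 = median(x[seq_len(h)]), q3 = median(x[seq.int(n - h + 1L, n)]))
}

#' Per-cancer-type burden distribution summary
#'
#' Five-number summaries of per-donor mutation burden for each cancer
#' type, sorted by median. Quartiles follow the median-of-halves rule
#' (the middle value is excluded from both halves when the donor count is
#' odd). Donors with zero burden are included by default; drop them with
#' `include_zero_donors = FALSE` to match conventions that only plot
#' mutation-bearing donors.
#'
#' @param burden data.table from [donor_burden()].
#' @param include_zero_donors keep donors with 0 mutations (default TRUE).
#' @return data.table with columns `cancer_type`, `n_donors`, `min`, `q1`,
#'   `median`, `q3`, `max`, sorted by increasing median. Cancer types left
#'   with no donors are skipped with a warning.
#' @export
burden_summary <- function(burden, include_zero_donors = TRUE) {
  burden <- as.data.table(burden)
  if (!include_zero_donors) burden <- burden[n_mutations > 0L]
  empty <- setdiff(unique(as.data.table(burden)$cancer_type), burden$cancer_type)
  if (length(empty) > 0L) {
    warning("cancer type(s) with no donors skipped: ",
            paste(empty, collapse = ", "))
  }
  if (nrow(burden) == 0L) {
    warning("no donors to summarize")
    return(data.table(cancer_type = character(), n_donors = integer(),
                      min = numeric(), q1 = numeric(), median = numeric(),
                      q3 = numeric(), max = numeric()))
  }
  out <- burden[, {
    q <- mh_quartiles(n_mutations)
    .(n_donors = .N, min = as.numeric(min(n_mutations)),
      q1 = as.numeric(q[["q1"]]), median = as.numeric(median(n_mutations)),
      q3 = as.numeric(q[["q3"]]), max = as.numeric(max(n_mutations)))
  }, by = cancer_type]
  setorder(out, median, cancer_type)
  out[]
}
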