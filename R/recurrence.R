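#' Per-mutation donor recurrence
#'
#' Recurrence of a mutation is the number of distinct donors in which the
#' same genomic change — identified by (chromosome, start, ref, alt) — is
#' observed. A donor contributing several calls of the same mutation
#' counts once. The `"PanCancer"` scope pools all cancer types before
#' counting, so a mutation seen in one donor of each of two types has
#' recurrence 2.
#'
#' @param catalog a `mut_catalog`.
#' @param scope a single cancer type label, or `"PanCancer"` (default) to
#'   pool every type.
#' @return A `recurrence_table`: list with `scope`, `counts` (data.table
#'   of key columns plus `recurrence`), and the scoped `calls` used for
#'   donor-level statistics. Empty scopes yield an empty table with a
#'   warning.
#' @export
recurrence_counts <- function(catalog, scope = "PanCancer") {
  stopifnot(inherits(catalog, "mut_catalog"), length(scope) == 1L)
  calls <- if (identical(scope, "PanCancer")) {
    catalog$calls
  } else {
    catalog$calls[cancer_type == scope]
  }
  if (nrow(calls) == 0L) {
    warning("no calls in scope '", scope, "'")
    counts <- data.table(chromosome = character(), start = integer(),
                         ref = character(), alt = character(),
                         recurrence = integer())
  } else {
    # calls are already unique per (donor, mutation), so recurrence is a
    # plain row count per key
    counts <- calls[, .(recurrence = .N), by = KEY_COLUMNS]
  }
  structure(list(scope = scope, counts = counts,
                 calls = calls[, c("donor_id", KEY_COLUMNS), with = FALSE]),
            class = "recurrence_table")
}

#' @export
print.recurrence_table <- function(x, ...) {
  cat(sprintf("<recurrence_table> scope %s | %s unique mutations | %s recurrent (>= 2 donors)\n",
              x$scope, format(nrow(x$counts), big.mark = ","),
              format(sum(x$counts$recurrence >= 2L), big.mark = ",")))
  invisible(x)
}

#' Format a half-up rounded percentage
#'
#' Renders `100 * numerator / denominator` with half-up rounding at the
#' requested number of decimals and a `%` suffix, matching the fixed-point
#' style of published per-cancer summary tables.
#'
#' @param numerator,denominator non-negative counts; `denominator` must be
#'   positive (callers decide how to render undefined cells).
#' @param decimals decimal places (default 1).
#' @return Character scalar such as `"1.7%"`.
#' @export
format_percent <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop("denominator must be > 0")
  p <- 100 * numerator / denominator
  f <- 10^decimals
  rounded <- floor(p * f + 0.5) / f
  sprintf("%.*f%%", decimals, rounded)
}

#' Summarize recurrence within a scope
#'
#' Counts unique mutations, recurrent mutations (observed in at least two
#' donors), and donors carrying at least one recurrent mutation, with
#' percentages formatted by [format_percent()] at one decimal. The donor
#' denominator is the roster size for the scope, which includes enrolled
#' donors without passing calls.
#'
#' @param table a `recurrence_table` from [recurrence_counts()].
#' @param roster roster data.table (`donor_id`, `cancer_type`), e.g.
#'   `catalog$roster`.
#' @param recurrent_min minimum donor count defining "recurrent"
#'   (default 2, the standard definition).
#' @return One-row data.table with scope, donor and mutation counts, and
#'   formatted percentage columns.
#' @export
recurrence_summary <- function(table, roster, recurrent_min = 2L) {
  stopifnot(inherits(table, "recurrence_table"))
  roster <- as.data.table(roster)
  if (!identical(table$scope, "PanCancer")) {
    roster <- roster[cancer_type == table$scope]
  }
  n_donors <- uniqueN(roster$donor_id)
  observed <- unique(table$calls$donor_id)
  if (length(setdiff(observed, roster$donor_id)) > 0L) {
    stop("roster for scope '", table$scope,
         "' is smaller than the set of donors with calls")
  }
  total <- nrow(table$counts)
  rec_keys <- table$counts[recurrence >= recurrent_min, KEY_COLUMNS,
                           with = FALSE]
  n_rec <- nrow(rec_keys)
  donors_with <- if (n_rec == 0L) 0L else {
    uniqueN(table$calls[rec_keys, on = KEY_COLUMNS, nomatch = NULL]$donor_id)
  }
  data.table(
    scope = table$scope,
    donors = n_donors,
    total_unique_mutations = total,
    recurrent_mutations = n_rec,
    recurrent_pct = if (total > 0L) format_percent(n_rec, total) else NA_character_,
    donors_with_recurrent = donors_with,
    donors_with_recurrent_pct = if (n_donors > 0L) {
      format_percent(donors_with, n_donors)
    } else NA_character_)
}

#' Complementary cumulative recurrence distributions
#'
#' For each recurrence threshold k = 1..k_max computes the fraction of
#' somatic mutations with recurrence >= k and the fraction of donors
#' carrying at least one such mutation. Both are complementary cumulative
#' distributions: non-increasing in k, with the mutation fraction exactly
#' 1 at k = 1. The donor denominator is the roster size for the scope.
#'
#' @inheritParams recurrence_summary
#' @param k_max largest threshold; defaults to the maximum observed
#'   recurrence.
#' @return A `coverage_curve`: data.table with columns `scope`, `k`,
#'   `mutation_fraction`, `donor_fraction`.
#' @export
coverage_curve <- function(table, roster, k_max = NULL) {
  stopifnot(inherits(table, "recurrence_table"))
  roster <- as.data.table(roster)
  if (!identical(table$scope, "PanCancer")) {
    roster <- roster[cancer_type == table$scope]
  }
  n_donors <- uniqueN(roster$donor_id)
  total <- nrow(table$counts)
  if (total == 0L) {
    warning("empty recurrence table for scope '", table$scope, "'")
    return(structure(data.table(scope = character(), k = integer(),
                                mutation_fraction = numeric(),
                                donor_fraction = numeric()),
                     class = c("coverage_curve", "data.table", "data.frame")))
  }
  max_rec <- max(table$counts$recurrence)
  if (is.null(k_max)) k_max <- max_rec
  k <- seq_len(k_max)
  tab <- tabulate(table$counts$recurrence, nbins = max(max_rec, k_max))
  n_at_least <- rev(cumsum(rev(tab)))   # index k: mutations with rec >= k
  mutation_fraction <- n_at_least[k] / total
  # a donor covers threshold k iff the max recurrence among its mutations >= k
  donor_max <- table$calls[table$counts, on = KEY_COLUMNS,
                           .(donor_id, recurrence)][
    , .(max_rec = max(recurrence)), by = donor_id]
  dtab <- tabulate(donor_max$max_rec, nbins = max(max_rec, k_max))
  d_at_least <- rev(cumsum(rev(dtab)))
  donor_fraction <- if (n_donors > 0L) d_at_least[k] / n_donors else rep(NA_real_, k_max)
  structure(data.table(scope = table$scope, k = k,
                       mutation_fraction = mutation_fraction,
                       donor_fraction = donor_fraction),
            class = c("coverage_curve", "data.table", "data.frame"))
}

#' Re-parameterize a coverage curve as donors vs mutations
#'
#' Turns the threshold-indexed curve into ordered (mutation fraction,
#' donor fraction) pairs — the fraction of donors recovered as a function
#' of the fraction of somatic mutations retained, sweeping the recurrence
#' threshold from high to low. Duplicate mutation fractions are collapsed
#' keeping the largest donor fraction.
#'
#' @param curve a `coverage_curve`.
#' @return data.table with columns `mutation_fraction`, `donor_fraction`,
#'   sorted by increasing mutation fraction.
#' @export
donors_vs_mutations <- function(curve) {
  dt <- as.data.table(curve)[order(-k)]
  dt <- dt[, .(donor_fraction = max(donor_fraction)),
           by = .(mutation_fraction)]
  setorder(dt, mutation_fraction)
  dt[]
}

#' Recurrence summaries for every cancer type plus PanCancer
#'
#' Convenience wrapper running [recurrence_counts()] and
#' [recurrence_summary()] per cancer type and on the pooled catalog.
#'
#' @param catalog a `mut_catalog`.
#' @param recurrent_min minimum donor count defining "recurrent".
#' @return data.table, one row per cancer type plus a final PanCancer row.
#' @export
recurrence_summary_all <- function(catalog, recurrent_min = 2L) {
  scopes <- c(sort(unique(catalog$roster$cancer_type)), "PanCancer")
  rbindlist(lapply(scopes, function(s) {
    tab <- suppressWarnings(recurrence_counts(catalog, s))
    recurrence_summary(tab, catalog$roster, recurrent_min = recurrent_min)
  }))
}
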