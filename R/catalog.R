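#' @import data.table
#' @importFrom stats median rnbinom rbinom pbinom lm coef setNames runif
#' @importFrom utils packageVersion
NULL

# column layout of the tidy internal representation; coordinates are
# 1-based inclusive on a single genome build
CALL_COLUMNS <- c("donor_id", "cancer_type", "chromosome", "start",
                  "ref", "alt", "consequence", "gene")
KEY_COLUMNS <- c("chromosome", "start", "ref", "alt")
CHROMOSOME_LEVELS <- c(as.character(1:22), "X", "Y", "MT")

#' Construct a somatic mutation catalog
#'
#' A `mut_catalog` couples donor-level mutation calls with a donor roster.
#' Calls hold one record per (donor, mutation) pair, where a mutation is
#' identified by (chromosome, start, ref, alt). The roster lists every
#' enrolled donor per cancer type; it may contain donors that carry no
#' calls, which matters for donor-fraction denominators.
#'
#' @param calls data.frame with columns `donor_id`, `cancer_type`,
#'   `chromosome`, `start` (1-based inclusive), `ref`, `alt` (`"-"` for
#'   pure insertion/deletion sides), `consequence`, `gene` (may be `""`).
#' @param roster optional data.frame with columns `donor_id`,
#'   `cancer_type`; defaults to the donors observed in `calls`.
#' @param validate run invariant checks (on by default).
#' @return An object of class `mut_catalog`: a list with data.tables
#'   `calls` and `roster`.
#' @export
new_catalog <- function(calls, roster = NULL, validate = TRUE) {
  calls <- as.data.table(calls)
  missing_cols <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing_cols) > 0L) {
    stop("calls are missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  calls <- calls[, CALL_COLUMNS, with = FALSE]
  calls[, start := as.integer(start)]
  for (col in setdiff(CALL_COLUMNS, "start")) {
    set(calls, j = col, value = as.character(calls[[col]]))
  }
  calls[is.na(gene), gene := ""]
  calls <- unique(calls, by = c("donor_id", KEY_COLUMNS))
  if (is.null(roster)) {
    roster <- unique(calls[, .(donor_id, cancer_type)])
  } else {
    roster <- as.data.table(roster)[, .(donor_id = as.character(donor_id),
                                        cancer_type = as.character(cancer_type))]
    roster <- unique(roster)
  }
  setkeyv(calls, c("cancer_type", "donor_id", KEY_COLUMNS))
  setkeyv(roster, c("cancer_type", "donor_id"))
  obj <- structure(list(calls = calls, roster = roster),
                   class = "mut_catalog")
  if (validate) validate_catalog(obj)
  obj
}

#' Validate catalog invariants
#'
#' Checks coordinates, allele sanity, chromosome labels, deduplication of
#' (donor, mutation) pairs, and that every donor with calls is enrolled in
#' the roster.
#'
#' @param catalog a `mut_catalog`.
#' @return `catalog`, invisibly; errors describe the first violation found.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "mut_catalog"))
  calls <- catalog$calls
  if (nrow(calls) > 0L) {
    if (anyNA(calls$start) || any(calls$start < 1L)) {
      stop("invalid start coordinate: all starts must be integers >= 1")
    }
    bad_chr <- setdiff(unique(calls$chromosome), CHROMOSOME_LEVELS)
    if (length(bad_chr) > 0L) {
      stop("chromosome label(s) outside {1..22, X, Y, MT}: ",
           paste(utils::head(bad_chr, 5L), collapse = ", "))
    }
    if (any(calls$ref == calls$alt)) {
      stop("ref and alt alleles must differ for every call")
    }
    if (anyDuplicated(calls, by = c("donor_id", KEY_COLUMNS)) > 0L) {
      stop("duplicate (donor_id, mutation) pairs in calls")
    }
    orphans <- setdiff(unique(calls$donor_id), catalog$roster$donor_id)
    if (length(orphans) > 0L) {
      stop("donor(s) with calls missing from roster: ",
           paste(utils::head(orphans, 5L), collapse = ", "))
    }
  }
  invisible(catalog)
}

#' @export
print.mut_catalog <- function(x, ...) {
  n_mut <- if (nrow(x$calls) > 0L) nrow(unique(x$calls, by = KEY_COLUMNS)) else 0L
  cat(sprintf(
    "<mut_catalog> %s calls | %s unique mutations | %s donors (%s with calls) | %s cancer types\n",
    format(nrow(x$calls), big.mark = ","),
    format(n_mut, big.mark = ","),
    format(nrow(x$roster), big.mark = ","),
    format(uniqueN(x$calls$donor_id), big.mark = ","),
    uniqueN(x$roster$cancer_type)))
  invisible(x)
}

#' Attach a donor roster to a catalog
#'
#' @param catalog a `mut_catalog`.
#' @param roster data.frame with `donor_id`, `cancer_type` columns,
#'   typically from [read_donor_manifest()].
#' @return The catalog with the new roster (validated).
#' @export
set_roster <- function(catalog, roster) {
  new_catalog(catalog$calls, roster = roster)
}

mut_key <- function(dt) {
  paste(dt$chromosome, dt$start, dt$ref, dt$alt, sep = ":")
}
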