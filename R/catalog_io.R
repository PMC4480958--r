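#' Consequence severity priority
#'
#' ICGC simple somatic mutation files carry one row per annotated
#' consequence, so the same (donor, mutation) pair can appear several
#' times. When collapsing to one call we keep the most severe consequence
#' according to this ordering (most to least severe). Terms not listed
#' rank after all listed ones.
#'
#' @return Character vector of consequence terms, most severe first.
#' @export
consequence_priority <- function() {
  c("stop_gained", "stop_lost", "start_lost",
    "frameshift_variant",
    "missense_variant",
    "disruptive_inframe_insertion", "disruptive_inframe_deletion",
    "inframe_insertion", "inframe_deletion",
    "synonymous_variant", "exon_variant",
    "splice_acceptor_variant", "splice_donor_variant",
    "splice_region_variant",
    "5_prime_UTR_variant", "3_prime_UTR_variant",
    "intron_variant", "upstream_gene_variant",
    "downstream_gene_variant", "intergenic_region")
}

#' Default exonic consequence include-list
#'
#' The coding-region consequence classes retained when an analysis is
#' restricted to exonic mutations (burden summaries and the recurrence
#' statistics reported per cancer type). Configurable wherever it is used.
#'
#' @return Character vector of consequence terms.
#' @export
exonic_consequences <- function() {
  c("missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
    "start_lost", "frameshift_variant", "inframe_insertion",
    "inframe_deletion", "exon_variant")
}

normalize_chromosome <- function(x) {
  x <- sub("^chr", "", x, ignore.case = TRUE)
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

# ICGC SSM dialect: header-named columns; extra columns are ignored
ICGC_COLUMNS <- c(donor_id = "icgc_donor_id",
                  cancer_type = "project_code",
                  chromosome = "chromosome",
                  start = "chromosome_start",
                  ref = "reference_genome_allele",
                  alt = "mutated_to_allele",
                  consequence = "consequence_type",
                  gene = "gene_affected")

#' Read an ICGC-style simple somatic mutation file
#'
#' Reads a tab-separated SSM export (one row per donor x mutation x
#' consequence), normalizes chromosome labels (leading "chr" stripped,
#' case-folded, "M" mapped to "MT"), and collapses per-consequence
#' duplicate rows to one call per (donor, mutation), keeping the most
#' severe consequence per [consequence_priority()].
#'
#' @param path path to a TSV with header columns `icgc_donor_id`,
#'   `project_code`, `chromosome`, `chromosome_start`,
#'   `reference_genome_allele`, `mutated_to_allele`, `consequence_type`,
#'   `gene_affected` (extra columns ignored).
#' @param include optional consequence include-list applied after reading
#'   (see [filter_consequences()]).
#' @param normalize_chromosomes strip "chr" prefixes and case-fold labels.
#' @param on_bad_record `"error"` (default) aborts on the first record with
#'   an unparseable coordinate, invalid chromosome, or identical ref/alt
#'   alleles, reporting line numbers; `"skip"` drops such records with a
#'   warning.
#' @param manifest optional donor roster from [read_donor_manifest()];
#'   defaults to the donors observed in the file.
#' @return A [new_catalog()] object. The cancer type of each call is its
#'   project code; use [merge_projects()] to pool national projects.
#' @export
read_icgc_ssm <- function(path, include = NULL, normalize_chromosomes = TRUE,
                          on_bad_record = c("error", "skip"),
                          manifest = NULL) {
  on_bad_record <- match.arg(on_bad_record)
  if (!file.exists(path)) stop("SSM file not found: ", path)
  raw <- fread(path, sep = "\t", colClasses = "character",
               na.strings = NULL, header = TRUE)
  missing_cols <- setdiff(unname(ICGC_COLUMNS), names(raw))
  if (length(missing_cols) > 0L) {
    stop("SSM file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  calls <- raw[, unname(ICGC_COLUMNS), with = FALSE]
  setnames(calls, unname(ICGC_COLUMNS), names(ICGC_COLUMNS))
  if (nrow(calls) == 0L) {
    return(new_catalog(empty_calls(), roster = manifest))
  }
  if (normalize_chromosomes) {
    calls[, chromosome := normalize_chromosome(chromosome)]
  }
  calls[ref == "", ref := "-"]
  calls[alt == "", alt := "-"]
  start_num <- suppressWarnings(as.integer(calls$start))
  bad <- is.na(start_num) | start_num < 1L |
    !(calls$chromosome %chin% CHROMOSOME_LEVELS) |
    calls$ref == calls$alt
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    msg <- sprintf(
      "%d unparseable/invalid record(s) at line(s) %s",
      sum(bad), paste(utils::head(lines, 10L), collapse = ", "))
    if (on_bad_record == "error") {
      stop(msg, " (set on_bad_record = \"skip\" to drop them)")
    }
    warning(msg, "; records skipped")
    calls <- calls[!bad]
    start_num <- start_num[!bad]
  }
  calls[, start := start_num]
  calls <- collapse_consequences(calls)
  catalog <- new_catalog(calls, roster = manifest)
  if (!is.null(include)) catalog <- filter_consequences(catalog, include)
  catalog
}

# keep the most severe consequence per (donor, mutation); stable for ties
collapse_consequences <- function(calls) {
  prio <- consequence_priority()
  calls[, .priority := match(consequence, prio, nomatch = length(prio) + 1L)]
  setorderv(calls, c("donor_id", KEY_COLUMNS, ".priority"))
  calls <- unique(calls, by = c("donor_id", KEY_COLUMNS))
  calls[, .priority := NULL]
  calls[]
}

empty_calls <- function() {
  data.table(donor_id = character(), cancer_type = character(),
             chromosome = character(), start = integer(),
             ref = character(), alt = character(),
             consequence = character(), gene = character())
}

#' Read a donor manifest
#'
#' A manifest enumerates enrolled donors per project, independently of
#' whether they carry any passing mutation call. Donor-fraction
#' denominators use the manifest when one is supplied, so cohorts where
#' many donors carry few or no exonic mutations are summarized correctly.
#'
#' @param path two-column TSV with header `icgc_donor_id` (or `donor_id`)
#'   and `project_code`.
#' @return data.table with columns `donor_id`, `cancer_type`, one row per
#'   donor. A donor listed twice under the same project is deduplicated; a
#'   donor listed under two different projects is an error.
#' @export
read_donor_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  raw <- fread(path, sep = "\t", colClasses = "character",
               na.strings = NULL, header = TRUE)
  donor_col <- intersect(c("icgc_donor_id", "donor_id"), names(raw))[1]
  if (is.na(donor_col) || !"project_code" %in% names(raw)) {
    stop("manifest must have columns donor_id (or icgc_donor_id) and project_code")
  }
  roster <- unique(data.table(donor_id = raw[[donor_col]],
                              cancer_type = raw[["project_code"]]))
  dup <- roster[, .N, by = donor_id][N > 1L]
  if (nrow(dup) > 0L) {
    stop("donor(s) listed under conflicting projects: ",
         paste(utils::head(dup$donor_id, 5L), collapse = ", "))
  }
  roster
}

#' Merge national projects into cancer types
#'
#' Data from the same tumor type sequenced by different national
#' consortiums carry project codes like `BRCA-US` and `BRCA-UK`; this
#' strips the trailing two-letter country suffix so they pool into one
#' cancer type. Calls are re-deduplicated after merging (a donor listed
#' under two merged projects contributes each mutation once). Idempotent.
#'
#' @param catalog a `mut_catalog`.
#' @return The merged catalog.
#' @export
merge_projects <- function(catalog) {
  calls <- copy(catalog$calls)
  roster <- copy(catalog$roster)
  strip <- function(x) sub("-[A-Z]{2}$", "", x)
  calls[, cancer_type := strip(cancer_type)]
  roster[, cancer_type := strip(cancer_type)]
  calls <- collapse_consequences(calls)
  new_catalog(calls, roster = unique(roster))
}

#' Restrict a catalog to selected consequence classes
#'
#' Keeps only calls whose consequence is in the include-list. The roster
#' is unchanged: donors whose calls are all filtered away remain enrolled
#' with zero burden, which is the correct denominator for donor-fraction
#' statistics.
#'
#' @param catalog a `mut_catalog`.
#' @param include non-empty character vector of consequence terms;
#'   defaults to [exonic_consequences()]. Terms outside the known
#'   vocabulary trigger a warning (not an error).
#' @return The filtered catalog.
#' @export
filter_consequences <- function(catalog, include = exonic_consequences()) {
  if (length(include) == 0L) stop("include-list must be non-empty")
  unknown <- setdiff(include, consequence_priority())
  if (length(unknown) > 0L) {
    warning("consequence term(s) not in the known vocabulary: ",
            paste(unknown, collapse = ", "))
  }
  calls <- catalog$calls[consequence %chin% include]
  new_catalog(calls, roster = catalog$roster)
}

#' Drop thinly covered cancer types
#'
#' Removes cancer types whose catalog is too small to analyze: fewer than
#' `min_mutations` unique mutations (e.g. a leukemia project with only 3
#' detected mutations) or fewer than `min_donors` enrolled donors (e.g.
#' the 50-donor floor used before curve fitting). Removal is logged.
#'
#' @param catalog a `mut_catalog`.
#' @param min_mutations minimum unique mutations per type (default 0).
#' @param min_donors minimum roster donors per type (default 0).
#' @return Catalog restricted to the passing cancer types.
#' @export
filter_cancer_types <- function(catalog, min_mutations = 0L, min_donors = 0L) {
  stopifnot(min_mutations >= 0L, min_donors >= 0L)
  muts <- catalog$calls[, .(n_mutations = uniqueN(mut_key(.SD))),
                        by = cancer_type, .SDcols = KEY_COLUMNS]
  dons <- catalog$roster[, .(n_donors = .N), by = cancer_type]
  tab <- merge(dons, muts, by = "cancer_type", all = TRUE)
  tab[is.na(n_mutations), n_mutations := 0L]
  tab[is.na(n_donors), n_donors := 0L]
  drop <- tab[n_mutations < min_mutations | n_donors < min_donors]
  if (nrow(drop) > 0L) {
    message(sprintf(
      "filter_cancer_types: removing %d type(s): %s",
      nrow(drop),
      paste(sprintf("%s (%d mutations, %d donors)", drop$cancer_type,
                    drop$n_mutations, drop$n_donors), collapse = "; ")))
  }
  keep <- setdiff(tab$cancer_type, drop$cancer_type)
  new_catalog(catalog$calls[cancer_type %chin% keep],
              roster = catalog$roster[cancer_type %chin% keep])
}

#' Write / read the tidy internal catalog format
#'
#' The tidy format is a plain TSV with the fixed column order `donor_id`,
#' `cancer_type`, `chromosome`, `start`, `ref`, `alt`, `consequence`,
#' `gene` (UTF-8, LF line endings; coordinates 1-based inclusive). The
#' roster is written alongside as `<path stem>.roster.tsv` so that
#' `read_catalog(write_catalog(c))` reproduces `c` exactly, including
#' donors without calls.
#'
#' @param catalog a `mut_catalog`.
#' @param path output TSV path for the calls.
#' @param roster_path output path for the roster; defaults to
#'   `<path stem>.roster.tsv`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path,
                          roster_path = default_roster_path(path)) {
  fwrite(catalog$calls, path, sep = "\t", eol = "\n", quote = FALSE)
  fwrite(catalog$roster, roster_path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path, roster_path = default_roster_path(path)) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  calls <- fread(path, sep = "\t", colClasses = "character",
                 na.strings = NULL, header = TRUE)
  if (nrow(calls) == 0L) calls <- empty_calls()
  roster <- NULL
  if (file.exists(roster_path)) {
    roster <- fread(roster_path, sep = "\t", colClasses = "character",
                    na.strings = NULL, header = TRUE)
  }
  new_catalog(calls, roster = roster)
}

default_roster_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".roster.tsv")
}
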