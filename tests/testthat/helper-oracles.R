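# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately written in plain base R, on string mutation keys,
# so that it shares no code path with the data.table implementation.

key_of <- function(df) paste(df$chromosome, df$start, df$ref, df$alt, sep = ":")

# random donor-level catalog with forced recurrence: mutations drawn from a
# small key space so that many keys are shared between donors
random_catalog <- function(seed, donors = 20L, types = 2L, calls_per_donor = 8L,
                           key_space = 40L, genes = 10L) {
  set.seed(seed)
  type_labels <- sprintf("T%02d", seq_len(types))
  donor_type <- sample(type_labels, donors, replace = TRUE)
  donor_ids <- sprintf("D%03d", seq_len(donors))
  rows <- do.call(rbind, lapply(seq_len(donors), function(i) {
    n <- rpois(1, calls_per_donor) + 1L
    ks <- sample.int(key_space, n, replace = TRUE)
    data.frame(donor_id = donor_ids[i], cancer_type = donor_type[i],
               chromosome = as.character(1L + (ks %% 3L)),
               start = 100L + ks,
               ref = "A", alt = "T",
               consequence = sample(c("missense_variant", "synonymous_variant",
                                      "stop_gained", "intron_variant"),
                                    n, replace = TRUE),
               gene = sprintf("G%02d", 1L + (ks %% genes)))
  }))
  new_catalog(rows)
}

# recurrence = number of distinct donors per key, by naive split/count
brute_recurrence <- function(calls, scope = "PanCancer") {
  df <- as.data.frame(calls)
  if (!identical(scope, "PanCancer")) df <- df[df$cancer_type == scope, ]
  sapply(split(df$donor_id, key_of(df)), function(d) length(unique(d)))
}

brute_summary <- function(calls, roster, scope = "PanCancer") {
  rec <- brute_recurrence(calls, scope)
  df <- as.data.frame(calls)
  ros <- as.data.frame(roster)
  if (!identical(scope, "PanCancer")) {
    df <- df[df$cancer_type == scope, ]
    ros <- ros[ros$cancer_type == scope, ]
  }
  rec_keys <- names(rec)[rec >= 2]
  donors_with <- unique(df$donor_id[key_of(df) %in% rec_keys])
  list(total = length(rec), recurrent = sum(rec >= 2),
       donors = length(unique(ros$donor_id)),
       donors_with_recurrent = length(donors_with))
}

# CCD by explicit looping over thresholds
brute_curve <- function(calls, roster, scope = "PanCancer", k_max = NULL) {
  rec <- brute_recurrence(calls, scope)
  df <- as.data.frame(calls)
  ros <- as.data.frame(roster)
  if (!identical(scope, "PanCancer")) {
    df <- df[df$cancer_type == scope, ]
    ros <- ros[ros$cancer_type == scope, ]
  }
  if (is.null(k_max)) k_max <- max(rec)
  keys <- key_of(df)
  n_donors <- length(unique(ros$donor_id))
  t(sapply(seq_len(k_max), function(k) {
    hot <- names(rec)[rec >= k]
    c(k = k,
      mutation_fraction = sum(rec >= k) / length(rec),
      donor_fraction = length(unique(df$donor_id[keys %in% hot])) / n_donors)
  }))
}

# donors of type t with >= 1 recurrent mutation in gene g, by triple loop
brute_gene_matrix <- function(calls, recurrent_keys) {
  df <- as.data.frame(calls)
  df <- df[key_of(df) %in% recurrent_keys & df$gene != "", ]
  types <- sort(unique(as.data.frame(calls)$cancer_type))
  genes <- sort(unique(df$gene))
  m <- matrix(0L, length(types), length(genes), dimnames = list(types, genes))
  for (t in types) for (g in genes) {
    m[t, g] <- length(unique(df$donor_id[df$cancer_type == t & df$gene == g]))
  }
  m
}

# naive UPGMA: repeatedly merge the pair of clusters with the smallest
# mean pairwise distance; returns the cophenetic distance matrix
brute_average_cophenetic <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  coph <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_h; coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# write a minimal ICGC-dialect SSM file from row vectors
write_ssm_fixture <- function(path, rows) {
  header <- c("icgc_donor_id", "project_code", "chromosome",
              "chromosome_start", "reference_genome_allele",
              "mutated_to_allele", "consequence_type", "gene_affected")
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}

# two groups of cancer types with group-specific hotspot pools, used for
# planted-cluster recovery
planted_panel <- function(per_group = 3L) {
  c(lapply(seq_len(per_group), function(i) {
    sim_config(sprintf("GA%d", i), donors = 60L, burden_mean = 40,
               burden_dispersion = 2, shared_pool_size = 500L,
               shared_fraction = 0.35, zipf_exponent = 1.1,
               genes = 400L, pool = "groupA")
  }),
  lapply(seq_len(per_group), function(i) {
    sim_config(sprintf("GB%d", i), donors = 60L, burden_mean = 40,
               burden_dispersion = 2, shared_pool_size = 500L,
               shared_fraction = 0.35, zipf_exponent = 1.1,
               genes = 400L, pool = "groupB")
  }))
}
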