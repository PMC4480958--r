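#' Synthetic catalog configuration
#'
#' Parameterizes the generative model for one simulated cancer type. Each
#' donor draws an exonic mutation burden from a negative binomial
#' (heavy-tailed, unlike a Poisson, to reproduce the orders-of-magnitude
#' spread of real per-donor counts). Each drawn mutation is, with
#' probability `shared_fraction`, a hotspot sampled from a finite pool
#' with Zipf-distributed popularity (a few "mountains", many "hills");
#' otherwise it is a donor-private mutation with a unique synthetic
#' coordinate, so the recurrence-1 class is exact by construction.
#' Hotspot identity, gene, and consequence are fixed pool-wide, so two
#' cancer types given the same `pool` label share hotspots.
#'
#' @param cancer_type label for the simulated type.
#' @param donors number of enrolled donors (>= 1).
#' @param burden_mean negative-binomial mean per-donor mutation count.
#' @param burden_dispersion negative-binomial size parameter; smaller
#'   values give heavier tails.
#' @param shared_pool_size number of distinct hotspot mutations in the pool.
#' @param shared_fraction probability in \[0,1\] that a drawn mutation
#'   comes from the hotspot pool rather than being private.
#' @param zipf_exponent skew of hotspot popularity weights (weight of
#'   hotspot i proportional to i^-zipf_exponent); 0 gives a uniform pool.
#' @param genes number of gene labels in the simulated gene universe.
#' @param pool pool label; configs sharing a label share hotspots (and
#'   must agree on `genes`).
#' @param consequence_probs named probability vector over consequence
#'   terms; hotspots get a pool-wide fixed consequence, private mutations
#'   sample per call.
#' @param seed default RNG seed used by [generate_catalog()].
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(cancer_type, donors, burden_mean,
                       burden_dispersion = 1,
                       shared_pool_size = 1000L, shared_fraction = 0.1,
                       zipf_exponent = 1.0, genes = 500L,
                       pool = cancer_type,
                       consequence_probs = default_consequence_probs(),
                       seed = 1L) {
  cfg <- list(cancer_type = as.character(cancer_type),
              donors = as.integer(donors),
              burden_mean = as.numeric(burden_mean),
              burden_dispersion = as.numeric(burden_dispersion),
              shared_pool_size = as.integer(shared_pool_size),
              shared_fraction = as.numeric(shared_fraction),
              zipf_exponent = as.numeric(zipf_exponent),
              genes = as.integer(genes),
              pool = as.character(pool),
              consequence_probs = consequence_probs,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (is.na(donors) || donors < 1L) stop("donors must be >= 1")
    if (!is.finite(burden_mean) || burden_mean <= 0) stop("burden_mean must be > 0")
    if (!is.finite(burden_dispersion) || burden_dispersion <= 0) {
      stop("burden_dispersion must be > 0")
    }
    if (shared_pool_size < 1L) stop("shared_pool_size must be >= 1")
    if (is.na(shared_fraction) || shared_fraction < 0 || shared_fraction > 1) {
      stop("shared_fraction must be in [0, 1]")
    }
    if (!is.finite(zipf_exponent) || zipf_exponent < 0) {
      stop("zipf_exponent must be >= 0")
    }
    if (genes < 1L) stop("genes must be >= 1")
    p <- consequence_probs
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("consequence_probs must be a named non-negative vector summing to 1")
    }
  })
  invisible(cfg)
}

#' Default consequence class mix for simulated catalogs
#'
#' Mostly coding classes with a small non-exonic admixture so that the
#' exonic consequence filter has observable effect on simulated data.
#'
#' @return Named probability vector.
#' @export
default_consequence_probs <- function() {
  c(missense_variant = 0.55, synonymous_variant = 0.25,
    stop_gained = 0.05, frameshift_variant = 0.04,
    inframe_deletion = 0.02, inframe_insertion = 0.02,
    splice_region_variant = 0.02, intron_variant = 0.05)
}

# pool offsets are spaced by a prime so gene assignment (start mod genes)
# is rotated between pools rather than replicated
POOL_STRIDE <- 10000019L

zipf_weights <- function(n, exponent) {
  w <- seq_len(n)^(-exponent)
  w / sum(w)
}

gene_label <- function(start, genes) {
  sprintf("G%05d", ((start - 1L) %% genes) + 1L)
}

#' Generate a synthetic mutation catalog
#'
#' Draws a donor-level catalog from one or several [sim_config()]s under
#' a single RNG stream; identical (configs, seed) pairs produce identical
#' catalogs. Hotspot pools are instantiated first (in sorted label order)
#' so that pool contents do not depend on the order or number of cancer
#' types using them. Drawn calls are deduplicated per (donor, mutation):
#' a donor sampling the same hotspot twice carries it once.
#'
#' @param configs a `sim_config` or list of them (one per cancer type).
#' @param seed integer seed; defaults to the first config's `seed`.
#' @return A [new_catalog()] whose roster contains every configured donor,
#'   including donors that drew a zero burden. The pre-deduplication
#'   per-donor draw counts are attached as attribute `"drawn_burden"` for
#'   conservation audits.
#' @export
generate_catalog <- function(configs, seed = NULL) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1L)
  lapply(configs, validate_sim_config)
  types <- vapply(configs, `[[`, "", "cancer_type")
  if (anyDuplicated(types)) stop("duplicate cancer_type labels in configs")
  pools <- sort(unique(vapply(configs, `[[`, "", "pool")))
  for (p in pools) {
    gs <- unique(vapply(configs[vapply(configs, `[[`, "", "pool") == p],
                        `[[`, 0L, "genes"))
    if (length(gs) > 1L) {
      stop("configs sharing pool '", p, "' must agree on `genes`")
    }
  }
  if (is.null(seed)) seed <- configs[[1L]]$seed
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  # instantiate pool-wide fixed consequences, deterministically by label
  pool_offset <- setNames((match(pools, pools) - 1L) * POOL_STRIDE + 1000L,
                          pools)
  pool_size <- setNames(integer(length(pools)), pools)
  for (cfg in configs) {
    pool_size[cfg$pool] <- max(pool_size[cfg$pool], cfg$shared_pool_size)
  }
  pool_consequence <- lapply(pools, function(p) {
    cfg <- configs[[which(vapply(configs, `[[`, "", "pool") == p)[1L]]]
    sample(names(cfg$consequence_probs), pool_size[p], replace = TRUE,
           prob = cfg$consequence_probs)
  })
  names(pool_consequence) <- pools

  private_counter <- 0L
  parts <- vector("list", length(configs))
  rosters <- vector("list", length(configs))
  drawn <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    donor_ids <- sprintf("%s-D%05d", cfg$cancer_type, seq_len(cfg$donors))
    rosters[[i]] <- data.table(donor_id = donor_ids,
                               cancer_type = cfg$cancer_type)
    burdens <- rnbinom(cfg$donors, size = cfg$burden_dispersion,
                       mu = cfg$burden_mean)
    drawn[[i]] <- data.table(donor_id = donor_ids, drawn_burden = burdens)
    total <- sum(burdens)
    if (total == 0L) next
    donor <- rep(donor_ids, burdens)
    is_shared <- runif(total) < cfg$shared_fraction
    n_sh <- sum(is_shared)
    n_pr <- total - n_sh
    chromosome <- character(total)
    start <- integer(total)
    gene <- character(total)
    consequence <- character(total)
    if (n_sh > 0L) {
      idx <- sample.int(cfg$shared_pool_size, n_sh, replace = TRUE,
                        prob = zipf_weights(cfg$shared_pool_size,
                                            cfg$zipf_exponent))
      s <- pool_offset[cfg$pool] + idx - 1L
      chromosome[is_shared] <- "1"
      start[is_shared] <- s
      gene[is_shared] <- gene_label(s, cfg$genes)
      consequence[is_shared] <- pool_consequence[[cfg$pool]][idx]
    }
    if (n_pr > 0L) {
      s <- private_counter + seq_len(n_pr)
      private_counter <- private_counter + n_pr
      chromosome[!is_shared] <- "2"
      start[!is_shared] <- s
      gene[!is_shared] <- gene_label(
        sample.int(cfg$genes, n_pr, replace = TRUE), cfg$genes)
      consequence[!is_shared] <- sample(names(cfg$consequence_probs), n_pr,
                                        replace = TRUE,
                                        prob = cfg$consequence_probs)
    }
    parts[[i]] <- data.table(donor_id = donor,
                             cancer_type = cfg$cancer_type,
                             chromosome = chromosome, start = start,
                             ref = ifelse(is_shared, "A", "C"),
                             alt = ifelse(is_shared, "G", "T"),
                             consequence = consequence, gene = gene)
  }
  calls <- rbindlist(parts[!vapply(parts, is.null, TRUE)])
  if (nrow(calls) == 0L) calls <- empty_calls()
  out <- new_catalog(calls, roster = rbindlist(rosters))
  # drawn (pre-deduplication) burdens, for conservation audits: total calls
  # can only fall below this when a donor samples the same hotspot twice
  attr(out, "drawn_burden") <- rbindlist(drawn)
  out
}

#' Expected recurrence CCD for a simulated cancer type
#'
#' Closed-form expectation of the mutation-fraction component of the
#' complementary cumulative recurrence distribution under the generative
#' model of [sim_config()]. Each hotspot i is carried by each donor
#' independently with probability `p_i = 1 - G(1 - q_i)`, where `q_i` is
#' the per-draw probability of hotspot i (shared_fraction times its Zipf
#' weight) and `G` is the probability generating function of the
#' negative-binomial burden; recurrence of hotspot i is then
#' Binomial(donors, p_i). Private mutations contribute only to the
#' recurrence-1 class with expected count
#' `donors * burden_mean * (1 - shared_fraction)`. The returned fraction
#' at threshold k is the ratio of expected counts
#' E\[mutations with recurrence >= k\] / E\[observed mutations\].
#'
#' @param config a `sim_config`.
#' @param k_max largest recurrence threshold (default 10).
#' @return data.table with columns `k`, `mutation_fraction`.
#' @export
expected_recurrence_ccd <- function(config, k_max = 10L) {
  validate_sim_config(config)
  w <- zipf_weights(config$shared_pool_size, config$zipf_exponent)
  q <- config$shared_fraction * w
  r <- config$burden_dispersion
  mu <- config$burden_mean
  # negative-binomial PGF evaluated at 1 - q
  pgf <- (r / (r + mu * q))^r
  p <- 1 - pgf
  expected_ccd_from_probs(
    p, config$donors,
    expected_private = config$donors * mu * (1 - config$shared_fraction),
    k_max = k_max)
}

#' Expected recurrence CCD from per-donor inclusion probabilities
#'
#' Workhorse behind [expected_recurrence_ccd()], exposed so expectations
#' can be computed for arbitrary hotspot inclusion probabilities. With
#' `n` donors and inclusion probability `p_i`, hotspot recurrence is
#' Binomial(n, p_i); the expected number of hotspots at recurrence >= k is
#' the sum of the binomial upper tails.
#'
#' @param p vector of per-donor inclusion probabilities, one per hotspot.
#' @param donors number of donors.
#' @param expected_private expected number of recurrence-1 private
#'   mutations added to the k = 1 class and to the denominator.
#' @param k_max largest recurrence threshold.
#' @return data.table with columns `k`, `mutation_fraction`; the fraction
#'   at k = 1 is exactly 1.
#' @export
expected_ccd_from_probs <- function(p, donors, expected_private = 0,
                                    k_max = 10L) {
  stopifnot(all(p >= 0 & p <= 1), donors >= 1, expected_private >= 0)
  k <- seq_len(k_max)
  e_k <- vapply(k, function(kk) {
    sum(pbinom(kk - 1L, donors, p, lower.tail = FALSE))
  }, 0)
  denom <- e_k[1L] + expected_private
  if (denom == 0) stop("model expects no observed mutations")
  data.table(k = k,
             mutation_fraction = (e_k + (k == 1L) * expected_private) / denom)
}

#' Preset simulation panels
#'
#' Documented configurations spanning the burden regimes seen in real
#' pan-cancer catalogs:
#' \describe{
#'   \item{"low-burden"}{one cohort of 130 donors with median exonic
#'     burden ~1 per donor (a chronic-myeloid-disorder-like regime).}
#'   \item{"high-burden"}{one cohort of 320 donors with median burden
#'     ~400 per donor (a melanoma-like regime).}
#'   \item{"pan-mini"}{six cancer types, ~590 donors: two colorectal-like
#'     types sharing a hotspot pool, two liver-like types sharing another,
#'     plus one low- and one high-burden type, for end-to-end runs.}
#'   \item{"pan-scale"}{five types, 650 donors, ~1M drawn calls, for
#'     throughput and conservation checks.}
#' }
#'
#' @param name preset label.
#' @return list of [sim_config()] objects.
#' @export
preset_panel <- function(name) {
  presets <- list(
    "low-burden" = function() list(
      sim_config("LOWB", donors = 130L, burden_mean = 1.5,
                 burden_dispersion = 1.2, shared_pool_size = 300L,
                 shared_fraction = 0.15, zipf_exponent = 1.2,
                 genes = 200L, pool = "lowb")),
    "high-burden" = function() list(
      sim_config("HIGHB", donors = 320L, burden_mean = 430,
                 burden_dispersion = 2.5, shared_pool_size = 2000L,
                 shared_fraction = 0.1, zipf_exponent = 1.1,
                 genes = 500L, pool = "highb")),
    "pan-mini" = function() list(
      sim_config("CRCA", donors = 120L, burden_mean = 90,
                 burden_dispersion = 2, shared_pool_size = 800L,
                 shared_fraction = 0.25, zipf_exponent = 1.3,
                 genes = 400L, pool = "crc"),
      sim_config("CRCB", donors = 60L, burden_mean = 80,
                 burden_dispersion = 2, shared_pool_size = 800L,
                 shared_fraction = 0.25, zipf_exponent = 1.3,
                 genes = 400L, pool = "crc"),
      sim_config("LIVA", donors = 100L, burden_mean = 60,
                 burden_dispersion = 2, shared_pool_size = 800L,
                 shared_fraction = 0.2, zipf_exponent = 1.2,
                 genes = 400L, pool = "liver"),
      sim_config("LIVB", donors = 80L, burden_mean = 70,
                 burden_dispersion = 2, shared_pool_size = 800L,
                 shared_fraction = 0.2, zipf_exponent = 1.2,
                 genes = 400L, pool = "liver"),
      sim_config("LOWB", donors = 130L, burden_mean = 1.5,
                 burden_dispersion = 1.2, shared_pool_size = 300L,
                 shared_fraction = 0.15, zipf_exponent = 1.2,
                 genes = 400L, pool = "lowb"),
      sim_config("HIGHB", donors = 100L, burden_mean = 430,
                 burden_dispersion = 2.5, shared_pool_size = 2000L,
                 shared_fraction = 0.1, zipf_exponent = 1.1,
                 genes = 400L, pool = "highb")),
    "pan-scale" = function() {
      mus <- c(300, 900, 1500, 2100, 2900)
      lapply(seq_along(mus), function(i) {
        sim_config(sprintf("SCL%d", i), donors = 130L, burden_mean = mus[i],
                   burden_dispersion = 3, shared_pool_size = 3000L,
                   shared_fraction = 0.12, zipf_exponent = 1.1,
                   genes = 600L, pool = if (i <= 3L) "scaleA" else "scaleB")
      })
    })
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]()
}

#' Serialize / deserialize a simulation configuration as YAML
#'
#' @param config a `sim_config` or list of them.
#' @param path YAML file path.
#' @return `read_sim_config()` returns a list of `sim_config` objects.
#' @export
write_sim_config <- function(config, path) {
  if (inherits(config, "sim_config")) config <- list(config)
  yaml::write_yaml(lapply(config, function(cfg) {
    cfg <- unclass(cfg)
    cfg$consequence_probs <- as.list(cfg$consequence_probs)
    cfg
  }), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(cfg) {
    cfg$consequence_probs <- unlist(cfg$consequence_probs)
    do.call(sim_config, cfg)
  })
}
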