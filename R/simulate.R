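# Seeded synthetic mitogenome populations, pileup and read simulators with
# truth tracking. The generator emulates the statistical structure the
# pipeline assumes: shared-haplotype partitions, point-heteroplasmy
# prevalence and variant-frequency spectra, length heteroplasmy in the
# catalogued homopolymer regions, optional NUMT spike-ins confined to one
# amplicon, and two-donor mixtures.

.mitohap_env <- new.env(parent = emptyenv())

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

#' Deterministic synthetic rCRS-like reference
#'
#' A fixed 16,569 bp synthetic mitochondrial genome: random background
#' composition with the nine catalogued length-heteroplasmy motifs planted
#' at their reference coordinates (e.g. the 303-315 segment is the
#' 7C-T-5C polycytosine tract), distinct anchor bases flanking each tract,
#' and N at the historical placeholder position 3107. The sequence is the
#' same in every session; it is a synthetic stand-in, not the rCRS.
#'
#' @return A \code{mito_reference} named \code{"chrM_synthetic"}.
#' @export
synthetic_reference <- function() {
  if (!is.null(.mitohap_env$reference)) return(.mitohap_env$reference)
  bases <- with_preserved_rng({
    set.seed(165690L)
    sample(BASES, RCRS_LENGTH, replace = TRUE,
           prob = c(0.31, 0.31, 0.13, 0.25))
  })
  plant <- function(at, s) {
    sc <- strsplit(s, "")[[1L]]
    bases[at:(at + length(sc) - 1L)] <<- sc
  }
  plant(302L, "A"); plant(303L, "CCCCCCCTCCCCC"); plant(316L, "G")
  plant(451L, "A"); plant(452L, "CCCCCCCCCCCC"); plant(464L, "T")
  plant(511L, "GT"); plant(513L, "ACACACACACAC"); plant(525L, "TG")
  plant(564L, "A"); plant(565L, "CCCCCCCCC"); plant(574L, "T")
  plant(955L, "A"); plant(956L, "CCCCCCCCCCC"); plant(967L, "T")
  plant(5890L, "A"); plant(5891L, "CCCCCCCCC"); plant(5900L, "T")
  plant(8269L, "G"); plant(8270L, "CACCCCCTCTACCCCCTCTA"); plant(8290L, "G")
  plant(12417L, "C"); plant(12418L, "AAAAAAAA"); plant(12426L, "G")
  plant(16179L, "C"); plant(16180L, "AAAACCCCCTCCCC"); plant(16194L, "A")
  bases[3107L] <- "N"
  ref <- mito_reference(paste0(bases, collapse = ""), "chrM_synthetic")
  .mitohap_env$reference <- ref
  ref
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: a 28\%
#' point-heteroplasmy carrier rate with 1/2/3 PHPs split 80.8/16.4/2.7,
#' a folded variant-frequency spectrum concentrated at low frequencies
#' (32\% of mass in 5-10\%, 47.5\% below 15\%), 95\% transitions with
#' hotspot weighting, per-region length-heteroplasmy rates led by the
#' HVII tract (86.9\%), 1000x mean depth and 0.5\% base error.
#'
#' @param seed Seed controlling every random choice of the generator.
#' @param n_individuals Number of samples.
#' @param partition Optional integer vector of haplotype class sizes
#'   (must sum to \code{n_individuals}); default all-singleton.
#' @param n_mutations_mean Mean substitutions per haplotype (Poisson).
#' @param ts_tv_ratio Transition/transversion count ratio for haplotype
#'   substitutions.
#' @param php_individual_rate Fraction of individuals carrying >= 1 PHP.
#' @param php_count_probs Probabilities of 1, 2, 3 PHPs given a carrier.
#' @param php_vf_breaks,php_vf_masses Folded variant-frequency histogram of
#'   injected PHPs (bin edges and masses; interior masses interpolate the
#'   published anchors).
#' @param php_variant_major_prob Probability that the non-reference base is
#'   the major base of a PHP.
#' @param php_hotspot_prob Probability that a PHP lands on a known hotspot
#'   (nps 146, 152, 204, 16,093).
#' @param php_transition_fraction Fraction of PHPs that are transitions.
#' @param length_het_rates Named per-region probabilities of length
#'   heteroplasmy.
#' @param length_het_major_shift_prob Probability that the major molecule of
#'   an affected region differs from the reference segment.
#' @param depth_mean Mean per-position read depth (Poisson).
#' @param base_error_rate Per-base sequencing error probability.
#' @param strand_fraction Probability a read is forward-stranded.
#' @param read_length,paired Read model for the read-level simulator.
#' @param numt Optional list(fraction, n_diff_sites, region) describing a
#'   nuclear-insert spike-in confined to the screened amplicon.
#' @param mixture Optional list(minor_fraction, n_diff_sites) describing a
#'   two-donor mixture.
#' @param population Population label stamped on the profiles.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_individuals = 100L, partition = NULL,
                       n_mutations_mean = 30, ts_tv_ratio = 20,
                       php_individual_rate = 0.28,
                       php_count_probs = c(0.808, 0.164, 0.027),
                       php_vf_breaks = seq(0.05, 0.50, by = 0.05),
                       php_vf_masses = c(0.32, 0.155, rep(0.075, 7)),
                       php_variant_major_prob = 0.25,
                       php_hotspot_prob = 0.06,
                       php_transition_fraction = 0.95,
                       length_het_rates = c(
                         "303-315" = 0.869, "452-463" = 0.01,
                         "513-524" = 0.041, "565-573" = 0.079,
                         "956-966" = 0.01, "5891-5899" = 0.01,
                         "8270-8289" = 0.02, "12418-12425" = 0.044,
                         "16180-16193" = 0.198),
                       length_het_major_shift_prob = 0.2,
                       depth_mean = 1000, base_error_rate = 0.005,
                       strand_fraction = 0.5, read_length = 150L,
                       paired = TRUE, numt = NULL, mixture = NULL,
                       population = "SIM") {
  if (!is.null(partition) && sum(partition) != n_individuals) {
    stop("partition sums to ", sum(partition), ", not n_individuals = ",
         n_individuals)
  }
  php_count_probs <- php_count_probs / sum(php_count_probs)
  php_vf_masses <- php_vf_masses / sum(php_vf_masses)
  stopifnot(length(php_vf_masses) == length(php_vf_breaks) - 1L,
            php_individual_rate >= 0, php_individual_rate <= 1,
            depth_mean > 0, base_error_rate >= 0, base_error_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

PHP_HOTSPOTS <- c(146L, 152L, 204L, 16093L)

transition_of <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[[base]]
}

# positions eligible for simulated substitutions/PHPs: outside the
# length-heteroplasmy tracts and off the N placeholder
eligible_positions <- function(reference, catalog) {
  lh <- positions_in(length_het_intervals(catalog))
  setdiff(seq_len(reference$length), c(lh, which_n_sites(
    reference, rbind(c(1L, reference$length)))))
}

random_alt <- function(ref, transition_fraction, n = length(ref)) {
  ts <- stats::runif(n) < transition_fraction
  alt <- character(n)
  alt[ts] <- vapply(ref[ts], transition_of, "")
  for (i in which(!ts)) {
    tv <- setdiff(BASES, c(ref[i], transition_of(ref[i])))
    alt[i] <- sample(tv, 1L)
  }
  alt
}

# one extra / one fewer unit of the longest single-base run in a segment
motif_unit_variants <- function(segment) {
  r <- rle(strsplit(segment, "")[[1L]])
  k <- which.max(r$lengths)
  end_off <- cumsum(r$lengths)[k]
  base <- r$values[k]
  ins <- paste0(substr(segment, 1L, end_off), base,
                substr(segment, end_off + 1L, nchar(segment)))
  del <- if (r$lengths[k] > 1L) {
    paste0(substr(segment, 1L, end_off - 1L),
           substr(segment, end_off + 1L, nchar(segment)))
  } else NA_character_
  list(insertion = ins, deletion = del)
}

#' Simulate a population of mitogenome haplotypes with truth
#'
#' Haplotypes are drawn as independent substitution sets (a star phylogeny);
#' an explicit partition reproduces shared-haplotype class structures. PHPs
#' are injected per the configured prevalence, count and folded-VF spectra
#' with hotspot weighting, and length-heteroplasmy truth (per-region motif
#' mixtures) is attached. The truth set is fully determined by the config
#' seed and regenerates identically.
#'
#' @param config A \code{sim_config}.
#' @param reference A \code{mito_reference}.
#' @param catalog A \code{region_catalog}.
#' @return List with \code{profiles} (list of \code{mito_profile}) and
#'   \code{truth} (per-sample variant/PHP/motif-mixture records).
#' @export
simulate_population <- function(config, reference = synthetic_reference(),
                                catalog = region_catalog()) {
  set.seed(config$seed)
  n <- config$n_individuals
  sizes <- if (is.null(config$partition)) rep(1L, n) else
    as.integer(config$partition)
  pool <- eligible_positions(reference, catalog)
  keys <- character(0)
  class_variants <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    repeat {
      k <- max(1L, stats::rpois(1L, config$n_mutations_mean))
      p <- sort(sample(pool, k))
      rb <- ref_base(reference, p)
      alt <- random_alt(rb, config$ts_tv_ratio / (config$ts_tv_ratio + 1))
      key <- paste(rb, p, alt, collapse = " ")
      if (!key %in% keys) {
        keys <- c(keys, key)
        class_variants[[ci]] <- do.call(rbind, lapply(seq_along(p),
          function(i) new_variant(p[i], "substitution", ref = rb[i],
                                  call = alt[i], major_freq = 1,
                                  major_base = alt[i])))
        break
      }
    }
  }
  assignment <- rep(seq_along(sizes), sizes)
  profiles <- vector("list", n)
  truth <- vector("list", n)
  regions <- names(catalog$length_het_regions)
  for (s in seq_len(n)) {
    id <- sprintf("%s%04d", config$population, s)
    v <- class_variants[[assignment[s]]]
    php <- empty_variants()
    if (stats::runif(1L) < config$php_individual_rate) {
      n_php <- sample(1:3, 1L, prob = config$php_count_probs)
      taken <- v$position
      for (k in seq_len(n_php)) {
        hot <- setdiff(PHP_HOTSPOTS, taken)
        p <- if (length(hot) && stats::runif(1L) < config$php_hotspot_prob) {
          sample(hot, 1L)
        } else {
          repeat {
            cand <- sample(pool, 1L)
            if (!cand %in% taken) break
          }
          cand
        }
        taken <- c(taken, p)
        rb <- ref_base(reference, p)
        alt <- random_alt(rb, config$php_transition_fraction, 1L)
        bin <- sample(seq_along(config$php_vf_masses), 1L,
                      prob = config$php_vf_masses)
        folded <- stats::runif(1L, config$php_vf_breaks[bin],
                               config$php_vf_breaks[bin + 1L])
        vf <- if (stats::runif(1L) < config$php_variant_major_prob) {
          1 - folded
        } else {
          folded
        }
        php <- rbind(php, new_variant(
          p, "substitution", ref = rb, call = iupac_code_for(rb, alt),
          major_freq = max(vf, 1 - vf),
          major_base = if (vf > 0.5) alt else rb))
      }
    }
    lh_truth <- list()
    lh_variants <- empty_variants()
    for (r in regions) {
      rate <- config$length_het_rates[[r]]
      if (is.na(rate) || stats::runif(1L) >= rate) next
      iv <- catalog$length_het_regions[[r]]
      segment <- substr(reference$sequence, iv[1L], iv[2L])
      alt_m <- motif_unit_variants(segment)
      other <- if (!is.na(alt_m$deletion) && stats::runif(1L) < 0.5) {
        alt_m$deletion
      } else {
        alt_m$insertion
      }
      minor_frac <- stats::runif(1L, 0.15, 0.45)
      if (stats::runif(1L) < config$length_het_major_shift_prob) {
        mix <- stats::setNames(c(1 - minor_frac, minor_frac),
                               c(other, segment))
        dv <- motif_variants(other, iv[1L], iv[2L], reference)
        lh_variants <- rbind(lh_variants, dv)
      } else {
        mix <- stats::setNames(c(1 - minor_frac, minor_frac),
                               c(segment, other))
      }
      lh_truth[[r]] <- mix
    }
    prof <- mito_profile(id, rbind(v, php, lh_variants),
                         haplogroup = NA_character_,
                         population = config$population,
                         source = "simulated")
    profiles[[s]] <- prof
    truth[[s]] <- list(sample_id = id, class = assignment[s],
                       variants = v, php = php, length_het = lh_truth)
  }
  names(truth) <- vapply(truth, `[[`, "", "sample_id")
  list(profiles = profiles,
       truth = list(samples = truth, partition = sizes, seed = config$seed))
}

#' Build a sample set with a prescribed haplotype-class composition
#'
#' Instantiates \code{n} synthetic profiles whose haplotype keys (under
#' default comparison options) form exactly the requested partition:
#' the given shared-class sizes plus singletons. Used to reproduce printed
#' summary-statistic rows from their compositions.
#'
#' @param n Sample size.
#' @param shared_sizes Integer vector of class sizes >= 2 (may be empty).
#' @param seed Seed for haplotype generation.
#' @param population Population label.
#' @return List of \code{mito_profile} objects.
#' @export
make_table6_fixture <- function(n, shared_sizes = integer(0), seed = 1L,
                                population = "SIM") {
  shared_sizes <- as.integer(shared_sizes)
  if (any(shared_sizes < 2L)) stop("shared class sizes must be >= 2")
  n_singletons <- n - sum(shared_sizes)
  if (n_singletons < 0L) stop("shared classes exceed the sample size")
  cfg <- sim_config(
    seed = seed, n_individuals = as.integer(n),
    partition = c(shared_sizes, rep(1L, n_singletons)),
    php_individual_rate = 0,
    length_het_rates = stats::setNames(
      rep(0, 9L), names(region_catalog()$length_het_regions)),
    population = population
  )
  simulate_population(cfg)$profiles
}

# ---- Pileup-level simulator ----------------------------------------------

# per-position allele probabilities (A,C,G,T,del) implied by a profile
allele_prob_matrix <- function(profile, reference, pos) {
  n <- length(pos)
  P <- matrix(0, n, 5L)
  refi <- match(ref_base(reference, pos), BASES)
  known <- !is.na(refi)
  P[cbind(which(known), refi[known])] <- 1
  P[!known, 1:4] <- 0.25  # N placeholder: composition is arbitrary
  v <- profile$variants
  v <- v[v$position %in% pos & v$kind != "insertion", , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    row <- match(v$position[i], pos)
    P[row, ] <- 0
    if (v$kind[i] == "deletion") {
      P[row, 5L] <- 1
    } else if (v$is_php[i]) {
      pair <- iupac_bases(v$call[i])
      maj <- v$major_base[i]
      if (is.na(maj)) maj <- pair[1L]
      minor <- setdiff(pair, maj)
      P[row, match(maj, BASES)] <- v$major_freq[i]
      P[row, match(minor, BASES)] <- 1 - v$major_freq[i]
    } else {
      P[row, match(v$call[i], BASES)] <- 1
    }
  }
  P
}

#' Simulate a per-position pileup for a profile
#'
#' Fast column-level simulator: depth is Poisson, allele counts multinomial
#' around the profile's allele frequencies (fixed variants at 1, PHPs at
#' their truth frequency), sequencing error redistributes mass uniformly
#' over the other bases, and counts are split binomially between strands.
#' Optional second-donor mixing and NUMT spike-ins perturb the frequency
#' vector before sampling. Insertion variants produce insertion
#' observations at their anchors; length-heteroplasmy motif mixtures are a
#' read-level phenomenon and are not modelled here (use
#' \code{\link{simulate_reads}}).
#'
#' @param profile A \code{mito_profile} (the truth haplotype).
#' @param reference A \code{mito_reference}.
#' @param config A \code{sim_config} (depth, error, strand fraction; its
#'   \code{mixture}/\code{numt} entries activate the corresponding
#'   perturbations).
#' @param range Interval matrix or length-2 vector (default whole genome).
#' @param minor_profile Second-donor profile for mixtures.
#' @param seed Optional seed.
#' @return A \code{mito_pileup}; NUMT spike-in truth (if any) is attached as
#'   attribute \code{numt_truth}.
#' @export
simulate_pileup <- function(profile, reference = synthetic_reference(),
                            config = sim_config(), range = NULL,
                            minor_profile = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(range)) range <- rbind(c(1L, reference$length))
  if (is.null(dim(range))) range <- matrix(as.integer(range), ncol = 2L)
  pos <- positions_in(range)
  n <- length(pos)
  P <- allele_prob_matrix(profile, reference, pos)
  if (!is.null(config$mixture) && !is.null(minor_profile)) {
    mf <- config$mixture$minor_fraction
    P <- (1 - mf) * P + mf * allele_prob_matrix(minor_profile, reference, pos)
  }
  numt_truth <- NULL
  if (!is.null(config$numt)) {
    region <- config$numt$region
    if (is.null(region)) region <- region_catalog()$numt_screen_region
    if (is.null(dim(region))) region <- matrix(as.integer(region), ncol = 2L)
    cand <- which(in_intervals(pos, region))
    ns <- min(config$numt$n_diff_sites, length(cand))
    sel <- sort(sample(cand, ns))
    frac <- config$numt$fraction
    rb <- ref_base(reference, pos[sel])
    alt <- vapply(rb, transition_of, "")
    for (k in seq_along(sel)) {
      P[sel[k], ] <- (1 - frac) * P[sel[k], ]
      ai <- match(alt[k], BASES)
      P[sel[k], ai] <- P[sel[k], ai] + frac
    }
    numt_truth <- data.frame(position = pos[sel], base = alt,
                             fraction = frac, stringsAsFactors = FALSE)
  }
  e <- config$base_error_rate
  base_mass <- rowSums(P[, 1:4, drop = FALSE])
  Pe <- P
  Pe[, 1:4] <- P[, 1:4] * (1 - e - e / 3) + (e / 3) * base_mass
  depth <- stats::rpois(n, config$depth_mean)
  counts <- matrix(0L, n, 5L)
  remaining <- depth
  pleft <- rowSums(Pe)
  for (a in 1:5) {
    pa <- ifelse(pleft > 0, pmin(Pe[, a] / pleft, 1), 0)
    counts[, a] <- stats::rbinom(n, remaining, pa)
    remaining <- remaining - counts[, a]
    pleft <- pleft - Pe[, a]
  }
  fwd <- matrix(stats::rbinom(5L * n, counts, config$strand_fraction), n, 5L)
  cm <- matrix(0L, reference$length, 10L)
  cm[pos, 1:5] <- fwd
  cm[pos, 6:10] <- counts - fwd
  ins <- empty_insertions()
  vi <- profile$variants[profile$variants$kind == "insertion", , drop = FALSE]
  if (nrow(vi)) {
    for (p in unique(vi$position)) {
      if (!p %in% pos) next
      g <- vi[vi$position == p, , drop = FALSE]
      motif <- paste0(g$call[order(g$insert_index)], collapse = "")
      d <- depth[match(p, pos)]
      tot <- stats::rbinom(1L, d, (1 - e)^nchar(motif))
      f <- stats::rbinom(1L, tot, config$strand_fraction)
      ins <- rbind(ins, data.frame(position = p, motif = motif, fwd = f,
                                   rev = tot - f, stringsAsFactors = FALSE))
    }
  }
  pl <- new_pileup(cm, ins, reference)
  attr(pl, "numt_truth") <- numt_truth
  pl
}

# ---- Read-level simulator -------------------------------------------------

# haplotype block: parallel char / reference-position vectors over an
# interval, with substitutions applied, insertions as NA-refpos chars and
# deletions removed; PHP positions carry the major base (minor bases are
# sampled per read)
haplotype_block <- function(profile, reference, interval,
                            php_resolution = "major_or_ref") {
  s <- interval[1L]; e <- interval[2L]
  chars <- strsplit(substr(reference$sequence, s, e), "")[[1L]]
  refpos <- s:e
  v <- profile$variants
  v <- v[v$position >= s & v$position <= e, , drop = FALSE]
  keep <- rep(TRUE, length(chars))
  ins_after <- vector("list", length(chars))
  for (i in seq_len(nrow(v))) {
    off <- v$position[i] - s + 1L
    if (v$kind[i] == "substitution") {
      if (v$is_php[i]) {
        mb <- v$major_base[i]
        chars[off] <- if (is.na(mb)) v$ref[i] else mb
      } else {
        chars[off] <- v$call[i]
      }
    } else if (v$kind[i] == "deletion") {
      keep[off] <- FALSE
    } else {
      ins_after[[off]] <- c(ins_after[[off]], v$call[i])
    }
  }
  out_chars <- character(0)
  out_pos <- integer(0)
  for (off in seq_along(chars)) {
    if (keep[off]) {
      out_chars <- c(out_chars, chars[off])
      out_pos <- c(out_pos, refpos[off])
    }
    if (!is.null(ins_after[[off]])) {
      out_chars <- c(out_chars, ins_after[[off]])
      out_pos <- c(out_pos, rep(NA_integer_, length(ins_after[[off]])))
    }
  }
  list(chars = out_chars, refpos = out_pos, start = s, end = e)
}

cigar_from_refpos <- function(refpos) {
  n <- length(refpos)
  if (!anyNA(refpos) && refpos[n] - refpos[1L] == n - 1L) {
    return(paste0(n, "M"))
  }
  ops <- character(0); lens <- integer(0)
  push <- function(op, len) {
    k <- length(ops)
    if (k && ops[k] == op) {
      lens[k] <<- lens[k] + len
    } else {
      ops <<- c(ops, op); lens <<- c(lens, len)
    }
  }
  last_ref <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(refpos[i])) {
      push("I", 1L)
    } else {
      if (!is.na(last_ref) && refpos[i] > last_ref + 1L) {
        push("D", refpos[i] - last_ref - 1L)
      }
      push("M", 1L)
      last_ref <- refpos[i]
    }
  }
  paste0(lens, ops, collapse = "")
}

#' Simulate aligned reads for a profile
#'
#' Reads are drawn pre-aligned from the sample's haplotype: uniform start
#' positions at Poisson-controlled depth, per-read strand and base errors,
#' per-read minor-base sampling at PHP positions, and per-read motif choice
#' in length-heteroplasmic regions according to the truth motif mixture.
#' Qualities are constant Q40. Reads are emitted in post-trim coordinates
#' (the trimming contract applies upstream of alignment and is tested on
#' hand-built reads).
#'
#' @param profile A \code{mito_profile}.
#' @param reference A \code{mito_reference}.
#' @param config A \code{sim_config}.
#' @param range Length-2 interval to cover (default whole genome).
#' @param lh_truth Optional named list of per-region motif mixtures (motif
#'   string -> fraction), as produced by \code{\link{simulate_population}}.
#' @param minor_profile Optional second donor; \code{config$mixture}
#'   controls the minor fraction.
#' @param n_reads Override the Poisson-derived read count.
#' @param seed Optional seed.
#' @param catalog A \code{region_catalog}.
#' @return A \code{read_stack}.
#' @export
simulate_reads <- function(profile, reference = synthetic_reference(),
                           config = sim_config(),
                           range = c(1L, reference$length), lh_truth = NULL,
                           minor_profile = NULL, n_reads = NULL, seed = NULL,
                           catalog = region_catalog()) {
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(range[1L]); e <- as.integer(range[2L])
  span <- e - s + 1L
  rl <- config$read_length
  if (is.null(n_reads)) {
    n_reads <- stats::rpois(1L, config$depth_mean * span / rl)
  }
  ext_end <- min(e + rl, s + span + rl)
  build_blocks <- function(prof) {
    base <- haplotype_block(prof, reference, c(s, min(ext_end,
                                                      reference$length)))
    region_alts <- list()
    if (!is.null(lh_truth)) {
      for (r in names(lh_truth)) {
        iv <- catalog$length_het_regions[[r]]
        if (iv[1L] < s || iv[2L] > ext_end) next
        motifs <- names(lh_truth[[r]])
        region_alts[[r]] <- list(
          interval = iv, motifs = motifs, probs = unname(lh_truth[[r]])
        )
      }
    }
    list(base = base, region_alts = region_alts)
  }
  blocks <- build_blocks(profile)
  blocks_minor <- if (!is.null(minor_profile)) build_blocks(minor_profile)
  mf <- if (!is.null(config$mixture)) config$mixture$minor_fraction else 0
  php <- profile$variants[profile$variants$is_php, , drop = FALSE]
  reads <- vector("list", n_reads)
  starts_ref <- sample(seq.int(s, e), n_reads, replace = TRUE)
  strands <- ifelse(stats::runif(n_reads) < config$strand_fraction, "+", "-")
  for (i in seq_len(n_reads)) {
    from_minor <- mf > 0 && stats::runif(1L) < mf
    bl <- if (from_minor) blocks_minor else blocks
    block <- bl$base
    # block index of the first aligned base at or after the start position
    bi <- which(!is.na(block$refpos) & block$refpos >= starts_ref[i])[1L]
    if (is.na(bi)) next
    idx <- seq.int(bi, min(bi + rl - 1L, length(block$chars)))
    chars <- block$chars[idx]
    refpos <- block$refpos[idx]
    # splice region motifs chosen per read
    for (r in names(bl$region_alts)) {
      ra <- bl$region_alts[[r]]
      iv <- ra$interval
      cover <- !is.na(refpos) & refpos >= iv[1L] & refpos <= iv[2L]
      if (!any(cover)) next
      spans <- any(refpos == iv[1L] - 1L, na.rm = TRUE) ||
        refpos[1L] < iv[1L]
      motif <- sample(ra$motifs, 1L, prob = ra$probs)
      segment <- substr(reference$sequence, iv[1L], iv[2L])
      if (identical(motif, segment)) next
      # rebuild the covered stretch from the chosen motif
      pre <- which(!is.na(refpos) & refpos < iv[1L])
      post <- which(!is.na(refpos) & refpos > iv[2L])
      mot_chars <- strsplit(motif, "")[[1L]]
      mal <- align_motif(motif, segment)
      mot_pos <- ifelse(is.na(mal$map), NA_integer_, iv[1L] + mal$map - 1L)
      if (length(pre) && length(post)) {
        chars <- c(chars[pre], mot_chars, chars[post])
        refpos <- c(refpos[pre], mot_pos, refpos[post])
      } else if (length(pre)) {
        # read ends inside the region: keep a clipped motif prefix
        kept <- length(which(cover))
        chars <- c(chars[pre], mot_chars[seq_len(min(kept,
                                                     length(mot_chars)))])
        refpos <- c(refpos[pre], mot_pos[seq_len(min(kept,
                                                     length(mot_chars)))])
      } else if (length(post)) {
        kept <- length(which(cover))
        tailidx <- seq.int(max(1L, length(mot_chars) - kept + 1L),
                           length(mot_chars))
        chars <- c(mot_chars[tailidx], chars[post])
        refpos <- c(mot_pos[tailidx], refpos[post])
      }
    }
    # per-read PHP minor bases
    if (nrow(php)) {
      for (k in seq_len(nrow(php))) {
        hit <- which(refpos == php$position[k])
        if (length(hit) != 1L) next
        maj <- php$major_base[k]
        if (is.na(maj)) maj <- php$ref[k]
        minor <- setdiff(iupac_bases(php$call[k]), maj)
        if (stats::runif(1L) < 1 - php$major_freq[k]) chars[hit] <- minor
      }
    }
    # sequencing errors
    if (config$base_error_rate > 0) {
      err <- which(stats::runif(length(chars)) < config$base_error_rate)
      for (j in err) {
        chars[j] <- sample(setdiff(BASES, chars[j]), 1L)
      }
    }
    # drop unanchored leading/trailing insertions
    first_m <- which(!is.na(refpos))[1L]
    last_m <- max(which(!is.na(refpos)))
    keep <- first_m:last_m
    chars <- chars[keep]; refpos <- refpos[keep]
    reads[[i]] <- list(
      read_id = sprintf("%s_r%06d", profile$sample_id, i),
      start = circular_position(refpos[first_m - first_m + 1L],
                                reference$length),
      strand = strands[i], paired = config$paired,
      seq = paste0(chars, collapse = ""),
      qual = strrep("I", length(chars)),
      cigar = cigar_from_refpos(refpos)
    )
  }
  reads <- reads[!vapply(reads, is.null, TRUE)]
  if (!length(reads)) {
    return(read_stack(data.frame(
      read_id = character(), start = integer(), strand = character(),
      paired = logical(), seq = character(), qual = character(),
      cigar = character(), stringsAsFactors = FALSE)))
  }
  read_stack(data.frame(
    read_id = vapply(reads, `[[`, "", "read_id"),
    start = vapply(reads, `[[`, 0L, "start"),
    strand = vapply(reads, `[[`, "", "strand"),
    paired = vapply(reads, `[[`, TRUE, "paired"),
    seq = vapply(reads, `[[`, "", "seq"),
    qual = vapply(reads, `[[`, "", "qual"),
    cigar = vapply(reads, `[[`, "", "cigar"),
    stringsAsFactors = FALSE
  ))
}
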