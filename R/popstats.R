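# Haplotype keying under the forensic comparison rules, random match
# probabilities and haplotype diversity, Kimura 2-parameter distances,
# pairwise Phi-st with permutation tests, principal coordinate analysis,
# PHP characterization and continental ancestry tabulation.

#' Options governing haplotype comparisons
#'
#' @param range \code{"whole_mitogenome"}, \code{"control_region"} or
#'   \code{"custom"} (supply \code{custom_intervals}).
#' @param php_mode \code{"differences"} (PHPs compared literally by their
#'   IUPAC code) or \code{"ignored"} (PHP variants dropped before keying, so
#'   a heteroplasmic sample merges with the matching non-heteroplasmic
#'   haplotype).
#' @param ignored_insertion_positions Insertion anchors ignored in
#'   comparisons (default: the ten common length-heteroplasmy positions).
#' @param custom_intervals Interval matrix, for \code{range = "custom"}.
#' @param catalog A \code{region_catalog}.
#' @return List of class \code{comparison_options}.
#' @export
comparison_options <- function(range = c("whole_mitogenome", "control_region",
                                         "custom"),
                               php_mode = c("differences", "ignored"),
                               ignored_insertion_positions = NULL,
                               custom_intervals = NULL,
                               catalog = region_catalog()) {
  range <- match.arg(range)
  php_mode <- match.arg(php_mode)
  if (is.null(ignored_insertion_positions)) {
    ignored_insertion_positions <- catalog$ignored_insertion_positions
  }
  intervals <- switch(range,
    whole_mitogenome = catalog$whole_mitogenome,
    control_region = catalog$control_region,
    custom = {
      if (is.null(custom_intervals)) stop("custom range needs intervals")
      custom_intervals
    }
  )
  structure(list(range = range, intervals = intervals, php_mode = php_mode,
                 ignored_insertion_positions =
                   as.integer(ignored_insertion_positions)),
            class = "comparison_options")
}

#' Canonical haplotype key for comparisons
#'
#' Variants outside the comparison range are dropped, insertions at the
#' ignored common length-heteroplasmy positions are dropped, and PHPs are
#' either kept literally or dropped per \code{php_mode}; the remainder is
#' sorted and joined into a deterministic string.
#'
#' @param profile A \code{mito_profile}.
#' @param options A \code{comparison_options}.
#' @return Character key.
#' @export
haplotype_key <- function(profile, options = comparison_options()) {
  v <- profile$variants
  v <- v[in_intervals(v$position, options$intervals), , drop = FALSE]
  drop_ins <- v$kind == "insertion" &
    v$position %in% options$ignored_insertion_positions
  v <- v[!drop_ins, , drop = FALSE]
  if (options$php_mode == "ignored") v <- v[!v$is_php, , drop = FALSE]
  v <- order_variants(v)
  paste(format_variant(v, deletion_style = "DEL"), collapse = " ")
}

#' Haplotype class counts for a sample set
#'
#' Groups profiles by haplotype key and records the class-size partition
#' from which the match statistics derive.
#'
#' @param profiles List of \code{mito_profile} objects, or an integer vector
#'   of class sizes (a partition) to wrap directly.
#' @param options A \code{comparison_options} (ignored for a partition).
#' @return List of class \code{haplotype_counts} with \code{n},
#'   \code{sizes} (decreasing), \code{distinct} and \code{unique}.
#' @export
haplotype_counts <- function(profiles, options = comparison_options()) {
  sizes <- if (is.numeric(profiles)) {
    as.integer(profiles)
  } else {
    keys <- vapply(profiles, haplotype_key, "", options = options)
    as.integer(table(keys))
  }
  stopifnot(all(sizes >= 1L))
  sizes <- sort(sizes, decreasing = TRUE)
  structure(list(n = sum(sizes), sizes = sizes, distinct = length(sizes),
                 unique = sum(sizes == 1L)), class = "haplotype_counts")
}

#' @export
print.haplotype_counts <- function(x, ...) {
  cat("<haplotype_counts> n = ", x$n, ", ", x$distinct, " haplotypes (",
      x$unique, " unique)\n", sep = "")
  invisible(x)
}

#' Observed random match probability
#'
#' The probability that two individuals drawn with replacement share a
#' haplotype: sum over classes of (k/n)^2.
#'
#' @param counts A \code{haplotype_counts}.
#' @return Fraction in (0, 1].
#' @export
observed_rmp <- function(counts) {
  sum((counts$sizes / counts$n)^2)
}

#' Empirical random match probability
#'
#' The fraction of matching pairs among all ordered pairs of distinct
#' individuals: sum k(k-1) / (n(n-1)).
#'
#' @param counts A \code{haplotype_counts}.
#' @return Fraction in [0, 1].
#' @export
empirical_rmp <- function(counts) {
  if (counts$n < 2L) stop("empirical RMP requires n >= 2")
  sum(counts$sizes * (counts$sizes - 1)) / (counts$n * (counts$n - 1))
}

#' Haplotype diversity
#'
#' The small-sample-corrected probability that two sampled haplotypes
#' differ: (n/(n-1)) (1 - sum p_i^2).
#'
#' @param counts A \code{haplotype_counts}.
#' @return Value in [0, 1].
#' @export
haplotype_diversity <- function(counts) {
  if (counts$n < 2L) stop("haplotype diversity requires n >= 2")
  counts$n / (counts$n - 1) * (1 - observed_rmp(counts))
}

# half-up rounding as used for display of percentages/diversity
round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summary statistics for a sample set
#'
#' @param counts A \code{haplotype_counts}.
#' @return Data frame with n, haplotype counts, observed and empirical RMP
#'   (percent, two decimals) and haplotype diversity (four decimals),
#'   alongside the unrounded values.
#' @export
summary_statistics <- function(counts) {
  obs <- observed_rmp(counts)
  emp <- empirical_rmp(counts)
  div <- haplotype_diversity(counts)
  data.frame(
    n = counts$n, total_haplotypes = counts$distinct,
    unique_haplotypes = counts$unique,
    observed_rmp_pct = round_half_up(100 * obs, 2),
    empirical_rmp_pct = round_half_up(100 * emp, 2),
    haplotype_diversity = round_half_up(div, 4),
    observed_rmp = obs, empirical_rmp = emp, diversity_raw = div
  )
}

#' Recover a haplotype-class partition from printed summary statistics
#'
#' Exhaustively enumerates partitions of \code{n} individuals into
#' \code{distinct} classes with \code{unique} singletons and keeps those
#' whose observed RMP, empirical RMP (both as percentages rounded to two
#' decimals) and haplotype diversity (rounded to four decimals) match the
#' supplied printed values. Used to reconstruct sample-set compositions that
#' the printed counts alone do not force.
#'
#' @param n Sample size.
#' @param distinct Number of haplotype classes.
#' @param unique Number of singleton classes.
#' @param observed_pct,empirical_pct Printed RMPs in percent (2 d.p.);
#'   \code{NA} to skip a constraint.
#' @param diversity Printed diversity (4 d.p.); \code{NA} to skip.
#' @return List of matching partitions (integer vectors of class sizes).
#' @export
resolve_partition <- function(n, distinct, unique, observed_pct = NA,
                              empirical_pct = NA, diversity = NA) {
  m <- n - unique
  k <- distinct - unique
  stopifnot(m >= 0L, k >= 0L, m >= 2L * k)
  parts <- partitions_min2(m, k)
  out <- list()
  for (p in parts) {
    sizes <- c(rep(1L, unique), p)
    h <- haplotype_counts(sizes)
    ok <- TRUE
    if (!is.na(observed_pct)) {
      ok <- ok && round_half_up(100 * observed_rmp(h), 2) == observed_pct
    }
    if (!is.na(empirical_pct)) {
      ok <- ok && round_half_up(100 * empirical_rmp(h), 2) == empirical_pct
    }
    if (!is.na(diversity)) {
      ok <- ok && round_half_up(haplotype_diversity(h), 4) == diversity
    }
    if (ok) out[[length(out) + 1L]] <- sizes
  }
  out
}

# partitions of m into exactly k parts, each part >= 2, non-increasing
partitions_min2 <- function(m, k, max_part = m) {
  if (k == 0L) return(if (m == 0L) list(integer(0)) else list())
  out <- list()
  for (first in seq.int(min(max_part, m - 2L * (k - 1L)), 2L)) {
    for (rest in partitions_min2(m - first, k - 1L, first)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# ---- Kimura 2-parameter distance -----------------------------------------

TRANSITION_PAIRS <- c("AG", "GA", "CT", "TC")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)) with P and Q the transition and
#' transversion fractions over compared sites. Sites where either sequence
#' carries a character outside A/C/G/T (N, ambiguity codes) are skipped.
#'
#' @param seq_a,seq_b Equal-length base strings.
#' @return Nonnegative distance.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must have equal length for K2P comparison")
  }
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  keep <- a %in% BASES & b %in% BASES
  k2p_from_counts(
    ts = sum(keep & paste0(a, b) %in% TRANSITION_PAIRS),
    tv = sum(keep & a != b & !paste0(a, b) %in% TRANSITION_PAIRS),
    sites = sum(keep)
  )
}

k2p_from_counts <- function(ts, tv, sites) {
  if (sites == 0L) stop("no comparable sites")
  P <- ts / sites
  Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance saturated (P = ", signif(P, 4), ", Q = ",
         signif(Q, 4), ")")
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Kimura 2-parameter distance between two profiles
#'
#' Profiles are compared sparsely over the reference: indel sites, PHP sites
#' (in either profile) and reference N sites are excluded from the
#' comparable-site total; fixed substitutions supply the transition and
#' transversion counts.
#'
#' @param a,b \code{mito_profile} objects.
#' @param reference A \code{mito_reference}.
#' @param intervals Interval matrix over which to compare (default whole
#'   genome).
#' @return Nonnegative distance.
#' @export
k2p_profile_distance <- function(a, b, reference,
                                 intervals = rbind(c(1L, reference$length))) {
  va <- a$variants[in_intervals(a$variants$position, intervals), ,
                   drop = FALSE]
  vb <- b$variants[in_intervals(b$variants$position, intervals), ,
                   drop = FALSE]
  excluded <- unique(c(
    va$position[va$kind == "deletion" | va$is_php],
    vb$position[vb$kind == "deletion" | vb$is_php],
    which_n_sites(reference, intervals)
  ))
  call_at <- function(v) {
    v <- v[v$kind == "substitution" & !v$is_php, , drop = FALSE]
    stats::setNames(v$call, v$position)
  }
  ca <- call_at(va); cb <- call_at(vb)
  pos <- setdiff(unique(c(names(ca), names(cb))), as.character(excluded))
  total_sites <- sum(intervals[, 2L] - intervals[, 1L] + 1L) -
    sum(in_intervals(excluded, intervals))
  if (!length(pos)) return(k2p_from_counts(0L, 0L, total_sites))
  base_a <- ifelse(pos %in% names(ca), ca[pos], NA)
  base_b <- ifelse(pos %in% names(cb), cb[pos], NA)
  rb <- ref_base(reference, as.integer(pos))
  base_a[is.na(base_a)] <- rb[is.na(base_a)]
  base_b[is.na(base_b)] <- rb[is.na(base_b)]
  diff <- base_a != base_b
  ts <- sum(diff & paste0(base_a, base_b) %in% TRANSITION_PAIRS)
  tv <- sum(diff) - ts
  k2p_from_counts(ts, tv, total_sites)
}

which_n_sites <- function(reference, intervals) {
  cache <- attr(reference, ".n_sites")
  if (is.null(cache)) {
    cache <- as.integer(gregexpr("N", reference$sequence, fixed = TRUE)[[1L]])
    cache <- cache[cache > 0L]
  }
  cache[in_intervals(cache, intervals)]
}

# ---- Pairwise Phi-st with permutation test -------------------------------

# AMOVA decomposition of squared distances for two groups given index sets
phist_from_d2 <- function(d2, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); N <- n1 + n2
  all_idx <- c(idx1, idx2)
  ssd_total <- sum(d2[all_idx, all_idx]) / (2 * N)
  ssd_within <- sum(d2[idx1, idx1]) / (2 * n1) + sum(d2[idx2, idx2]) / (2 * n2)
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - 2)
  n_eff <- (N - (n1^2 + n2^2) / N)  # k - 1 = 1 groups in the denominator
  sigma_a <- (ssd_among - sigma_w) / n_eff
  denom <- sigma_a + sigma_w
  phi <- if (denom <= 0) 0 else sigma_a / denom
  list(phi_st = phi, sigma_among = sigma_a, sigma_within = sigma_w)
}

#' Pairwise Phi-st between two sample sets
#'
#' Analysis of molecular variance on squared Kimura 2-parameter distances
#' between haplotypes: Phi-st is the among-population fraction of molecular
#' variance. Significance is assessed by permuting individuals between the
#' two sets (sizes preserved) and counting permuted statistics at least as
#' large as the observed one, with +1 smoothing.
#'
#' @param pop_a,pop_b Lists of \code{mito_profile} objects.
#' @param reference A \code{mito_reference}.
#' @param intervals Comparison intervals (default whole genome).
#' @param n_permutations Number of label permutations.
#' @param seed Optional seed for the permutation stream.
#' @return List of class \code{phist_result} with \code{phi_st},
#'   \code{p_value}, \code{n_permutations}, variance components and labels.
#' @export
pairwise_phist <- function(pop_a, pop_b, reference,
                           intervals = rbind(c(1L, reference$length)),
                           n_permutations = 1000L, seed = NULL) {
  n1 <- length(pop_a); n2 <- length(pop_b)
  stopifnot(n1 >= 2L, n2 >= 2L)
  all_p <- c(pop_a, pop_b)
  N <- n1 + n2
  d2 <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      d <- tryCatch(
        k2p_profile_distance(all_p[[i]], all_p[[j]], reference, intervals),
        error = function(e) {
          stop("distance failed for pair ", all_p[[i]]$sample_id, " / ",
               all_p[[j]]$sample_id, ": ", conditionMessage(e))
        })
      d2[i, j] <- d2[j, i] <- d^2
    }
  }
  obs <- phist_from_d2(d2, seq_len(n1), n1 + seq_len(n2))
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (r in seq_len(n_permutations)) {
    perm <- sample.int(N)
    stat <- phist_from_d2(d2, perm[seq_len(n1)], perm[n1 + seq_len(n2)])
    if (stat$phi_st >= obs$phi_st - 1e-12) ge <- ge + 1L
  }
  structure(list(
    populations = c(pop_label(pop_a, "A"), pop_label(pop_b, "B")),
    phi_st = obs$phi_st, sigma_among = obs$sigma_among,
    sigma_within = obs$sigma_within,
    p_value = (ge + 1L) / (n_permutations + 1L),
    n_permutations = n_permutations, seed = seed
  ), class = "phist_result")
}

pop_label <- function(pop, default) {
  lab <- unique(stats::na.omit(vapply(pop, `[[`, "", "population")))
  if (length(lab) == 1L) lab else default
}

#' @export
print.phist_result <- function(x, ...) {
  cat(sprintf("<phist_result> %s vs %s: Phi-st = %.4f, p = %.4g (%d perms)\n",
              x$populations[1L], x$populations[2L], x$phi_st, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' All pairwise Phi-st values among named sample sets
#'
#' @param datasets Named list; each element a list of \code{mito_profile}s.
#' @param ... Passed to \code{\link{pairwise_phist}}.
#' @return List with \code{phi} and \code{p} matrices and the per-pair
#'   \code{results}.
#' @export
phist_matrix <- function(datasets, ...) {
  k <- length(datasets)
  nm <- names(datasets)
  phi <- matrix(0, k, k, dimnames = list(nm, nm))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  results <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- pairwise_phist(datasets[[i]], datasets[[j]], ...)
      phi[i, j] <- phi[j, i] <- r$phi_st
      p[i, j] <- p[j, i] <- r$p_value
      results[[paste(nm[i], nm[j], sep = ":")]] <- r
    }
  }
  list(phi = phi, p = p, results = results)
}

# ---- Principal coordinate analysis ---------------------------------------

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues, and explained fractions are taken over the positive
#' eigenvalues.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @return List of class \code{mito_pcoa} with \code{coordinates},
#'   \code{eigenvalues} and \code{explained}.
#' @export
pcoa_embed <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(D)
  if (length(pos)) colnames(coords) <- paste0("Coord", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    explained = if (length(pos)) e$values[pos] / sum(e$values[pos])
                else numeric(0)
  ), class = "mito_pcoa")
}

#' @export
print.mito_pcoa <- function(x, ...) {
  cat("<mito_pcoa> ", ncol(x$coordinates), " positive axes; explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained[seq_len(min(3,
            length(x$explained)))]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- PHP characterization and ancestry -----------------------------------

#' Characterize point heteroplasmies across a sample set
#'
#' Tabulates PHPs per individual, classifies each PHP variant as a purine
#' (R) or pyrimidine (Y) transition or a transversion, assigns it to the
#' control region or the coding region, and folds the variant frequency of
#' the non-reference base onto [0, 0.5] (frequencies above 50\% are
#' reported as 1 - VF).
#'
#' @param profiles List of \code{mito_profile} objects.
#' @param catalog A \code{region_catalog}.
#' @return List of class \code{php_summary} with \code{per_individual}
#'   (counts of individuals with 0/1/2/3+ PHPs), \code{variants} (one row
#'   per PHP) and headline fractions.
#' @export
php_characterize <- function(profiles, catalog = region_catalog()) {
  per_ind <- vapply(profiles, function(p) nrow(php_rows(p)), 0L)
  rows <- lapply(profiles, function(p) {
    v <- php_rows(p)
    if (!nrow(v)) return(NULL)
    pair <- v$call
    cls <- ifelse(pair == "R", "transition_R",
                  ifelse(pair == "Y", "transition_Y", "transversion"))
    var_freq <- ifelse(!is.na(v$major_base) & v$major_base == v$ref,
                       1 - v$major_freq, v$major_freq)
    data.frame(
      sample_id = p$sample_id, position = v$position, pair = pair,
      class = cls,
      region = ifelse(in_intervals(v$position, catalog$control_region),
                      "CR", "CDS"),
      variant_freq = var_freq,
      folded_vf = pmin(var_freq, 1 - var_freq),
      stringsAsFactors = FALSE
    )
  })
  variants <- do.call(rbind, rows)
  if (is.null(variants)) variants <- data.frame()
  n_php <- nrow(variants)
  counts <- c(`0` = sum(per_ind == 0L), `1` = sum(per_ind == 1L),
              `2` = sum(per_ind == 2L), `3+` = sum(per_ind >= 3L))
  structure(list(
    per_individual = counts,
    n_individuals_with_php = sum(per_ind > 0L),
    variants = variants,
    fraction_transitions = if (n_php) {
      mean(variants$class != "transversion")
    } else NA_real_,
    fraction_cr = if (n_php) mean(variants$region == "CR") else NA_real_
  ), class = "php_summary")
}

#' Default haplogroup-prefix to continental ancestry map
#'
#' Longest-prefix matching over haplogroup labels; specific Native American
#' founder lineages (A2, B2, C1, C4c, D1, X2a) take precedence over their
#' broader Asian/European parent letters.
#'
#' @return Named character vector mapping prefixes to continents.
#' @export
default_ancestry_map <- function() {
  c(
    L = "African",
    H = "European", HV = "European", I = "European", J = "European",
    K = "European", T = "European", U = "European", V = "European",
    W = "European", X = "European",
    A = "Asian", B = "Asian", C = "Asian", D = "Asian", E = "Asian",
    F = "Asian", G = "Asian", M = "Asian", N = "Asian", Y = "Asian",
    Z = "Asian", R = "Asian",
    A2 = "Native American", B2 = "Native American", C1 = "Native American",
    C4c = "Native American", D1 = "Native American", X2a = "Native American"
  )
}

#' Continental ancestry proportions from haplogroup labels
#'
#' @param profiles List of \code{mito_profile} objects carrying haplogroup
#'   labels.
#' @param map Named prefix-to-continent vector; the longest matching prefix
#'   wins. Unmapped haplogroups are reported as \code{unassigned}, never
#'   guessed.
#' @return List with \code{continent} (proportion table),
#'   \code{haplogroup} (frequency table) and \code{assignments}.
#' @export
ancestry_proportions <- function(profiles, map = default_ancestry_map()) {
  hg <- vapply(profiles, function(p) as.character(p$haplogroup)[1L], "")
  if (anyNA(hg)) stop("every profile must carry a haplogroup label")
  prefixes <- names(map)[order(-nchar(names(map)))]
  continent <- vapply(hg, function(h) {
    for (p in prefixes) {
      if (startsWith(h, p)) return(unname(map[[p]]))
    }
    "unassigned"
  }, "")
  list(
    continent = sort(table(continent) / length(hg), decreasing = TRUE),
    haplogroup = sort(table(hg) / length(hg), decreasing = TRUE),
    assignments = data.frame(haplogroup = hg, continent = continent,
                             stringsAsFactors = FALSE)
  )
}
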