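# Covariate-controlled annotation-permutation null and selection of
# PTM-enriched protein complexes.

#' Default per-type confidence cutoffs for complex selection
#'
#' 99% for Ac, pY and Ub; 95% for pS/T (whose broad distribution gives a
#' heavier null upper tail).
#'
#' @format Named numeric vector.
#' @export
DEFAULT_CONFIDENCE <- c(Ac = 0.99, pST = 0.95, pY = 0.99, Ub = 0.99)

#' Assign complex-member proteins to covariate bins
#'
#' Each protein occurring in the filtered complex set is binned by the
#' quartile of its frequency in the complex dataset crossed with the
#' quartile of its sequence length (up to 16 bins). The bins control for
#' the mild correlation of modification count with both covariates when
#' annotations are permuted. Values equal to a quartile boundary go to the
#' lower quartile. If a covariate is degenerate (fewer distinct quartile
#' boundaries), that axis collapses and the fallback is logged.
#'
#' @param dataset a collated `ptm_dataset`.
#' @param complexes a filtered `complex_set`.
#' @return Object of class `bin_scheme`: list with `bins` (named integer
#'   vector protein -> bin index), `n_bins`, and a `log`.
#' @export
assign_bins <- function(dataset, complexes) {
  proteins <- intersect(unique(unlist(complexes$members)), names(dataset$sequences))
  if (length(proteins) < 16L)
    stopf("need at least 16 distinct complex-member proteins to bin (have %d)",
          length(proteins))
  freq <- vapply(proteins, function(p)
    sum(vapply(complexes$members, function(m) p %in% m, logical(1))), numeric(1))
  len <- nchar(dataset$sequences[proteins])
  log <- character()

  quart <- function(x, label) {
    br <- unique(c(-Inf, stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE), Inf))
    if (length(br) < 5L)
      log <<- c(log, sprintf("%s quartiles degenerate: %d group(s) used",
                             label, length(br) - 1L))
    as.integer(cut(x, breaks = br, right = TRUE, labels = FALSE))
  }
  fq <- quart(freq, "frequency")
  lq <- quart(len, "length")
  bins <- (fq - 1L) * max(lq) + lq
  bins <- as.integer(factor(bins))  # compact indices
  names(bins) <- proteins
  structure(list(bins = bins, n_bins = max(bins),
                 frequency = freq, length = len, log = log),
            class = "bin_scheme")
}

#' Permute PTM annotations across proteins within covariate bins
#'
#' The whole per-protein bundle of site records moves as a unit to another
#' protein identity in the same bin, so per-bin bundle multisets and global
#' per-type site totals are exactly conserved. Positions are retained
#' verbatim: the permuted dataset is a counting null for complex
#' statistics, not a sequence-valid annotation.
#'
#' @param dataset a `ptm_dataset`.
#' @param scheme a `bin_scheme` from [assign_bins()].
#' @param seed integer seed.
#' @return A `ptm_dataset` with permuted protein identities (attribute
#'   `permuted` set).
#' @export
permute_annotations <- function(dataset, scheme, seed) {
  map <- with_local_seed(seed, {
    m <- character(0)
    for (b in seq_len(scheme$n_bins)) {
      ids <- names(scheme$bins)[scheme$bins == b]
      m[ids] <- if (length(ids) > 1L) sample(ids) else ids
    }
    m
  })
  sites <- dataset$sites
  sel <- sites$protein_id %in% names(map)
  new_ids <- map[sites$protein_id[sel]]
  sites$protein_id[sel] <- new_ids
  sites$gene_id[sel] <- dataset$gene_ids[new_ids]
  out <- new_ptm_dataset(sites, dataset$sequences, dataset$gene_ids,
                         c(dataset$log, sprintf("annotation permutation (seed %s)", seed)))
  attr(out, "permuted") <- TRUE
  out
}

# fast kernel: per-complex per-type totals and medians from a count matrix
# with precomputed member row indices (0 rows for unknown members).
complex_tm_kernel <- function(member_rows, member_sizes, counts) {
  k <- ncol(counts)
  n <- length(member_rows)
  total <- matrix(0, n, k)
  med <- matrix(0, n, k)
  for (i in seq_len(n)) {
    rows <- member_rows[[i]]
    sz <- member_sizes[i]
    m <- matrix(0, nrow = sz, ncol = k)
    if (length(rows) > 0L) m[seq_along(rows), ] <- counts[rows, , drop = FALSE]
    total[i, ] <- colSums(m)
    med[i, ] <- apply(m, 2L, stats::median)
  }
  list(total = total, median = med)
}

#' Build the permutation null cloud of complex statistics
#'
#' Generates `R` annotation-permuted datasets, computes every complex's
#' (total, median) statistic for each PTM type under each permutation, and
#' pools all replicates into one null cloud per type.
#'
#' @param dataset a collated `ptm_dataset`.
#' @param complexes a filtered `complex_set`.
#' @param scheme a `bin_scheme`.
#' @param R number of permutation replicates (default 100).
#' @param seed integer seed; replicate r uses a seed derived from it.
#' @return Object of class `null_cloud`: data.frame with columns
#'   `complex_id`, `ptm_type`, `total`, `median`, `replicate` and
#'   attributes `R`, `seed`. Selection pools the pairs across complexes
#'   and replicates; the per-complex identity is retained for diagnostics.
#' @export
build_null <- function(dataset, complexes, scheme, R = 100L, seed = 1L) {
  stopifnot(R >= 1L)
  counts <- ptm_count_matrix(dataset)
  prot <- rownames(counts)
  members <- complexes$members
  member_rows <- lapply(members, function(m) match(intersect(m, prot), prot))
  member_sizes <- lengths(members)
  bin_rows <- lapply(seq_len(scheme$n_bins), function(b)
    match(names(scheme$bins)[scheme$bins == b], prot))

  res <- vector("list", R)
  for (r in seq_len(R)) {
    perm_counts <- with_local_seed(derive_seed(seed, r), {
      pc <- counts
      for (rows in bin_rows)
        if (length(rows) > 1L) pc[rows, ] <- counts[sample(rows), , drop = FALSE]
      pc
    })
    tm <- complex_tm_kernel(member_rows, member_sizes, perm_counts)
    res[[r]] <- data.frame(
      complex_id = rep(names(members), times = length(PTM_TYPES)),
      ptm_type = rep(PTM_TYPES, each = length(members)),
      total = as.vector(tm$total),
      median = as.vector(tm$median),
      replicate = r,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  attr(out, "R") <- R
  attr(out, "seed") <- seed
  class(out) <- c("null_cloud", class(out))
  out
}

#' Select PTM-enriched complexes against the permutation null
#'
#' For each complex and PTM type, the joint empirical exceedance
#' `q = Pr(null total >= observed total AND null median >= observed median)`
#' is computed over the pooled null cloud of that type; a complex is
#' selected when `q < 1 - confidence`. The joint rule is monotone in both
#' coordinates, so raising the confidence can only shrink the selected set.
#'
#' @param stats observed statistics from [complex_ptm_stats()].
#' @param null a `null_cloud` from [build_null()].
#' @param confidence single value or named per-type vector (default
#'   [DEFAULT_CONFIDENCE]).
#' @return data.frame `enrichment_result` with columns complex_id,
#'   ptm_type, total, median, n_members, q, cutoff, selected.
#' @export
select_enriched <- function(stats, null, confidence = DEFAULT_CONFIDENCE) {
  if (length(confidence) == 1L && is.null(names(confidence)))
    confidence <- structure(rep(confidence, 4), names = PTM_TYPES)
  stopifnot(all(PTM_TYPES %in% names(confidence)))
  out <- stats
  out$q <- NA_real_
  out$cutoff <- unname(confidence[out$ptm_type])
  for (t in unique(out$ptm_type)) {
    nt <- null[null$ptm_type == t, , drop = FALSE]
    if (nrow(nt) == 0L) stopf("null cloud empty for type %s", t)
    sel <- which(out$ptm_type == t)
    out$q[sel] <- vapply(sel, function(i)
      mean(nt$total >= out$total[i] & nt$median >= out$median[i]), numeric(1))
  }
  out$selected <- out$q < (1 - out$cutoff)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Overlap analysis among per-type enriched complex sets
#'
#' @param result an `enrichment_result` covering all four PTM types.
#' @return List with `membership` (complex x type logical data.frame for
#'   selected complexes), `pattern_counts` (counts per selection pattern),
#'   `pair_counts` (the six pairwise intersection sizes) and `groups`
#'   (named sets: one per single type, `ge3` = selected for >= 3 types,
#'   `ac_ub` = selected for Ac and Ub but fewer than 3 types).
#' @export
overlap_enriched <- function(result) {
  sel <- result[result$selected, , drop = FALSE]
  ids <- unique(sel$complex_id)
  memb <- matrix(FALSE, nrow = length(ids), ncol = length(PTM_TYPES),
                 dimnames = list(ids, PTM_TYPES))
  for (t in PTM_TYPES) memb[, t] <- ids %in% sel$complex_id[sel$ptm_type == t]
  n_types <- rowSums(memb)
  pattern <- if (length(ids) > 0L)
    apply(memb, 1L, function(v) paste(PTM_TYPES[v], collapse = "&"))
  else character()
  pairs <- utils::combn(PTM_TYPES, 2L)
  pair_counts <- apply(pairs, 2L, function(p) sum(memb[, p[1]] & memb[, p[2]]))
  names(pair_counts) <- apply(pairs, 2L, paste, collapse = "&")
  groups <- lapply(PTM_TYPES, function(t) ids[memb[, t]])
  names(groups) <- PTM_TYPES
  groups$ge3 <- ids[n_types >= 3L]
  groups$ac_ub <- ids[memb[, "Ac"] & memb[, "Ub"] & n_types < 3L]
  list(
    membership = data.frame(complex_id = ids, as.data.frame(memb),
                            n_types = n_types, row.names = NULL),
    pattern_counts = as.data.frame(table(pattern), stringsAsFactors = FALSE),
    pair_counts = pair_counts,
    groups = groups
  )
}
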