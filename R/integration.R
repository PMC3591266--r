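# Signal integration on enriched complex groups: 4 (PTM multiplicity) x
# 4 (PTM type) observed totals versus a complex-resampling null, summarised
# as Z-scores.

#' Partition a complex group's proteins by PTM-type multiplicity
#'
#' Takes the union of member proteins over the group's complexes
#' (deduplicated), drops unmodified members, and splits the rest by the
#' number of distinct PTM types they carry (1-4).
#'
#' @param group character vector of complex ids.
#' @param complexes a `complex_set`.
#' @param dataset a `ptm_dataset`.
#' @return List of four character vectors named `"1" .. "4"`.
#' @export
partition_by_multiplicity <- function(group, complexes, dataset) {
  stopifnot(length(group) > 0L)
  prot <- unique(unlist(complexes$members[group]))
  prot <- intersect(prot, names(dataset$sequences))
  m <- ptm_count_matrix(dataset, prot)
  mult <- rowSums(m > 0L)
  out <- lapply(1:4, function(k) rownames(m)[mult == k])
  names(out) <- as.character(1:4)
  out
}

#' Observed 4x4 signal matrix for a complex group
#'
#' Cell (m, t) is the total number of type-`t` sites carried by the
#' group's multiplicity-`m` proteins.
#'
#' @inheritParams partition_by_multiplicity
#' @return 4x4 numeric matrix, rows multiplicity 1-4, columns Ac/pST/pY/Ub.
#' @export
observed_signal_matrix <- function(group, complexes, dataset) {
  part <- partition_by_multiplicity(group, complexes, dataset)
  out <- matrix(0, 4L, 4L, dimnames = list(paste0(1:4, "_PTMs"), PTM_TYPES))
  counts <- ptm_count_matrix(dataset, unique(unlist(part)))
  for (k in 1:4) {
    p <- part[[k]]
    if (length(p) > 0L) out[k, ] <- colSums(counts[p, , drop = FALSE])
  }
  out
}

#' Null distribution of signal matrices by complex resampling
#'
#' Draws `S` uniform samples of `n_complexes` complexes without
#' replacement from the whole complex universe and reduces each draw to
#' its 4x4 signal matrix.
#'
#' @param n_complexes complexes per draw (the size of the observed group).
#' @param complexes a `complex_set` (the universe).
#' @param dataset a `ptm_dataset`.
#' @param S number of draws (default 1000).
#' @param seed integer seed.
#' @param replace draw complexes with replacement (default `FALSE`,
#'   matching "samples of the same number of complexes").
#' @return List with `mean` and `sd` (4x4 matrices; sd uses the population
#'   n-denominator convention) and `samples` (S x 16 matrix, columns in
#'   column-major 4x4 order).
#' @export
null_signal_distribution <- function(n_complexes, complexes, dataset,
                                     S = 1000L, seed = 1L, replace = FALSE) {
  ids <- names(complexes$members)
  if (n_complexes > length(ids))
    stopf("n_complexes (%d) exceeds available complexes (%d)",
          n_complexes, length(ids))
  ## precompute per-protein multiplicity and counts once
  prot <- names(dataset$sequences)
  counts <- ptm_count_matrix(dataset)
  mult <- rowSums(counts > 0L)
  member_idx <- lapply(complexes$members, function(m) match(intersect(m, prot), prot))

  samples <- with_local_seed(seed, {
    s <- matrix(0, nrow = S, ncol = 16L)
    for (i in seq_len(S)) {
      draw <- sample(seq_along(ids), n_complexes, replace = replace)
      rows <- unique(unlist(member_idx[draw]))
      mm <- matrix(0, 4L, 4L)
      for (k in 1:4) {
        p <- rows[mult[rows] == k]
        if (length(p) > 0L) mm[k, ] <- colSums(counts[p, , drop = FALSE])
      }
      s[i, ] <- as.vector(mm)
    }
    s
  })
  mu <- matrix(colMeans(samples), 4L, 4L,
               dimnames = list(paste0(1:4, "_PTMs"), PTM_TYPES))
  sd_pop <- matrix(sqrt(colMeans(samples^2) - colMeans(samples)^2), 4L, 4L,
                   dimnames = dimnames(mu))
  list(mean = mu, sd = sd_pop, samples = samples, S = S, seed = seed)
}

#' Z-scores of an observed signal matrix against its resampling null
#'
#' `Z = (observed - null mean) / null sd` per cell, with the population-sd
#' convention. Cells whose null sd is zero are flagged undefined rather
#' than reported as infinite; |Z| > 35 is additionally flagged (display
#' saturation convention).
#'
#' @param observed 4x4 matrix from [observed_signal_matrix()].
#' @param null list from [null_signal_distribution()].
#' @return Object of class `signal_matrix`: list with `observed`,
#'   `null_mean`, `null_sd`, `z`, `undefined` and `saturated` (logical
#'   matrices), plus `S` and `seed` metadata.
#' @export
signal_zscores <- function(observed, null) {
  undefined <- null$sd == 0
  z <- (observed - null$mean) / null$sd
  z[undefined] <- NA_real_
  structure(
    list(observed = observed, null_mean = null$mean, null_sd = null$sd,
         z = z, undefined = undefined, saturated = !undefined & abs(z) > 35,
         S = null$S, seed = null$seed, sd_convention = "population"),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix (multiplicity x PTM type) Z-scores:\n")
  print(round(x$z, 2))
  if (any(x$undefined)) cat(sprintf("  %d cell(s) undefined (null sd = 0)\n",
                                    sum(x$undefined)))
  invisible(x)
}

#' Full signal-integration analysis for one complex group
#'
#' Convenience wrapper: observed matrix, resampling null and Z-scores.
#'
#' @inheritParams partition_by_multiplicity
#' @param S number of null draws.
#' @param seed integer seed.
#' @return A `signal_matrix` object.
#' @export
signal_matrix_analysis <- function(group, complexes, dataset,
                                   S = 1000L, seed = 1L) {
  obs <- observed_signal_matrix(group, complexes, dataset)
  null <- null_signal_distribution(length(unique(group)), complexes, dataset,
                                   S = S, seed = seed)
  signal_zscores(obs, null)
}

#' Per-type percentage composition of a complex group's modifications
#'
#' @inheritParams partition_by_multiplicity
#' @return Named numeric vector over the four types summing to 100, or
#'   all-NA with attribute `undefined = TRUE` if the group carries no
#'   modifications.
#' @export
composition_shares <- function(group, complexes, dataset) {
  stopifnot(length(group) > 0L)
  prot <- intersect(unique(unlist(complexes$members[group])),
                    names(dataset$sequences))
  counts <- colSums(ptm_count_matrix(dataset, prot))
  tot <- sum(counts)
  if (tot == 0) {
    out <- structure(rep(NA_real_, 4), names = PTM_TYPES)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * counts / tot
}
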