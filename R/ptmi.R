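# 20AA window density scanning, local peak selection, PTMi spot calling,
# within-protein type-permutation null, and motif annotators.

#' Scan configuration
#'
#' @param window window width in residues (default 20).
#' @param step scan step for the overlapping mode (default 10; the tiled
#'   mode of [tile_windows()] always uses `step = window`).
#' @param theta high-density threshold in modifications per residue
#'   (default 0.3).
#' @param medium_low boundary separating medium from low density
#'   (default 0.05; a window at exactly 0.05 is "low", at exactly
#'   `theta` is "medium").
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(window = 20L, step = 10L, theta = 0.3,
                        medium_low = 0.05) {
  stopifnot(step >= 1L, step <= window, theta > 0, theta < 2,
            medium_low > 0, medium_low < theta)
  structure(list(window = as.integer(window), step = as.integer(step),
                 theta = theta, medium_low = medium_low),
            class = "scan_config")
}

# sites for one protein as a data.frame (possibly empty)
protein_sites <- function(dataset, protein_id) {
  dataset$sites[dataset$sites$protein_id == protein_id, , drop = FALSE]
}

# window statistics at given starts for one protein
window_stats <- function(sequence, sites, starts, width) {
  chars <- seq_chars(sequence)
  styk <- chars %in% c("S", "T", "Y", "K")
  styk_cum <- c(0L, cumsum(styk))
  ends <- starts + width - 1L
  n <- length(starts)
  type_counts <- matrix(0L, n, length(PTM_TYPES),
                        dimnames = list(NULL, PTM_TYPES))
  pos <- sites$position
  for (j in seq_len(n)) {
    inw <- pos >= starts[j] & pos <= ends[j]
    if (any(inw))
      type_counts[j, ] <- as.integer(table(factor(sites$ptm_type[inw],
                                                  levels = PTM_TYPES)))
  }
  n_mods <- rowSums(type_counts)
  data.frame(
    start = starts, end = ends, width = rep(width, n),
    n_mods = n_mods,
    ptm_density = n_mods / width,
    styk_density = (styk_cum[ends + 1L] - styk_cum[starts]) / width,
    type_counts,
    n_types = rowSums(type_counts > 0L),
    stringsAsFactors = FALSE
  )
}

#' Overlapping window scan of one protein
#'
#' Windows of `config$window` residues at starts `1, 1+step, ...` while
#' the window fits inside the sequence; the trailing stretch shorter than
#' one window is not scanned. For each window the modification count
#' (every (position, type) record counts once, so a dually modified lysine
#' counts twice), the PTM density, the S/T/Y/K residue density, per-type
#' counts and the number of distinct types are reported.
#'
#' @param dataset a `ptm_dataset`.
#' @param protein_id protein to scan.
#' @param config a [scan_config()].
#' @return data.frame of windows (zero rows, with a `truncated` note, when
#'   the protein is shorter than one window).
#' @export
scan_windows <- function(dataset, protein_id, config = scan_config()) {
  sequence <- dataset$sequences[[protein_id]]
  len <- nchar(sequence)
  if (len < config$window) {
    out <- window_stats(sequence, protein_sites(dataset, protein_id),
                        integer(0), config$window)
    attr(out, "note") <- sprintf("%s shorter than window (%d < %d): not scanned",
                                 protein_id, len, config$window)
    return(out)
  }
  starts <- seq.int(1L, len - config$window + 1L, by = config$step)
  out <- window_stats(sequence, protein_sites(dataset, protein_id),
                      starts, config$window)
  out$protein_id <- protein_id
  out[, c("protein_id", setdiff(names(out), "protein_id"))]
}

#' Non-overlapping local density peaks
#'
#' Candidate peaks are scan windows with at least one modification whose
#' density is >= that of both span-overlapping neighbours (the windows at
#' the previous and next start; a missing neighbour imposes no
#' constraint). The final set is chosen greedily by descending density
#' (ties broken leftmost-first), discarding candidates whose span overlaps
#' an already accepted peak.
#'
#' @param windows data.frame from [scan_windows()].
#' @return Subset of `windows` rows, ordered by start.
#' @export
local_peaks <- function(windows) {
  n <- nrow(windows)
  if (n == 0L) return(windows)
  d <- windows$ptm_density
  prev_ok <- c(TRUE, d[-1L] >= d[-n])
  next_ok <- c(d[-n] >= d[-1L], TRUE)
  cand <- which(windows$n_mods >= 1L & prev_ok & next_ok)
  if (length(cand) == 0L) return(windows[integer(0), , drop = FALSE])
  ord <- cand[order(-d[cand], windows$start[cand])]
  chosen <- integer(0)
  for (i in ord) {
    s <- windows$start[i]; e <- windows$end[i]
    if (!any(windows$start[chosen] <= e & windows$end[chosen] >= s))
      chosen <- c(chosen, i)
  }
  windows[sort(chosen), , drop = FALSE]
}

#' Minimum modification count for a window to exceed a density threshold
#'
#' Smallest integer `k` with `k / width > theta`. At the default 20-residue
#' window and threshold 0.3 this is 7 modified residues.
#'
#' @param width window width.
#' @param theta density threshold.
#' @return Integer.
#' @export
min_sites_exceeding <- function(width, theta) {
  stopifnot(width >= 1L)
  k <- which((seq_len(width) / width) > theta + 1e-9)
  if (length(k) == 0L) return(width + 1L)
  k[1L]
}

#' Number of binary occupancy states of k modifiable sites
#'
#' @param k number of sites.
#' @return `2^k`.
#' @export
modification_states <- function(k) {
  stopifnot(k >= 0)
  2^k
}

#' Call PTMi spots on one protein
#'
#' All overlapping-scan windows with PTM density strictly above
#' `config$theta` are merged whenever their spans overlap or abut; each
#' merged span becomes a PTMi spot with its density recomputed over the
#' full span. A spot is classified `single` if one PTM type is present
#' and `multi` otherwise.
#'
#' @inheritParams scan_windows
#' @return data.frame with protein_id, start, end, length, n_mods,
#'   density, n_types, types (comma-joined) and classification.
#' @export
call_spots <- function(dataset, protein_id, config = scan_config()) {
  w <- scan_windows(dataset, protein_id, config)
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), length = integer(), n_mods = integer(),
                      density = numeric(), n_types = integer(),
                      types = character(), classification = character(),
                      stringsAsFactors = FALSE)
  hi <- w[w$ptm_density > config$theta, , drop = FALSE]
  if (nrow(hi) == 0L) return(empty)
  hi <- hi[order(hi$start), , drop = FALSE]
  spans <- list(c(hi$start[1L], hi$end[1L]))
  for (i in seq_len(nrow(hi))[-1L]) {
    last <- spans[[length(spans)]]
    if (hi$start[i] <= last[2L] + 1L) {
      spans[[length(spans)]][2L] <- max(last[2L], hi$end[i])
    } else {
      spans[[length(spans) + 1L]] <- c(hi$start[i], hi$end[i])
    }
  }
  sites <- protein_sites(dataset, protein_id)
  out <- lapply(spans, function(sp) {
    inr <- sites$position >= sp[1L] & sites$position <= sp[2L]
    types <- sort(unique(sites$ptm_type[inr]))
    data.frame(
      protein_id = protein_id, start = sp[1L], end = sp[2L],
      length = sp[2L] - sp[1L] + 1L, n_mods = sum(inr),
      density = sum(inr) / (sp[2L] - sp[1L] + 1L),
      n_types = length(types),
      types = paste(types, collapse = ","),
      classification = if (length(types) > 1L) "multi" else "single",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Call PTMi spots across a whole dataset
#'
#' @param dataset a `ptm_dataset`.
#' @param config a [scan_config()].
#' @param proteins proteins to scan (default all).
#' @return data.frame of spots across proteins (with a per-dataset
#'   `spot_id`).
#' @export
call_spots_all <- function(dataset, config = scan_config(),
                           proteins = unique(dataset$sites$protein_id)) {
  out <- lapply(proteins, function(p) call_spots(dataset, p, config))
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), length = integer(), n_mods = integer(),
                      density = numeric(), n_types = integer(),
                      types = character(), classification = character(),
                      stringsAsFactors = FALSE)
  }
  out$spot_id <- sprintf("spot_%04d", seq_len(nrow(out)))
  out
}

#' Permute PTM type labels within one protein
#'
#' Modified positions stay fixed; only the multiset of type labels is
#' permuted uniformly over the site records, so per-type counts and the
#' type-blind density profile are exactly conserved. With fewer than two
#' site records the identity is returned. In `mode = "compatible"`,
#' labels are permuted only among records on residue-compatible positions
#' (in practice: Ac/Ub labels shuffle among lysine records), so the
#' permuted annotation stays chemically valid; the default `"literal"`
#' mode shuffles all labels jointly.
#'
#' @param sites data.frame of one protein's site records.
#' @param seed integer seed.
#' @param mode `"literal"` or `"compatible"`.
#' @return The site data.frame with permuted `ptm_type`.
#' @export
permute_types_within_protein <- function(sites, seed, mode = c("literal", "compatible")) {
  mode <- match.arg(mode)
  if (nrow(sites) < 2L) return(sites)
  with_local_seed(seed, {
    if (mode == "literal") {
      sites$ptm_type <- sample(sites$ptm_type)
    } else {
      cls <- ifelse(sites$residue == "K", "K",
                    ifelse(sites$residue == "Y", "Y", "ST"))
      for (g in unique(cls)) {
        idx <- which(cls == g)
        if (length(idx) > 1L) sites$ptm_type[idx] <- sample(sites$ptm_type[idx])
      }
    }
    sites
  })
}

#' Observed vs permutation-null counts of multi-PTM high-density windows
#'
#' Counts the local density peaks above `config$theta`, split into
#' single-type and multi-type windows, for the observed annotation and
#' for `R` within-protein type permutations. Because the permutation
#' conserves the type-blind density profile, the peak windows themselves
#' are identical across permutations; only the type composition within
#' each peak changes.
#'
#' @param dataset a `ptm_dataset`.
#' @param config a [scan_config()].
#' @param R number of permutation replicates (default 100).
#' @param seed integer seed.
#' @param mode permutation mode, see [permute_types_within_protein()].
#' @return List with `observed` (named vector: single, multi) and `null`
#'   (R x 2 matrix of the same counts per replicate).
#' @export
multi_ptm_high_density_counts <- function(dataset, config = scan_config(),
                                          R = 100L, seed = 1L,
                                          mode = "literal") {
  proteins <- unique(dataset$sites$protein_id)
  ## peak windows above theta, fixed across permutations
  peak_spans <- list()
  for (p in proteins) {
    pk <- local_peaks(scan_windows(dataset, p, config))
    pk <- pk[pk$ptm_density > config$theta, , drop = FALSE]
    if (nrow(pk) > 0L)
      peak_spans[[p]] <- pk[, c("start", "end")]
  }
  count_types <- function(sites_by_prot) {
    single <- 0L; multi <- 0L
    for (p in names(peak_spans)) {
      s <- sites_by_prot[[p]]
      sp <- peak_spans[[p]]
      for (j in seq_len(nrow(sp))) {
        inw <- s$position >= sp$start[j] & s$position <= sp$end[j]
        nt <- length(unique(s$ptm_type[inw]))
        if (nt >= 2L) multi <- multi + 1L else if (nt == 1L) single <- single + 1L
      }
    }
    c(single = single, multi = multi)
  }
  obs_sites <- split(dataset$sites, dataset$sites$protein_id)
  observed <- count_types(obs_sites)
  null <- matrix(0L, R, 2L, dimnames = list(NULL, c("single", "multi")))
  for (r in seq_len(R)) {
    perm <- obs_sites
    for (p in names(peak_spans)) {
      perm[[p]] <- permute_types_within_protein(
        perm[[p]], derive_seed(seed, r * 100003 + match(p, proteins)), mode)
    }
    null[r, ] <- count_types(perm)
  }
  list(observed = observed, null = null, R = R, seed = seed, mode = mode)
}

#' Find PY-NLS core motifs in a protein
#'
#' Matches the tripartite nuclear localization signal core
#' `[R/H/K]-X(2,5)-P-Y` (shortest match per start position). Each match is
#' annotated with the modification records inside its span, whether the
#' motif tyrosine itself carries pY, and the 10 residues upstream (for
#' manual inspection of the basic/hydrophobic stretch, which is not
#' formalised here).
#'
#' @param dataset a `ptm_dataset`.
#' @param protein_id protein to search.
#' @return data.frame with protein_id, start, end, match, upstream10,
#'   n_mods_in_span, mods_in_span (comma-joined `pos:type`), py_on_motif_y.
#' @export
find_py_nls <- function(dataset, protein_id) {
  sequence <- dataset$sequences[[protein_id]]
  m <- gregexpr("(?=([RHK].{2,5}?PY))", sequence, perl = TRUE)[[1L]]
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), match = character(),
                      upstream10 = character(), n_mods_in_span = integer(),
                      mods_in_span = character(), py_on_motif_y = logical(),
                      stringsAsFactors = FALSE)
  if (m[1L] == -1L) return(empty)
  cs <- attr(m, "capture.start")[, 1L]
  cl <- attr(m, "capture.length")[, 1L]
  sites <- protein_sites(dataset, protein_id)
  out <- lapply(seq_along(cs), function(i) {
    s <- cs[i]; e <- cs[i] + cl[i] - 1L
    inr <- sites$position >= s & sites$position <= e
    data.frame(
      protein_id = protein_id, start = s, end = e,
      match = substring(sequence, s, e),
      upstream10 = substring(sequence, max(1L, s - 10L), s - 1L),
      n_mods_in_span = sum(inr),
      mods_in_span = paste(sprintf("%d:%s", sites$position[inr],
                                   sites$ptm_type[inr]), collapse = ","),
      py_on_motif_y = any(sites$position == e & sites$ptm_type == "pY"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Candidate hyperphospho-degron spots
#'
#' Filters multi-type PTMi spots for the Sic1-style degron signature:
#' at least 4 pS/T sites in the span, at least one of which is
#' proline-directed (the modified S/T immediately followed by P in the
#' sequence), and at least one ubiquitination site in the span.
#'
#' @param spots data.frame from [call_spots_all()].
#' @param dataset the `ptm_dataset` the spots were called on.
#' @param min_pst minimum pS/T sites (default 4).
#' @return Subset of `spots` with extra columns n_pst, n_pst_sp, n_ub.
#' @export
find_hyperphospho_degrons <- function(spots, dataset, min_pst = 4L) {
  if (nrow(spots) == 0L) {
    spots$n_pst <- integer(0); spots$n_pst_sp <- integer(0)
    spots$n_ub <- integer(0)
    return(spots)
  }
  keep <- logical(nrow(spots))
  n_pst <- n_sp <- n_ub <- integer(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    p <- spots$protein_id[i]
    sequence <- dataset$sequences[[p]]
    s <- protein_sites(dataset, p)
    inr <- s$position >= spots$start[i] & s$position <= spots$end[i]
    pst <- s[inr & s$ptm_type == "pST", , drop = FALSE]
    n_pst[i] <- nrow(pst)
    nxt <- if (nrow(pst) > 0L)
      substring(sequence, pst$position + 1L, pst$position + 1L)
    else character()
    n_sp[i] <- sum(nxt == "P")
    n_ub[i] <- sum(inr & s$ptm_type == "Ub")
    keep[i] <- n_pst[i] >= min_pst && n_sp[i] >= 1L && n_ub[i] >= 1L
  }
  out <- spots[keep, , drop = FALSE]
  out$n_pst <- n_pst[keep]
  out$n_pst_sp <- n_sp[keep]
  out$n_ub <- n_ub[keep]
  out
}

#' Write spots as a BED-like table
#'
#' Coordinates are emitted 0-based half-open (`start - 1`, `end`).
#'
#' @param spots data.frame from [call_spots_all()].
#' @param path output file.
#' @export
write_spots_bed <- function(spots, path) {
  bed <- data.frame(
    protein_id = spots$protein_id,
    start = spots$start - 1L,
    end = spots$end,
    spot_id = spots$spot_id %||% sprintf("spot_%04d", seq_len(nrow(spots))),
    density = spots$density,
    classification = spots$classification,
    types = spots$types,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
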