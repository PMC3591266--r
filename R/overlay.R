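# Tiled 20AA windows cross-classified by domain overlap, disorder
# content, PTM density and cancer mutation burden.

#' Tile a protein with consecutive non-overlapping windows
#'
#' Starts at 1, W+1, 2W+1, ...; trailing residues shorter than one window
#' are discarded (noted in the `note` attribute).
#'
#' @param dataset a `ptm_dataset`.
#' @param protein_id protein to tile.
#' @param config a [scan_config()]; only `window` is used.
#' @return data.frame of windows as in [scan_windows()].
#' @export
tile_windows <- function(dataset, protein_id, config = scan_config()) {
  W <- config$window
  sequence <- dataset$sequences[[protein_id]]
  len <- nchar(sequence)
  n <- len %/% W
  starts <- if (n >= 1L) seq.int(1L, by = W, length.out = n) else integer(0)
  out <- window_stats(sequence, protein_sites(dataset, protein_id), starts, W)
  if (len %% W != 0L)
    attr(out, "note") <- sprintf("%s: trailing %d residue(s) not tiled",
                                 protein_id, len %% W)
  if (nrow(out) > 0L) out$protein_id <- protein_id
  out
}

#' Parse a tab-delimited domain annotation table
#'
#' Columns: `protein_id`, `name`, `start`, `end` (1-based inclusive).
#' Rows outside the protein bounds are dropped and logged.
#'
#' @param path file path.
#' @param dataset a `ptm_dataset` used for bounds checking.
#' @return data.frame of domains with attribute `log`.
#' @export
parse_domain_table <- function(path, dataset) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "name", "start", "end") %in% names(tab)))
  lens <- nchar(dataset$sequences)[tab$protein_id]
  ok <- !is.na(lens) & tab$start >= 1L & tab$end >= tab$start & tab$end <= lens
  out <- tab[ok, , drop = FALSE]
  attr(out, "log") <- if (any(!ok))
    sprintf("dropped %d out-of-bounds/unknown domain row(s)", sum(!ok))
  else character()
  out
}

#' Parse per-residue binary disorder tracks
#'
#' Two tab-delimited columns: `protein_id` and a 0/1 string of the same
#' length as the protein (1 = disordered, IUPred-style binarised at 0.5).
#'
#' @param path file path.
#' @param dataset a `ptm_dataset`; a length mismatch is an error.
#' @return Named list of integer vectors.
#' @export
parse_disorder_tracks <- function(path, dataset) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("protein_id", "track") %in% names(tab)))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    p <- tab$protein_id[i]
    v <- as.integer(strsplit(tab$track[i], "", fixed = TRUE)[[1L]])
    if (!p %in% names(dataset$sequences))
      stopf("disorder track for unknown protein %s", p)
    if (length(v) != nchar(dataset$sequences[[p]]))
      stopf("disorder track length mismatch for %s (%d vs %d)",
            p, length(v), nchar(dataset$sequences[[p]]))
    out[[p]] <- v
  }
  out
}

#' Parse a mutation table, keeping only residue-consistent records
#'
#' Columns: `protein_id`, `position`, `ref_aa`, `alt_aa`. Records whose
#' annotated reference residue does not match the sequence at that
#' position (or fall outside it) are dropped and counted in the log,
#' mirroring the position-consistency filter applied to cancer mutation
#' data.
#'
#' @param path file path.
#' @param dataset a `ptm_dataset`.
#' @return data.frame of retained mutations with attribute `log`.
#' @export
parse_mutation_table <- function(path, dataset) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "position", "ref_aa") %in% names(tab)))
  tab$position <- as.integer(tab$position)
  lens <- nchar(dataset$sequences)[tab$protein_id]
  inb <- !is.na(lens) & tab$position >= 1L & tab$position <= lens
  res <- rep(NA_character_, nrow(tab))
  res[inb] <- substring(dataset$sequences[tab$protein_id[inb]],
                        tab$position[inb], tab$position[inb])
  ok <- inb & res == tab$ref_aa
  out <- tab[ok, , drop = FALSE]
  attr(out, "log") <- sprintf("retained %d of %d mutation records (%d failed the residue-match filter)",
                              sum(ok), nrow(tab), sum(!ok))
  out
}

#' Classify a window's overlap with protein domains
#'
#' Overlap is the maximum single-domain intersection in residues:
#' `W` residues -> `Int` (internal), 11 to W-1 -> `Lg`, 1-10 -> `Sm`,
#' 0 -> `Ext`.
#'
#' @param starts,ends window coordinates (vectors).
#' @param domains data.frame of this protein's domains (columns start,
#'   end); zero rows means every window is `Ext`.
#' @param W window width.
#' @return Character vector of classes.
#' @export
classify_domain_overlap <- function(starts, ends, domains, W = 20L) {
  ov <- numeric(length(starts))
  for (j in seq_len(nrow(domains))) {
    o <- pmax(0L, pmin(ends, domains$end[j]) - pmax(starts, domains$start[j]) + 1L)
    ov <- pmax(ov, o)
  }
  ifelse(ov == W, "Int", ifelse(ov >= 11L, "Lg", ifelse(ov >= 1L, "Sm", "Ext")))
}

#' Classify a window's disorder content
#'
#' By count of disordered residues in a W-residue window: all `W` ->
#' `High`, 11 to W-1 -> `Med`, 1-10 -> `Low`, 0 -> `none`.
#'
#' @param starts,ends window coordinates.
#' @param track integer 0/1 disorder vector for the protein.
#' @param W window width.
#' @return Character vector of classes.
#' @export
classify_disorder <- function(starts, ends, track, W = 20L) {
  if (length(starts) > 0L && max(ends) > length(track))
    stopf("disorder track shorter than window span")
  cum <- c(0L, cumsum(track))
  cnt <- cum[ends + 1L] - cum[starts]
  ifelse(cnt == W, "High", ifelse(cnt >= 11L, "Med",
                                  ifelse(cnt >= 1L, "Low", "none")))
}

#' Classify a window's PTM density bin
#'
#' `> theta` -> high; `(medium_low, theta]` -> medium; `(0, medium_low]`
#' -> low; 0 -> unmodified. At the defaults a density of exactly 0.05
#' (one site in a 20AA window) is "low" and exactly 0.3 is "medium".
#'
#' @param density numeric vector of window densities.
#' @param config a [scan_config()].
#' @return Character vector of bins.
#' @export
classify_density_bin <- function(density, config = scan_config()) {
  eps <- 1e-9
  ifelse(density > config$theta + eps, "high",
         ifelse(density > config$medium_low + eps, "medium",
                ifelse(density > 0, "low", "unmodified")))
}

#' Flag windows carrying at least kappa mutations
#'
#' @param starts,ends window coordinates.
#' @param positions mutation positions on this protein.
#' @param kappa minimum mutation count (default 2; windows with 0 or 1
#'   mutation are background).
#' @return Logical vector.
#' @export
mutated_window_flag <- function(starts, ends, positions, kappa = 2L) {
  cnt <- vapply(seq_along(starts), function(j)
    sum(positions >= starts[j] & positions <= ends[j]), integer(1))
  cnt >= kappa
}

#' Per-window overlay classification across a dataset
#'
#' Tiles every protein and classifies each window on four independent
#' axes: domain overlap, disorder content, PTM density bin and mutation
#' flag.
#'
#' @param dataset a `ptm_dataset`.
#' @param domains data.frame from [parse_domain_table()] (or equivalent).
#' @param disorder named list from [parse_disorder_tracks()]; proteins
#'   without a track are treated as fully ordered.
#' @param mutations data.frame from [parse_mutation_table()].
#' @param config a [scan_config()].
#' @param kappa mutation-count cutoff (default 2).
#' @param proteins subset of proteins (default all in the dataset).
#' @return data.frame of classified windows.
#' @export
overlay_windows <- function(dataset, domains, disorder, mutations,
                            config = scan_config(), kappa = 2L,
                            proteins = names(dataset$sequences)) {
  W <- config$window
  out <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    p <- proteins[i]
    w <- tile_windows(dataset, p, config)
    if (nrow(w) == 0L) next
    dom <- domains[domains$protein_id == p, , drop = FALSE]
    trk <- disorder[[p]] %||% rep(0L, nchar(dataset$sequences[[p]]))
    mut <- mutations$position[mutations$protein_id == p]
    w$domain_class <- classify_domain_overlap(w$start, w$end, dom, W)
    w$disorder_class <- classify_disorder(w$start, w$end, trk, W)
    w$density_bin <- classify_density_bin(w$ptm_density, config)
    w$n_mutations <- vapply(seq_len(nrow(w)), function(j)
      sum(mut >= w$start[j] & mut <= w$end[j]), integer(1))
    w$mutated <- w$n_mutations >= kappa
    out[[i]] <- w
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stopf("no protein long enough to tile")
  rownames(res) <- NULL
  res
}

#' Mutated-window fraction by domain class and, outside domains, by
#' PTM-density bin
#'
#' One row per domain class (Int, Lg, Sm, Ext) and one row per density
#' bin restricted to `Ext` windows; each row carries its own denominator
#' (`n_windows`), so the fraction can be re-based on all Ext windows or on
#' modified Ext windows only by aggregating rows. Empty categories report
#' `NA` fractions.
#'
#' @param windows data.frame from [overlay_windows()].
#' @param tumor_ids optional protein-id subset (e.g. tumor
#'   suppressors/oncogenes); windows on other proteins are ignored.
#' @return data.frame with axis, category, n_windows, n_mutated, fraction.
#' @export
mutated_fraction_table <- function(windows, tumor_ids = NULL) {
  if (!is.null(tumor_ids))
    windows <- windows[windows$protein_id %in% tumor_ids, , drop = FALSE]
  row_for <- function(axis, category, sel) {
    n <- sum(sel)
    data.frame(axis = axis, category = category, n_windows = n,
               n_mutated = sum(windows$mutated[sel]),
               fraction = if (n > 0L) sum(windows$mutated[sel]) / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (cl in c("Int", "Lg", "Sm", "Ext"))
    out[[length(out) + 1L]] <- row_for("domain", cl, windows$domain_class == cl)
  ext <- windows$domain_class == "Ext"
  for (b in c("high", "medium", "low", "unmodified"))
    out[[length(out) + 1L]] <- row_for("ext_density", b,
                                       ext & windows$density_bin == b)
  do.call(rbind, out)
}
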