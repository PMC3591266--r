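# Protein complex membership: parsing, filtering, family collapsing and
# per-complex per-PTM-type modification statistics.

#' Construct a complex set
#'
#' @param members named list; one character vector of member protein ids
#'   per complex, names are complex ids.
#' @param family named character vector of family-group labels (NA when a
#'   complex is not part of a family-expanded group).
#' @param log provenance messages.
#' @return Object of class `complex_set`.
#' @export
new_complex_set <- function(members, family = NULL, log = character()) {
  stopifnot(is.list(members), !is.null(names(members)))
  if (is.null(family))
    family <- structure(rep(NA_character_, length(members)), names = names(members))
  structure(list(members = members, family = family[names(members)], log = log),
            class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  sizes <- lengths(x$members)
  cat(sprintf("complex_set: %d complexes, member count %d-%d (median %g)\n",
              length(x$members),
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L,
              if (length(sizes)) stats::median(sizes) else 0))
  invisible(x)
}

#' Parse a tab-delimited complex membership table
#'
#' Expected columns: `complex_id`, `members` (semicolon-separated protein
#' ids) and optionally `family_group`. Duplicate member ids within one
#' complex are collapsed to the unique set (flagged in the log); rows with
#' an empty member field are rejected.
#'
#' @param path file path.
#' @return A `complex_set`.
#' @export
parse_complexes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("complex_id", "members") %in% names(tab)))
    stopf("complex table must have columns complex_id and members")
  log <- character()
  members <- list()
  family <- character()
  for (i in seq_len(nrow(tab))) {
    cid <- tab$complex_id[i]
    raw <- strsplit(tab$members[i], ";", fixed = TRUE)[[1L]]
    raw <- raw[nzchar(raw)]
    if (length(raw) == 0L) {
      log <- c(log, sprintf("rejected complex %s: empty member list", cid))
      next
    }
    uniq <- unique(raw)
    if (length(uniq) < length(raw))
      log <- c(log, sprintf("complex %s: duplicate member ids collapsed", cid))
    members[[cid]] <- uniq
    family[cid] <- if ("family_group" %in% names(tab) && nzchar(tab$family_group[i]))
      tab$family_group[i] else NA_character_
  }
  new_complex_set(members, family, log)
}

#' Filter complexes and collapse family-expanded variants
#'
#' Removes complexes with fewer than 3 unique members, merges complexes
#' with exactly identical member sets, and within each family group keeps
#' only the variant with the largest total PTM count over all four types
#' (ties broken by smallest complex id). Member ids absent from the PTM
#' dataset are retained but flagged; they contribute zero modifications.
#'
#' @param complexes a `complex_set`.
#' @param dataset a collated `ptm_dataset`.
#' @return A filtered `complex_set`.
#' @export
filter_and_collapse <- function(complexes, dataset) {
  members <- complexes$members
  family <- complexes$family
  log <- complexes$log

  unknown <- setdiff(unique(unlist(members)), names(dataset$sequences))
  if (length(unknown) > 0L)
    log <- c(log, sprintf("%d member id(s) absent from PTM dataset (count 0): %s",
                          length(unknown),
                          paste(utils::head(unknown, 10), collapse = ",")))

  small <- names(members)[lengths(members) < 3L]
  if (length(small) > 0L) {
    log <- c(log, sprintf("removed %d complex(es) with <3 unique members: %s",
                          length(small), paste(small, collapse = ",")))
    members <- members[setdiff(names(members), small)]
  }

  ## merge exact-duplicate member sets (keep smallest id)
  sig <- vapply(members, function(m) paste(sort(m), collapse = ";"), character(1))
  for (s in unique(sig[duplicated(sig)])) {
    ids <- sort(names(members)[sig == s])
    members <- members[setdiff(names(members), ids[-1L])]
    sig <- sig[names(members)]
    log <- c(log, sprintf("identical member sets %s merged onto %s",
                          paste(ids, collapse = ","), ids[1L]))
  }

  ## family collapse: most PTM-annotated variant, tie -> smallest id
  fam <- complexes$family[names(members)]
  counts <- ptm_count_matrix(dataset)
  total_of <- function(ids) {
    known <- intersect(ids, rownames(counts))
    if (length(known) == 0L) 0L else sum(counts[known, , drop = FALSE])
  }
  for (g in unique(stats::na.omit(fam))) {
    ids <- names(members)[!is.na(fam) & fam == g]
    if (length(ids) < 2L) next
    tot <- vapply(members[ids], total_of, numeric(1))
    ord <- order(-tot, ids)
    keep <- ids[ord[1L]]
    members <- members[setdiff(names(members), setdiff(ids, keep))]
    fam <- fam[names(members)]
    log <- c(log, sprintf("family %s: kept %s (total %d of %s)", g, keep,
                          as.integer(max(tot)),
                          paste(as.integer(tot), collapse = "/")))
  }

  new_complex_set(members, complexes$family[names(members)], log)
}

#' Per-complex, per-type modification statistics
#'
#' For each complex and PTM type, the total over members of per-member
#' site counts and the median of the member-count vector. Members absent
#' from the dataset count zero; the median of an even-sized vector is the
#' mean of the two central values.
#'
#' @param complexes a `complex_set`.
#' @param dataset a `ptm_dataset`.
#' @param ptm_type PTM types to report (default all four).
#' @return data.frame with complex_id, ptm_type, total, median, n_members.
#' @export
complex_ptm_stats <- function(complexes, dataset, ptm_type = PTM_TYPES) {
  counts <- ptm_count_matrix(dataset)
  complex_stats_from_counts(complexes$members, counts, ptm_type)
}

# Core statistic kernel, reused by the permutation null (which permutes
# the rows of `counts` rather than rebuilding datasets).
complex_stats_from_counts <- function(members, counts, ptm_type = PTM_TYPES) {
  out <- vector("list", length(members))
  ids <- names(members)
  for (i in seq_along(members)) {
    mem <- members[[i]]
    known <- intersect(mem, rownames(counts))
    m <- matrix(0, nrow = length(mem), ncol = length(ptm_type))
    if (length(known) > 0L)
      m[match(known, mem), ] <- counts[known, ptm_type, drop = FALSE]
    out[[i]] <- data.frame(
      complex_id = ids[i],
      ptm_type = ptm_type,
      total = colSums(m),
      median = apply(m, 2L, stats::median),
      n_members = length(mem),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
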