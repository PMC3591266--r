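# Synthetic proteome / PTM / complex / annotation generator. Emits exactly
# the dialects the analysis modules consume, plus a ground-truth manifest,
# so every pipeline stage is testable without external downloads.

# Approximate human proteome amino-acid frequencies.
HUMAN_AA_FREQ <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, Q = 0.048,
  E = 0.071, G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.057,
  M = 0.021, F = 0.037, P = 0.063, S = 0.083, T = 0.053, W = 0.012,
  Y = 0.027, V = 0.060
)

# Low-complexity composition used inside hotspot spans, emulating the
# disordered regions where dense modification clusters live (S/T-rich
# serine stretches, K-rich histone-tail-like stretches). The residues
# compatible with the span's target PTM type take a combined frequency of
# `compat_total`; the remainder follows the proteome composition.
hotspot_composition <- function(target_type, compat_total = 0.5) {
  compat <- PTM_COMPAT[[target_type]]
  rest <- HUMAN_AA_FREQ[setdiff(names(HUMAN_AA_FREQ), compat)]
  out <- c(structure(rep(compat_total / length(compat), length(compat)),
                     names = compat),
           rest / sum(rest) * (1 - compat_total))
  out[names(HUMAN_AA_FREQ)[names(HUMAN_AA_FREQ) %in% names(out)]]
}

#' Configuration for the synthetic data generator
#'
#' Defaults emulate the structure of the real collated inputs: protein
#' lengths roughly log-normal around 400 residues; human-like amino acid
#' composition; per-type background modification rates in the observed
#' proportions (pS/T > Ub > pY > Ac) at a total of ~0.017 modifications
#' per residue; hotspot spans of 20-60 residues with a low-complexity
#' composition rich in residues compatible with the span's target type
#' (disorder-like); complexes of >= 3 members with a
#' configurable enriched fraction whose members carry a multiplied rate of
#' one target type.
#'
#' @param n_proteins number of proteins.
#' @param length_meanlog,length_sdlog log-normal length parameters; with
#'   `length_sdlog = 0` every protein has length `exp(length_meanlog)`.
#' @param length_min minimum protein length.
#' @param composition `"human"`, `"uniform"`, or a named frequency vector.
#' @param background_rates expected background modifications per sequence
#'   residue, per type.
#' @param hotspot list: `fraction` of proteins given hotspots,
#'   `n_per_protein`, `span_range` (min/max span length), `rate` (total
#'   modifications per residue inside a span), `n_sites` (exact site count
#'   per hotspot, overriding `rate` when non-NULL), `type_pure` (one PTM
#'   type per hotspot), `types` (candidate target types).
#' @param complexes list: `n`, `size_min`, `size_lambda` (member count =
#'   size_min + Poisson(size_lambda)), `enriched_fraction`, `multiplier`
#'   (background-rate multiplier for members of enriched complexes),
#'   `types` (candidate target types for enriched complexes).
#' @param domains list: `per_protein` (max domains per protein; the count
#'   is uniform on 0..per_protein), `length_range`.
#' @param disorder list: `per_protein` max segments, `length_range`,
#'   `cover_hotspots` (mark hotspot spans disordered).
#' @param mutations list: `rate` (mutations per residue outside domains),
#'   `domain_multiplier`, `dense_multiplier` (applied in tiled windows
#'   whose PTM density exceeds `theta`), `theta`.
#' @param seed master seed; all child seeds derive from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_proteins = 300L,
    length_meanlog = log(400), length_sdlog = 0.45, length_min = 50L,
    composition = "human",
    background_rates = c(Ac = 0.0011, pST = 0.0095, pY = 0.0022, Ub = 0.0041),
    hotspot = list(fraction = 0.1, n_per_protein = 1L, span_range = c(20L, 60L),
                   rate = 0.35, n_sites = NULL, type_pure = TRUE,
                   types = PTM_TYPES),
    complexes = list(n = 100L, size_min = 3L, size_lambda = 2,
                     enriched_fraction = 0.1, multiplier = 5,
                     types = PTM_TYPES),
    domains = list(per_protein = 2L, length_range = c(80L, 150L)),
    disorder = list(per_protein = 2L, length_range = c(30L, 100L),
                    cover_hotspots = TRUE),
    mutations = list(rate = 0.05, domain_multiplier = 3,
                     dense_multiplier = 3, theta = 0.3),
    seed = 1L) {
  stopifnot(all(background_rates >= 0), all(background_rates <= 1),
            all(PTM_TYPES %in% names(background_rates)))
  comp <- if (identical(composition, "human")) HUMAN_AA_FREQ
          else if (identical(composition, "uniform"))
            structure(rep(1 / 20, 20), names = AA20)
          else composition
  stopifnot(abs(sum(comp) - 1) < 0.01)
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         length_min = as.integer(length_min),
         composition = comp / sum(comp),
         background_rates = background_rates[PTM_TYPES],
         hotspot = hotspot, complexes = complexes, domains = domains,
         disorder = disorder, mutations = mutations, seed = seed),
    class = "synthetic_config"
  )
}

#' Generate a synthetic proteome with hotspot spans
#'
#' Sequences are drawn residue-wise from the configured composition;
#' hotspot spans (placed uniformly at random, non-overlapping) are
#' re-drawn from a composition rich in residues compatible with the
#' span's target PTM type so that dense modification is
#' chemically possible, and their coordinates are recorded as ground
#' truth.
#'
#' @param config a [synthetic_config()].
#' @return List with `sequences` (named character vector) and `hotspots`
#'   (data.frame protein_id, start, end, target_type).
#' @export
generate_proteome <- function(config) {
  with_local_seed(derive_seed(config$seed, 1L), {
    n <- config$n_proteins
    lens <- pmax(config$length_min,
                 round(stats::rlnorm(n, config$length_meanlog, config$length_sdlog)))
    ids <- sprintf("P%04d", seq_len(n))
    aa <- names(config$composition)
    seqs <- vapply(lens, function(L)
      paste(sample(aa, L, replace = TRUE, prob = config$composition),
            collapse = ""), character(1))
    names(seqs) <- ids

    hs <- config$hotspot
    hot <- list()
    n_hot <- round(hs$fraction * n)
    hot_prot <- if (n_hot > 0L) sample(ids, n_hot) else character(0)
    for (p in hot_prot) {
      L <- lens[match(p, ids)]
      taken <- matrix(0L, 0L, 2L)
      for (k in seq_len(hs$n_per_protein)) {
        span <- sample_from(seq.int(hs$span_range[1L], hs$span_range[2L]), 1L)
        if (L < span) next
        for (try in 1:20) {
          s <- sample.int(L - span + 1L, 1L)
          e <- s + span - 1L
          if (!any(taken[, 1L] <= e & taken[, 2L] >= s)) {
            taken <- rbind(taken, c(s, e))
            tt <- sample(hs$types, 1L)
            hot[[length(hot) + 1L]] <- data.frame(
              protein_id = p, start = s, end = e, target_type = tt,
              stringsAsFactors = FALSE)
            ## rewrite the span with a disorder-like composition rich in
            ## residues compatible with the target type; when an exact
            ## site count is requested the span must be able to host it,
            ## so that many positions are forced to compatible residues
            comp <- hotspot_composition(tt)
            repl <- sample(names(comp), span, replace = TRUE, prob = comp)
            if (!is.null(hs$n_sites)) {
              need <- min(hs$n_sites, span)
              compat <- PTM_COMPAT[[tt]]
              have <- which(repl %in% compat)
              if (length(have) < need) {
                fill <- sample(setdiff(seq_len(span), have), need - length(have))
                repl[fill] <- sample(compat, length(fill), replace = TRUE)
              }
            }
            seqs[p] <- paste0(substring(seqs[p], 1L, s - 1L),
                              paste(repl, collapse = ""),
                              substring(seqs[p], e + 1L, L))
            break
          }
        }
      }
    }
    hotspots <- if (length(hot) > 0L) do.call(rbind, hot) else
      data.frame(protein_id = character(), start = integer(),
                 end = integer(), target_type = character(),
                 stringsAsFactors = FALSE)
    list(sequences = seqs, hotspots = hotspots)
  })
}

# Bernoulli site draw on compatible residues of one type within a span.
# `rate` is the expected number of modifications per span residue, so the
# per-compatible-residue probability is rate * span / n_compatible.
draw_sites_span <- function(chars, from, to, type, rate, n_exact = NULL) {
  compat <- which(chars %in% PTM_COMPAT[[type]])
  compat <- compat[compat >= from & compat <= to]
  if (length(compat) == 0L) return(integer(0))
  if (!is.null(n_exact)) {
    k <- min(n_exact, length(compat))
    return(sort(sample_from(compat, k)))
  }
  p <- min(1, rate * (to - from + 1L) / length(compat))
  compat[stats::runif(length(compat)) < p]
}

#' Implant PTM sites onto a synthetic proteome
#'
#' Background sites are drawn per residue-compatible position so that the
#' expected count per type equals `rate * length`; hotspot spans receive
#' the elevated hotspot rate (or an exact per-hotspot site count), of the
#' recorded target type only when `type_pure`. `elevation` (from
#' [generate_complex_set()]) multiplies a protein's background rate for
#' one target type, implementing complex-level enrichment.
#'
#' @param proteome from [generate_proteome()].
#' @param config a [synthetic_config()].
#' @param elevation optional data.frame (protein_id, ptm_type, multiplier).
#' @return A validated `ptm_dataset` (gene id = protein id).
#' @export
implant_sites <- function(proteome, config, elevation = NULL) {
  seqs <- proteome$sequences
  hs <- config$hotspot
  rows <- list()
  with_local_seed(derive_seed(config$seed, 2L), {
    for (p in names(seqs)) {
      chars <- seq_chars(seqs[[p]])
      L <- length(chars)
      for (t in PTM_TYPES) {
        r <- config$background_rates[[t]]
        if (!is.null(elevation)) {
          m <- elevation$multiplier[elevation$protein_id == p &
                                    elevation$ptm_type == t]
          if (length(m) > 0L) r <- r * max(m)
        }
        if (r <= 0) next
        pos <- draw_sites_span(chars, 1L, L, t, r)
        if (length(pos) > 0L)
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = p, position = pos, ptm_type = t,
            stringsAsFactors = FALSE)
      }
      hsp <- proteome$hotspots[proteome$hotspots$protein_id == p, , drop = FALSE]
      for (j in seq_len(nrow(hsp))) {
        types <- if (isTRUE(hs$type_pure)) hsp$target_type[j] else hs$types
        for (t in types) {
          pos <- draw_sites_span(chars, hsp$start[j], hsp$end[j], t,
                                 hs$rate / length(types), hs$n_sites)
          if (length(pos) > 0L)
            rows[[length(rows) + 1L]] <- data.frame(
              protein_id = p, position = pos, ptm_type = t,
              stringsAsFactors = FALSE)
        }
      }
    }
  })
  sites <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(protein_id = character(), position = integer(),
               ptm_type = character(), stringsAsFactors = FALSE)
  ## dedupe (protein, position, type); fill residue, flank, gene
  key <- paste(sites$protein_id, sites$position, sites$ptm_type, sep = "\r")
  sites <- sites[!duplicated(key), , drop = FALSE]
  sites$gene_id <- sites$protein_id
  sites$residue <- substring(seqs[sites$protein_id], sites$position, sites$position)
  sites$flank13 <- vapply(seq_len(nrow(sites)), function(i)
    flank13_of(seqs[[sites$protein_id[i]]], sites$position[i]), character(1))
  sites <- sites[order(sites$protein_id, sites$position, sites$ptm_type),
                 SITE_COLUMNS, drop = FALSE]
  new_ptm_dataset(sites, seqs,
                  log = sprintf("synthetic sites (seed %s)", config$seed))
}

#' Generate a synthetic complex set with designated enriched complexes
#'
#' Members are drawn uniformly; complexes designated enriched recruit
#' proteins not already claimed by another enriched complex and assign
#' them a background-rate multiplier for the complex's target type
#' (realised later by [implant_sites()]).
#'
#' @param proteome from [generate_proteome()].
#' @param config a [synthetic_config()].
#' @return List with `complexes` (a `complex_set`), `truth` (data.frame
#'   complex_id, enriched, target_type) and `elevation` (data.frame for
#'   [implant_sites()]).
#' @export
generate_complex_set <- function(proteome, config) {
  cc <- config$complexes
  ids <- names(proteome$sequences)
  with_local_seed(derive_seed(config$seed, 3L), {
    n <- cc$n
    sizes <- cc$size_min + stats::rpois(n, cc$size_lambda)
    cplx_ids <- sprintf("C%03d", seq_len(n))
    n_enr <- round(cc$enriched_fraction * n)
    enriched <- seq_len(n) <= n_enr  # first complexes enriched; ids are arbitrary labels
    target <- rep(NA_character_, n)
    members <- vector("list", n)
    claimed <- character(0)
    elev <- list()
    for (i in seq_len(n)) {
      if (enriched[i]) {
        pool <- setdiff(ids, claimed)
        if (length(pool) < sizes[i]) pool <- ids
        mem <- sample(pool, sizes[i])
        claimed <- union(claimed, mem)
        target[i] <- sample(cc$types, 1L)
        elev[[i]] <- data.frame(protein_id = mem, ptm_type = target[i],
                                multiplier = cc$multiplier,
                                stringsAsFactors = FALSE)
      } else {
        mem <- sample(ids, min(sizes[i], length(ids)))
      }
      members[[i]] <- mem
    }
    names(members) <- cplx_ids
    list(
      complexes = new_complex_set(members,
                                  log = sprintf("synthetic complexes (seed %s)",
                                                config$seed)),
      truth = data.frame(complex_id = cplx_ids, enriched = enriched,
                         target_type = target, stringsAsFactors = FALSE),
      elevation = if (length(elev) > 0L) do.call(rbind, elev) else
        data.frame(protein_id = character(), ptm_type = character(),
                   multiplier = numeric(), stringsAsFactors = FALSE)
    )
  })
}

#' Generate domain, disorder and mutation annotations
#'
#' Domains are non-overlapping random spans; disorder segments are random
#' spans, with hotspot spans additionally marked disordered when
#' configured; mutations are drawn per residue at the background rate
#' multiplied inside domains and (optionally) inside tiled windows whose
#' PTM density exceeds the configured threshold.
#'
#' @param proteome from [generate_proteome()].
#' @param config a [synthetic_config()].
#' @param dataset optional `ptm_dataset` (needed for the dense-window
#'   mutation multiplier).
#' @return List with `domains`, `disorder` (named list of 0/1 vectors)
#'   and `mutations` (data.frame protein_id, position, ref_aa, alt_aa).
#' @export
generate_annotations <- function(proteome, config, dataset = NULL) {
  seqs <- proteome$sequences
  dm <- config$domains; dz <- config$disorder; mu <- config$mutations
  with_local_seed(derive_seed(config$seed, 4L), {
    domains <- list(); disorder <- list(); mutations <- list()
    for (p in names(seqs)) {
      L <- nchar(seqs[[p]])
      ## domains
      taken <- matrix(0L, 0L, 2L)
      n_dom <- if (dm$per_protein > 0L) sample.int(dm$per_protein + 1L, 1L) - 1L else 0L
      for (k in seq_len(n_dom)) {
        span <- sample_from(seq.int(dm$length_range[1L], dm$length_range[2L]), 1L)
        if (L < span) next
        for (try in 1:20) {
          s <- sample.int(L - span + 1L, 1L); e <- s + span - 1L
          if (!any(taken[, 1L] <= e & taken[, 2L] >= s)) {
            taken <- rbind(taken, c(s, e))
            domains[[length(domains) + 1L]] <- data.frame(
              protein_id = p, name = sprintf("DOM_%s_%d", p, k),
              start = s, end = e, stringsAsFactors = FALSE)
            break
          }
        }
      }
      ## disorder
      trk <- rep(0L, L)
      n_seg <- if (dz$per_protein > 0L) sample.int(dz$per_protein + 1L, 1L) - 1L else 0L
      for (k in seq_len(n_seg)) {
        span <- sample_from(seq.int(dz$length_range[1L], dz$length_range[2L]), 1L)
        if (L < span) next
        s <- sample.int(L - span + 1L, 1L)
        trk[s:(s + span - 1L)] <- 1L
      }
      if (isTRUE(dz$cover_hotspots)) {
        hsp <- proteome$hotspots[proteome$hotspots$protein_id == p, , drop = FALSE]
        for (j in seq_len(nrow(hsp))) trk[hsp$start[j]:hsp$end[j]] <- 1L
      }
      disorder[[p]] <- trk
      ## mutations
      rate <- rep(mu$rate, L)
      for (j in seq_len(nrow(taken)))
        rate[taken[j, 1L]:taken[j, 2L]] <- mu$rate * mu$domain_multiplier
      if (!is.null(dataset) && mu$dense_multiplier != 1) {
        w <- tile_windows(dataset, p, scan_config(theta = mu$theta))
        dense <- w[w$ptm_density > mu$theta, , drop = FALSE]
        for (j in seq_len(nrow(dense)))
          rate[dense$start[j]:dense$end[j]] <-
            rate[dense$start[j]:dense$end[j]] * mu$dense_multiplier
      }
      hit <- which(stats::runif(L) < rate)
      if (length(hit) > 0L) {
        ref <- substring(seqs[[p]], hit, hit)
        alt <- vapply(ref, function(a) sample(setdiff(AA20, a), 1L), character(1))
        mutations[[length(mutations) + 1L]] <- data.frame(
          protein_id = p, position = hit, ref_aa = ref, alt_aa = alt,
          stringsAsFactors = FALSE)
      }
    }
    list(
      domains = if (length(domains) > 0L) do.call(rbind, domains) else
        data.frame(protein_id = character(), name = character(),
                   start = integer(), end = integer(), stringsAsFactors = FALSE),
      disorder = disorder,
      mutations = if (length(mutations) > 0L) do.call(rbind, mutations) else
        data.frame(protein_id = character(), position = integer(),
                   ref_aa = character(), alt_aa = character(),
                   stringsAsFactors = FALSE)
    )
  })
}

#' Generate a complete synthetic input bundle
#'
#' Runs the full generator chain (proteome -> complexes -> sites ->
#' annotations) and optionally writes every input file in the dialect the
#' parsers consume, plus a JSON ground-truth manifest.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; created if missing.
#' @return List with `dataset` (a `ptm_dataset`), `complexes`, `truth`
#'   (hotspots, enriched complexes, elevation), `domains`, `disorder`,
#'   `mutations`, `config`, and (when written) `paths`.
#' @export
generate_synthetic_bundle <- function(config = synthetic_config(), dir = NULL) {
  proteome <- generate_proteome(config)
  cx <- generate_complex_set(proteome, config)
  dataset <- implant_sites(proteome, config, cx$elevation)
  ann <- generate_annotations(proteome, config, dataset)
  out <- list(dataset = dataset, complexes = cx$complexes,
              truth = list(hotspots = proteome$hotspots,
                           enriched = cx$truth, elevation = cx$elevation),
              domains = ann$domains, disorder = ann$disorder,
              mutations = ann$mutations, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "proteome.fasta"),
      sites = file.path(dir, "sites.tsv"),
      complexes = file.path(dir, "complexes.tsv"),
      domains = file.path(dir, "domains.tsv"),
      disorder = file.path(dir, "disorder.tsv"),
      mutations = file.path(dir, "mutations.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    aa <- Biostrings::AAStringSet(dataset$sequences)
    Biostrings::writeXStringSet(aa, paths$fasta)
    write_site_table(dataset, paths$sites)
    utils::write.table(
      data.frame(complex_id = names(out$complexes$members),
                 members = vapply(out$complexes$members, paste,
                                  character(1), collapse = ";"),
                 family_group = ifelse(is.na(out$complexes$family), "",
                                       out$complexes$family)),
      paths$complexes, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ann$domains, paths$domains, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(protein_id = names(ann$disorder),
                 track = vapply(ann$disorder, paste, character(1), collapse = "")),
      paths$disorder, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ann$mutations, paths$mutations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           n_proteins = config$n_proteins,
           hotspots = proteome$hotspots,
           enriched_complexes = cx$truth[cx$truth$enriched, , drop = FALSE]),
      paths$manifest, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
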